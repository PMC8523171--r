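#' Preset ITC scenarios
#'
#' Named parameter sets for the titration simulator. The Kd1/Kd2 ratios of
#' the presets anchor to the printed reference values for tandem-RRM and
#' single-RRM constructs on GT repeats (128, 8.9, 0.25, 0.05); the absolute
#' constants and enthalpies are package defaults chosen so the experiment
#' operates in the informative Wiseman-c range, and are labelled synthetic,
#' not measured values.
#'
#' @param name One of `"cooperative"` (Kd1/Kd2 = 128, total dH -80),
#'   `"weak_cooperative"` (8.9), `"independent"` (0.25, two identical
#'   independent sites), `"anticooperative"` (0.05), `"ratio1"` (1) or
#'   `"onesite"` (one site, dH -33).
#' @return A list with `name`, `model` (a [binding_model()]) and
#'   `kd1_over_kd2`.
#' @export
itc_scenario <- function(name = c("cooperative", "weak_cooperative",
                                  "independent", "anticooperative",
                                  "ratio1", "onesite")) {
  name <- match.arg(name)
  model <- switch(name,
    cooperative      = binding_model(c(4e-6, 31.25e-9), c(-40, -40)),
    weak_cooperative = binding_model(c(2e-6, 2e-6 / 8.9), c(-20, -20)),
    independent      = binding_model(c(1e-6, 4e-6), c(-16.5, -16.5)),
    anticooperative  = binding_model(c(0.25e-6, 5e-6), c(-16.5, -16.5)),
    ratio1           = binding_model(c(1e-6, 1e-6), c(-20, -20)),
    onesite          = binding_model(0.3e-6, -33)
  )
  list(name = name,
       model = model,
       kd1_over_kd2 = if (model$n_sites == 2L) model$kd[1] / model$kd[2]
                      else NA_real_)
}

#' Generate a synthetic ITC titration
#'
#' Wraps [simulate_itc()] with the default experimental geometry (36 x 1 uL
#' injections of 120 uM lattice into a 200 uL cell at 15 uM protein) and
#' Gaussian heat noise expressed as a fraction of the largest expected
#' injection heat. Deterministic given `(scenario, seed)`.
#'
#' @param scenario A preset name for [itc_scenario()], or a list with a
#'   `model` element (a [binding_model()]) and optional `name`.
#' @param seed Integer seed.
#' @param protocol An [itc_protocol()].
#' @param noise_frac Noise SD as a fraction of `max(abs(expected heat))`.
#' @param dilution_offset_ucal Constant per-injection dilution heat, ucal.
#' @return List with `thermogram` and `truth` (model parameters, ratio,
#'   noise SD, seed, scenario name).
#' @export
gen_itc <- function(scenario = "cooperative", seed = 1,
                    protocol = itc_protocol(), noise_frac = 0.01,
                    dilution_offset_ucal = 0) {
  sc <- if (is.character(scenario)) itc_scenario(scenario) else scenario
  stopifnot(inherits(sc$model, "binding_model"))
  q0 <- expected_heats(sc$model, protocol, dilution_offset_ucal)
  noise_sd <- noise_frac * max(abs(q0))
  tg <- simulate_itc(sc$model, protocol, noise_sd_ucal = noise_sd,
                     dilution_offset_ucal = dilution_offset_ucal, seed = seed)
  list(thermogram = tg,
       truth = list(scenario = sc$name %||% "custom",
                    kd = sc$model$kd, dh = sc$model$dh,
                    kd1_over_kd2 = if (sc$model$n_sites == 2L)
                      sc$model$kd[1] / sc$model$kd[2] else NA_real_,
                    noise_sd_ucal = noise_sd,
                    dilution_offset_ucal = dilution_offset_ucal,
                    seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default scenario for synthetic microtubule-bench profiles
#'
#' @param n_paths Number of paths.
#' @param path_length_px Path length, pixels.
#' @param pixel_size_nm Pixel size, nm.
#' @param baseline Mean channel intensity away from compartments, a.u.
#' @param compartment_rate_per_mm Expected planted compartments per mm of
#'   path (Poisson).
#' @param enrichment_meanlog,enrichment_sdlog,enrichment_min Lognormal
#'   enrichment distribution, truncated below at `enrichment_min`.
#' @param length_px_range Integer range of planted compartment lengths.
#' @param snr Baseline signal-to-noise ratio (total noise SD =
#'   `baseline / snr`).
#' @param poisson_share Fraction of the noise variance carried by the
#'   shot-noise (Poisson) component; the rest is additive Gaussian.
#' @param shading_amplitude,shading_period_nm Multiplicative sinusoidal
#'   illumination shading (independent random phase per channel).
#' @param n_replicates Biological replicates the paths are spread over.
#' @return A scenario list for [gen_profiles()].
#' @export
profile_scenario <- function(n_paths = 200, path_length_px = 200,
                             pixel_size_nm = 120, baseline = 100,
                             compartment_rate_per_mm = 60,
                             enrichment_meanlog = log(1.9),
                             enrichment_sdlog = 0.15,
                             enrichment_min = 1.5,
                             length_px_range = c(8L, 16L),
                             snr = 10, poisson_share = 0.5,
                             shading_amplitude = 0.08,
                             shading_period_nm = 24000,
                             n_replicates = 4) {
  as.list(environment())
}

#' Generate synthetic two-channel profiles with planted compartments
#'
#' Builds baseline-1 mixed two-channel paths, plants non-overlapping
#' enrichment compartments as Poisson events with lognormal enrichment and
#' uniform length, applies multiplicative sinusoidal shading (independent
#' phase per channel) and Gaussian + shot (Poisson) noise, and returns the
#' ground-truth spans. Deterministic given `(scenario, seed)`.
#'
#' @param scenario A [profile_scenario()] list.
#' @param seed Integer seed.
#' @return List with `profiles` (list of [two_channel_profile()]) and
#'   `truth` (data frame of planted compartments: `path_id`,
#'   `enriched_channel`, `start_px`, `end_px`, `enrichment`; plus the
#'   scenario and seed as attributes).
#' @export
gen_profiles <- function(scenario = profile_scenario(), seed = 1) {
  s <- scenario
  set.seed(seed)
  if (s$length_px_range[2] > s$path_length_px) {
    stop("planted compartments cannot be longer than the path", call. = FALSE)
  }
  path_mm <- s$path_length_px * s$pixel_size_nm / 1e6
  profiles <- vector("list", s$n_paths)
  truth <- vector("list", s$n_paths)
  sd_total <- s$baseline / s$snr
  shot_var <- s$poisson_share * sd_total^2
  gain <- if (shot_var > 0) s$baseline / shot_var else 0
  gauss_sd <- sqrt((1 - s$poisson_share)) * sd_total
  for (i in seq_len(s$n_paths)) {
    pid <- sprintf("path%03d", i)
    rep_id <- sprintf("rep%d", ((i - 1L) %% s$n_replicates) + 1L)
    gfp <- rep(s$baseline, s$path_length_px)
    rfp <- rep(s$baseline, s$path_length_px)
    k <- stats::rpois(1, s$compartment_rate_per_mm * path_mm)
    spans <- plant_spans(k, s$path_length_px, s$length_px_range)
    tr <- NULL
    if (nrow(spans)) {
      for (j in seq_len(nrow(spans))) {
        enr <- exp(stats::rnorm(1, s$enrichment_meanlog, s$enrichment_sdlog))
        enr <- max(enr, s$enrichment_min)
        chan <- sample(c("RFP", "GFP"), 1L)
        px <- (spans$start[j] + 1L):spans$end[j]
        if (chan == "RFP") rfp[px] <- rfp[px] * enr else gfp[px] <- gfp[px] * enr
        tr <- rbind(tr, data.frame(path_id = pid, enriched_channel = chan,
                                   start_px = spans$start[j],
                                   end_px = spans$end[j], enrichment = enr))
      }
    }
    x_nm <- (seq_len(s$path_length_px) - 0.5) * s$pixel_size_nm
    noisy <- function(ch) {
      if (s$shading_amplitude > 0) {
        ch <- ch * (1 + s$shading_amplitude *
                      sin(2 * pi * x_nm / s$shading_period_nm +
                            stats::runif(1, 0, 2 * pi)))
      }
      if (gain > 0) ch <- stats::rpois(length(ch), ch * gain) / gain
      if (gauss_sd > 0) ch <- ch + stats::rnorm(length(ch), sd = gauss_sd)
      pmax(ch, 0)
    }
    profiles[[i]] <- two_channel_profile(noisy(gfp), noisy(rfp),
                                         pixel_size_nm = s$pixel_size_nm,
                                         path_id = pid,
                                         cell_id = sprintf("cell%03d", i),
                                         replicate_id = rep_id)
    truth[[i]] <- tr
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(path_id = character(), enriched_channel = character(),
                        start_px = integer(), end_px = integer(),
                        enrichment = numeric())
  }
  attr(truth, "seed") <- seed
  attr(truth, "scenario") <- s
  list(profiles = profiles, truth = truth)
}

# k non-overlapping [start, end) spans (0-based) with >= 1 px gap, by
# rejection; gives up on spans that no longer fit.
plant_spans <- function(k, path_len, length_range) {
  starts <- integer(0)
  ends <- integer(0)
  tries <- 0L
  while (k > 0L && tries < 200L) {
    len <- sample(length_range[1]:length_range[2], 1L)
    st <- sample(0:(path_len - len), 1L)
    en <- st + len
    if (all(en < starts - 1L | st > ends + 1L)) {
      starts <- c(starts, st)
      ends <- c(ends, en)
      k <- k - 1L
    }
    tries <- tries + 1L
  }
  o <- order(starts)
  data.frame(start = starts[o], end = ends[o])
}

#' Generate synthetic per-object intensity records
#'
#' Three-class mixture of compartment objects with bivariate lognormal
#' (TDP-43, mRNA) intensities: mRNA-rich/protein-rich stress granules,
#' mRNA-rich/protein-poor stress granules and mRNA-poor protein
#' condensates. Deterministic given `(scenario, seed)`.
#'
#' @param n_objects Number of objects.
#' @param proportions Length-3 numeric summing to 1 (rich SG, poor SG,
#'   condensate).
#' @param meanlog_high,meanlog_low Log-means of the high and low intensity
#'   modes; their separation in units of `sdlog` controls class overlap
#'   (the defaults give a 5-sigma separation).
#' @param sdlog Log-SD of both channels.
#' @param rho Within-object correlation of the two channels (|rho| < 1).
#' @param nucleus_fraction Fraction of objects labelled nuclear.
#' @param condition Condition label stamped on all records.
#' @param seed Integer seed.
#' @return List with `records` (object data frame) and `truth` (factor of
#'   planted class labels plus scenario attributes).
#' @export
gen_objects <- function(n_objects = 1000,
                        proportions = c(0.4, 0.3, 0.3),
                        meanlog_high = log(500),
                        meanlog_low = log(500) - 5 * 0.25,
                        sdlog = 0.25, rho = 0.2,
                        nucleus_fraction = 0.3,
                        condition = "wildtype", seed = 1) {
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0)) {
    stop("`proportions` must be non-negative and sum to 1", call. = FALSE)
  }
  if (abs(rho) >= 1 || sdlog <= 0) {
    stop("degenerate covariance: need |rho| < 1 and sdlog > 0", call. = FALSE)
  }
  set.seed(seed)
  cls <- sample(c("TDP43_RICH_SG", "TDP43_POOR_SG", "TDP43_CONDENSATE"),
                n_objects, replace = TRUE, prob = proportions)
  mu_tdp <- ifelse(cls == "TDP43_POOR_SG", meanlog_low, meanlog_high)
  mu_mrna <- ifelse(cls == "TDP43_CONDENSATE", meanlog_low, meanlog_high)
  z1 <- stats::rnorm(n_objects)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_objects)
  records <- data.frame(
    object_id = sprintf("obj%05d", seq_len(n_objects)),
    cell_id = sprintf("cell%03d", sample(ceiling(n_objects / 10),
                                         n_objects, replace = TRUE)),
    condition = condition,
    location = ifelse(stats::runif(n_objects) < nucleus_fraction,
                      "nucleus", "cytoplasm"),
    tdp_intensity = exp(mu_tdp + sdlog * z1),
    mrna_intensity = exp(mu_mrna + sdlog * z2),
    area_px = 1L + stats::rpois(n_objects, 25)
  )
  truth <- factor(cls, levels = c("TDP43_RICH_SG", "TDP43_POOR_SG",
                                  "TDP43_CONDENSATE", "UNCLASSIFIED"))
  attr(truth, "seed") <- seed
  list(records = records, truth = truth)
}

#' Generate synthetic per-cell nuclear/cytoplasmic intensities
#'
#' Nuclear means are lognormal; cytoplasmic means are
#' `slope * nuclear * (1 + noise)` with Gaussian multiplicative noise, so
#' the planted nucleo-cytoplasmic slope is recoverable by regression
#' through the origin. Deterministic given `(scenario, seed)`.
#'
#' @param n_cells Number of cells.
#' @param slope Planted slope (>= 0).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param meanlog,sdlog Nuclear intensity lognormal parameters.
#' @param condition Condition label.
#' @param seed Integer seed.
#' @return List with `cells` (data frame) and `truth` (planted slope,
#'   noise, seed).
#' @export
gen_cells <- function(n_cells = 150, slope = 0.6, noise_cv = 0.10,
                      meanlog = log(100), sdlog = 0.3,
                      condition = "wildtype", seed = 1) {
  if (slope < 0) stop("`slope` must be >= 0", call. = FALSE)
  set.seed(seed)
  nuc <- stats::rlnorm(n_cells, meanlog, sdlog)
  cyt <- pmax(slope * nuc * (1 + stats::rnorm(n_cells, sd = noise_cv)), 0)
  list(cells = data.frame(cell_id = sprintf("cell%03d", seq_len(n_cells)),
                          condition = condition,
                          nuclear_mean = nuc,
                          cytoplasmic_mean = cyt),
       truth = list(slope = slope, noise_cv = noise_cv, seed = seed))
}
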