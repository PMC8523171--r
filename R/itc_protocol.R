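#' Titration protocol geometry
#'
#' The physical set-up of an isothermal titration calorimetry run in which
#' the repeat oligonucleotide (the lattice) is injected from the syringe
#' into the protein-filled cell. Defaults reflect a typical small-cell
#' instrument run: 36 injections of 1 uL from a 120 uM oligonucleotide
#' syringe into a 200 uL cell holding 15 uM protein at 25 degrees C.
#'
#' @param cell_volume_ul Cell volume, uL.
#' @param injection_volumes_ul Vector of per-injection volumes, uL
#'   (>= 2 injections).
#' @param syringe_conc_um Syringe (lattice) concentration, uM.
#' @param cell_conc_um Cell (protein) concentration, uM.
#' @param temperature_c Temperature, degrees C (recorded, not used by the
#'   enthalpy-only heat model).
#' @return Object of class `"itc_protocol"`.
#' @export
itc_protocol <- function(cell_volume_ul = 200,
                         injection_volumes_ul = rep(1, 36),
                         syringe_conc_um = 120,
                         cell_conc_um = 15,
                         temperature_c = 25) {
  if (cell_volume_ul <= 0 || any(injection_volumes_ul <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  if (length(injection_volumes_ul) < 2L) {
    stop("a titration needs at least 2 injections", call. = FALSE)
  }
  if (syringe_conc_um <= 0 || cell_conc_um <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  structure(
    list(cell_volume_ul = cell_volume_ul,
         injection_volumes_ul = as.numeric(injection_volumes_ul),
         syringe_conc_um = syringe_conc_um,
         cell_conc_um = cell_conc_um,
         temperature_c = temperature_c),
    class = "itc_protocol"
  )
}

#' @export
print.itc_protocol <- function(x, ...) {
  cat(sprintf("<itc_protocol> %d injections (%.3g uL total), %g uM lattice into %g uL cell at %g uM protein, %g C\n",
              length(x$injection_volumes_ul), sum(x$injection_volumes_ul),
              x$syringe_conc_um, x$cell_volume_ul, x$cell_conc_um,
              x$temperature_c))
  invisible(x)
}

#' Per-injection heat record
#'
#' @param heats_ucal Per-injection heats, ucal (exothermic negative).
#' @param protocol The [itc_protocol()] the heats belong to; lengths must
#'   agree.
#' @return Object of class `"thermogram"` with `heats_ucal`,
#'   `normalized_kcal_mol` (heat per mole of injected lattice) and the
#'   protocol.
#' @export
thermogram <- function(heats_ucal, protocol) {
  stopifnot(inherits(protocol, "itc_protocol"))
  if (length(heats_ucal) != length(protocol$injection_volumes_ul)) {
    stop("`heats_ucal` length must equal the number of injections", call. = FALSE)
  }
  structure(
    list(heats_ucal = as.numeric(heats_ucal),
         normalized_kcal_mol = normalize_heats(heats_ucal, protocol),
         protocol = protocol),
    class = "thermogram"
  )
}

# ucal per injection -> kcal per mole of injectant:
# moles injected = v[uL] * 1e-6 L * c[uM] * 1e-6 M = v*c*1e-12 mol;
# q[ucal] = q*1e-9 kcal; ratio = q * 1e3 / (v * c).
normalize_heats <- function(heats_ucal, protocol) {
  heats_ucal * 1e3 /
    (protocol$injection_volumes_ul * protocol$syringe_conc_um)
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %d injections, total heat %.4g ucal\n",
              length(x$heats_ucal), sum(x$heats_ucal)))
  cat("  normalized (kcal/mol injectant), first/last:",
      sprintf("%.3g", x$normalized_kcal_mol[1]), "/",
      sprintf("%.3g", x$normalized_kcal_mol[length(x$normalized_kcal_mol)]), "\n")
  invisible(x)
}

# Injection-by-injection totals in the cell under the linear displacement
# approximation: existing contents scaled by (1 - v/V0), injectant added at
# (v/V0) * syringe concentration. Returns molar totals after each injection
# plus the per-injection dilution factors.
injection_schedule <- function(protocol) {
  v <- protocol$injection_volumes_ul
  V0 <- protocol$cell_volume_ul
  d <- 1 - v / V0
  n <- length(v)
  P <- numeric(n)
  R <- numeric(n)
  p_prev <- protocol$cell_conc_um * 1e-6
  r_prev <- 0
  for (k in seq_len(n)) {
    p_prev <- p_prev * d[k]
    r_prev <- r_prev * d[k] + (v[k] / V0) * protocol$syringe_conc_um * 1e-6
    P[k] <- p_prev
    R[k] <- r_prev
  }
  list(protein_m = P, rna_m = R, dilution = d)
}

# Deterministic expected per-injection heats (ucal) for a model under a
# protocol. The cell heat content after injection k is
# H_k = V0 * sum_j [complex_j] * cumsum(dh)_j ; the measured heat is the
# change net of the content displaced out of the cell:
# q_k = H_k - H_{k-1} * (1 - v_k/V0) + offset.
expected_heats <- function(model, protocol, dilution_offset_ucal = 0) {
  sched <- injection_schedule(protocol)
  p_free <- equilibrate_free(model, sched$protein_m, sched$rna_m)
  f <- species_distribution(model, p_free)
  if (is.null(dim(f))) f <- matrix(f, nrow = 1L)
  cum_dh <- c(0, cumsum(model$dh))
  V0_l <- protocol$cell_volume_ul * 1e-6
  # heat content in ucal: V0[L] * conc[M] * dH[kcal/mol] * 1e9 ucal/kcal
  H <- as.numeric((f * sched$rna_m) %*% cum_dh) * V0_l * 1e9
  H_prev <- c(0, H[-length(H)])
  H - H_prev * sched$dilution + dilution_offset_ucal
}

#' Simulate an ITC titration
#'
#' Generates per-injection heats for a sequential binding model under a
#' titration protocol. After each injection the cell totals follow the
#' linear displacement rule (contents scaled by `1 - v/V0`, injectant added
#' at `v/V0` times the syringe concentration), the cell is re-equilibrated,
#' and the measured heat is the change in cell heat content corrected for
#' the displaced volume, plus a constant per-injection dilution offset and
#' Gaussian noise.
#'
#' @param model A [binding_model()] (enthalpies in kcal/mol).
#' @param protocol An [itc_protocol()].
#' @param noise_sd_ucal Gaussian noise standard deviation, ucal (>= 0).
#' @param dilution_offset_ucal Constant per-injection dilution heat, ucal.
#' @param seed Optional integer seed for the noise.
#' @return A [thermogram()].
#' @examples
#' m <- binding_model(kd = c(4e-6, 31.25e-9), dh = c(-40, -40))
#' tg <- simulate_itc(m, itc_protocol(), noise_sd_ucal = 0)
#' @export
simulate_itc <- function(model, protocol, noise_sd_ucal = 0,
                         dilution_offset_ucal = 0, seed = NULL) {
  stopifnot(inherits(model, "binding_model"), inherits(protocol, "itc_protocol"))
  if (noise_sd_ucal < 0) stop("`noise_sd_ucal` must be >= 0", call. = FALSE)
  q <- expected_heats(model, protocol, dilution_offset_ucal)
  if (noise_sd_ucal > 0) {
    if (!is.null(seed)) set.seed(seed)
    q <- q + stats::rnorm(length(q), sd = noise_sd_ucal)
  }
  thermogram(q, protocol)
}
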