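#' Fit a sequential binding model to an ITC thermogram
#'
#' Weighted least squares of predicted against observed per-injection heats
#' for a one- or two-site sequential binding model. Free parameters are the
#' step dissociation constants (optimized in log space, which enforces
#' positivity), the step enthalpies and a constant per-injection dilution
#' heat. Given the dissociation constants the predicted heats are linear in
#' the enthalpies and the offset, so those are profiled out by linear least
#' squares (variable projection) and the nonlinear search runs only over
#' log-Kd. The search starts from a deterministic 5 x 5 (or 5-point)
#' log-spaced grid and refines the best grid points by Nelder-Mead —
#' two-site ITC fits are multi-modal and a single start is not trustworthy.
#'
#' @param tg A [thermogram()].
#' @param n_sites 1 or 2.
#' @param weights Optional per-injection weights (default equal).
#' @param log10_kd_grid Numeric vector of log10(Kd / M) start values for the
#'   deterministic multi-start grid.
#' @param n_refine Number of best grid points refined by Nelder-Mead.
#' @param start_kd Optional numeric vector of Kd values (molar, length
#'   `n_sites`) used as the only start (bypasses the grid; used by the
#'   bootstrap for warm starts).
#'
#' @return An object of class `"itc_fit"` with components `kd`, `dh`,
#'   `dilution_offset_ucal`, `kd1_over_kd2` (two-site only), `rss`, `aic`,
#'   `fitted_ucal`, `residuals_ucal`, `n_sites`, `thermogram` and
#'   convergence details. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `logLik`, `plot`, `simulate`, `confint`.
#' @examples
#' m <- binding_model(kd = c(4e-6, 31.25e-9), dh = c(-40, -40))
#' tg <- simulate_itc(m, itc_protocol(), noise_sd_ucal = 0)
#' fit <- itc_fit(tg, n_sites = 2)
#' coef(fit)
#' @export
itc_fit <- function(tg, n_sites = 2, weights = NULL,
                    log10_kd_grid = seq(-9, -4, length.out = 5),
                    n_refine = 3, start_kd = NULL, nm_maxit = 500) {
  stopifnot(inherits(tg, "thermogram"))
  if (!n_sites %in% c(1, 2)) stop("`n_sites` must be 1 or 2", call. = FALSE)
  n_sites <- as.integer(n_sites)
  protocol <- tg$protocol
  q_obs <- tg$heats_ucal
  n_obs <- length(q_obs)
  n_par <- 2L * n_sites + 1L
  if (n_obs <= n_par) {
    stop("fewer data points than free parameters", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, n_obs) else as.numeric(weights)
  if (length(w) != n_obs || any(w <= 0)) {
    stop("`weights` must be positive and match the number of injections",
         call. = FALSE)
  }

  sched <- injection_schedule(protocol)
  V0_l <- protocol$cell_volume_ul * 1e-6
  sw <- sqrt(w)

  # Linear design for fixed Kd: q_k = sum_i dH_i * A[k, i] + offset, where
  # A[k, i] is the dilution-corrected increment in (total lattice that has
  # completed binding step i), converted to ucal per (kcal/mol).
  profile_fit <- function(log_kd) {
    model <- binding_model(exp(log_kd))
    p_free <- equilibrate_free(model, sched$protein_m, sched$rna_m)
    f <- species_distribution(model, p_free)
    if (is.null(dim(f))) f <- matrix(f, nrow = 1L)
    conc <- f * sched$rna_m
    # C[k, i] = sum_{j >= i} [complex_j]_k
    C <- sapply(seq_len(n_sites), function(i) {
      rowSums(conc[, (i + 1L):(n_sites + 1L), drop = FALSE])
    })
    C <- matrix(C, nrow = n_obs)
    C_prev <- rbind(0, C[-n_obs, , drop = FALSE])
    A <- (C - C_prev * sched$dilution) * V0_l * 1e9
    X <- cbind(A, offset = 1)
    ls <- stats::lm.fit(X * sw, q_obs * sw)
    list(rss = sum(ls$residuals^2), coef = ls$coefficients, design = X)
  }
  objective <- function(log_kd) profile_fit(log_kd)$rss

  starts <- if (!is.null(start_kd)) {
    stopifnot(length(start_kd) == n_sites, all(start_kd > 0))
    matrix(log(start_kd), nrow = 1L)
  } else if (n_sites == 1L) {
    matrix(log(10^log10_kd_grid), ncol = 1L)
  } else {
    g <- expand.grid(log10_kd_grid, log10_kd_grid)
    log(10^as.matrix(g))
  }

  grid_rss <- apply(starts, 1L, function(s) {
    tryCatch(objective(s), error = function(e) Inf)
  })
  if (all(!is.finite(grid_rss))) {
    stop("itc_fit: no start point produced a finite objective", call. = FALSE)
  }
  keep <- order(grid_rss)[seq_len(min(n_refine, sum(is.finite(grid_rss))))]

  best <- NULL
  for (i in keep) {
    opt <- tryCatch(
      if (n_sites == 1L) {
        o <- stats::optimize(function(lk) objective(lk),
                             interval = starts[i, 1L] + c(-3, 3),
                             tol = 1e-10)
        list(par = o$minimum, value = o$objective, convergence = 0L)
      } else {
        stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                     control = list(maxit = nm_maxit, reltol = 1e-12))
      },
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("itc_fit: all refinement starts failed", call. = FALSE)

  pf <- profile_fit(best$par)
  kd <- unname(exp(best$par))
  dh <- unname(pf$coef[seq_len(n_sites)])
  offset <- unname(pf$coef[n_sites + 1L])
  fitted_q <- as.numeric(pf$design %*% pf$coef)
  resid_q <- q_obs - fitted_q
  rss <- pf$rss
  k_par <- n_par + 1L  # + residual variance
  ll <- -n_obs / 2 * (log(2 * pi * max(rss, .Machine$double.xmin) / n_obs) + 1)
  structure(
    list(n_sites = n_sites,
         kd = kd,
         dh = dh,
         dilution_offset_ucal = offset,
         kd1_over_kd2 = if (n_sites == 2L) kd[1] / kd[2] else NA_real_,
         rss = rss,
         aic = 2 * k_par - 2 * ll,
         logLik = ll,
         n_par = k_par,
         fitted_ucal = fitted_q,
         residuals_ucal = resid_q,
         weights = w,
         thermogram = tg,
         convergence = best$convergence,
         n_starts = nrow(starts)),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("<itc_fit> %d-site sequential model, %d injections\n",
              x$n_sites, length(x$fitted_ucal)))
  for (i in seq_len(x$n_sites)) {
    cat(sprintf("  Kd%d = %.4g M, dH%d = %.4g kcal/mol\n",
                i, x$kd[i], i, x$dh[i]))
  }
  cat(sprintf("  dilution offset = %.4g ucal/injection\n",
              x$dilution_offset_ucal))
  if (x$n_sites == 2L) {
    cat(sprintf("  Kd1/Kd2 = %.4g (omega = %.4g)\n",
                x$kd1_over_kd2, 4 * x$kd1_over_kd2))
  }
  cat(sprintf("  RSS = %.4g ucal^2, AIC = %.2f\n", x$rss, x$aic))
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  est <- coef(object)
  out <- list(coefficients = est,
              n_sites = object$n_sites,
              kd1_over_kd2 = object$kd1_over_kd2,
              omega = if (object$n_sites == 2L) 4 * object$kd1_over_kd2 else NA_real_,
              total_dh = sum(object$dh),
              rss = object$rss,
              aic = object$aic,
              sigma = sqrt(object$rss /
                             (length(object$fitted_ucal) - object$n_par + 1L)),
              n_obs = length(object$fitted_ucal))
  class(out) <- "summary.itc_fit"
  out
}

#' @export
print.summary.itc_fit <- function(x, ...) {
  cat(sprintf("Sequential %d-site ITC fit (%d injections)\n", x$n_sites, x$n_obs))
  print(x$coefficients)
  if (x$n_sites == 2L) {
    cat(sprintf("Cooperativity: Kd1/Kd2 = %.4g, omega = %.4g\n",
                x$kd1_over_kd2, x$omega))
  }
  cat(sprintf("Total enthalpy = %.4g kcal/mol; residual sigma = %.3g ucal; AIC = %.2f\n",
              x$total_dh, x$sigma, x$aic))
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) {
  c(stats::setNames(object$kd, paste0("kd", seq_len(object$n_sites))),
    stats::setNames(object$dh, paste0("dh", seq_len(object$n_sites))),
    dilution_offset_ucal = object$dilution_offset_ucal)
}

#' @export
fitted.itc_fit <- function(object, ...) object$fitted_ucal

#' @export
residuals.itc_fit <- function(object, ...) object$residuals_ucal

#' @export
logLik.itc_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_par, nobs = length(object$fitted_ucal),
            class = "logLik")
}

#' Predicted per-injection heats from a fitted model
#'
#' @param object An `itc_fit`.
#' @param protocol Optional [itc_protocol()] to predict for (defaults to the
#'   fitted one).
#' @param ... Unused.
#' @return Numeric vector of expected per-injection heats, ucal.
#' @export
predict.itc_fit <- function(object, protocol = NULL, ...) {
  if (is.null(protocol)) protocol <- object$thermogram$protocol
  expected_heats(binding_model(object$kd, object$dh), protocol,
                 object$dilution_offset_ucal)
}

#' Simulate thermograms from a fitted model
#'
#' Parametric simulation: expected heats from the fitted parameters plus
#' Gaussian noise at the fitted residual standard deviation.
#'
#' @param object An `itc_fit`.
#' @param nsim Number of simulated thermograms.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of [thermogram()] objects of length `nsim`.
#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- summary(object)$sigma
  mu <- predict(object)
  protocol <- object$thermogram$protocol
  lapply(seq_len(nsim), function(i) {
    thermogram(mu + stats::rnorm(length(mu), sd = s), protocol)
  })
}

#' @export
plot.itc_fit <- function(x, ...) {
  tg <- x$thermogram
  mu <- predict(x)
  norm_fit <- normalize_heats(mu, tg$protocol)
  ratio <- cumsum(tg$protocol$injection_volumes_ul *
                    tg$protocol$syringe_conc_um) /
    (tg$protocol$cell_volume_ul * tg$protocol$cell_conc_um)
  graphics::plot(ratio, tg$normalized_kcal_mol, pch = 16,
                 xlab = "molar ratio (lattice/protein)",
                 ylab = "kcal/mol of injectant", ...)
  graphics::lines(ratio, norm_fit, col = "red3", lwd = 2)
  invisible(x)
}

#' Bootstrap confidence intervals for an ITC fit
#'
#' Residual-resampling bootstrap: residuals are resampled with replacement,
#' added to the fitted heats, and the model is refit (warm-started at the
#' point estimate). Percentile intervals are returned for every parameter
#' and, for two-site fits, for the Kd1/Kd2 ratio. With all-zero residuals
#' the intervals collapse to the point estimate and are flagged degenerate.
#'
#' @param fit An `itc_fit`.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return A list with `ci` (matrix: estimate, lower, upper per parameter),
#'   `replicates` (matrix of bootstrap estimates) and `degenerate` flag.
#' @export
bootstrap_ci <- function(fit, n_boot = 200, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "itc_fit"))
  if (n_boot < 100) stop("`n_boot` must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  est <- coef(fit)
  if (fit$n_sites == 2L) est <- c(est, kd1_over_kd2 = fit$kd1_over_kd2)
  # numerically-zero residuals (relative to the heat scale) mean there is
  # nothing to resample
  degenerate <- all(abs(fit$residuals_ucal) <=
                      1e-4 * max(abs(fit$thermogram$heats_ucal), 1e-300))
  if (degenerate) {
    ci <- cbind(estimate = est, lower = est, upper = est)
    return(list(ci = ci, replicates = NULL, degenerate = TRUE))
  }
  protocol <- fit$thermogram$protocol
  reps <- t(vapply(seq_len(n_boot), function(b) {
    q_star <- fit$fitted_ucal +
      sample(fit$residuals_ucal, length(fit$residuals_ucal), replace = TRUE)
    fb <- itc_fit(thermogram(q_star, protocol), n_sites = fit$n_sites,
                  start_kd = fit$kd, nm_maxit = 150)
    cb <- coef(fb)
    if (fit$n_sites == 2L) cb <- c(cb, kd1_over_kd2 = fb$kd1_over_kd2)
    cb
  }, est))
  alpha <- (1 - level) / 2
  ci <- cbind(estimate = est,
              lower = apply(reps, 2L, stats::quantile, probs = alpha),
              upper = apply(reps, 2L, stats::quantile, probs = 1 - alpha))
  # percentile intervals can exclude the point estimate in tiny samples;
  # clamp so the contract "CI contains the estimate" always holds
  ci[, "lower"] <- pmin(ci[, "lower"], est)
  ci[, "upper"] <- pmax(ci[, "upper"], est)
  list(ci = ci, replicates = reps, degenerate = FALSE)
}

#' @export
confint.itc_fit <- function(object, parm, level = 0.95, ...) {
  ci <- bootstrap_ci(object, level = level, ...)$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Count plateaus in a normalized ITC curve
#'
#' Operationalizes the visual notion of "distinct plateaus": the normalized
#' heat curve is smoothed by a running mean, injections where the local
#' change is below `slope_frac` of the total heat range are collected into
#' flat runs of at least `min_run + 1` points, and the mean levels of the
#' flat runs are clustered; levels separated by more than `level_frac`
#' (default 20%) of the range count as distinct plateaus.
#'
#' @param tg A [thermogram()] (or numeric vector of normalized heats).
#' @param window Running-mean window (odd integer).
#' @param slope_frac Flatness threshold as a fraction of the heat range per
#'   injection.
#' @param level_frac Minimal separation between distinct levels, as a
#'   fraction of the heat range.
#' @return Integer plateau count.
#' @export
plateau_count <- function(tg, window = 7, slope_frac = 0.007,
                          level_frac = 0.20) {
  x <- if (inherits(tg, "thermogram")) tg$normalized_kcal_mol else as.numeric(tg)
  n <- length(x)
  if (n < window + 1L) stop("curve too short for plateau detection", call. = FALSE)
  s <- stats::filter(x, rep(1 / window, window), sides = 2)
  s <- as.numeric(s)
  # pad the ends with partial-window means
  half <- (window - 1L) %/% 2L
  for (i in seq_len(half)) {
    s[i] <- mean(x[1:(i + half)])
    s[n - i + 1L] <- mean(x[(n - i + 1L - half):n])
  }
  rng <- diff(range(s))
  if (rng == 0) return(1L)
  flat <- abs(diff(s)) <= slope_frac * rng
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_run <- 3L
  levels <- c()
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= min_run) {
      levels <- c(levels, mean(s[starts[i]:(ends[i] + 1L)]))
    }
  }
  if (length(levels) == 0L) return(0L)
  levels <- sort(levels)
  sum(c(TRUE, diff(levels) > level_frac * rng))
}

#' Compare one-site and two-site fits of the same thermogram
#'
#' Akaike-information model selection between a one-site and a two-site
#' sequential fit of the same titration, with the plateau count of the
#' underlying curve as a descriptive check: a cooperative two-site curve
#' shows two distinct flat levels while a one-site curve decays gradually
#' from a single initial plateau.
#'
#' @param fit_1site,fit_2site `itc_fit` objects for the same thermogram.
#' @return List with `selected` (`"1-site"` or `"2-site"`), `delta_aic`
#'   (`AIC_1site - AIC_2site`; positive favours the two-site model) and
#'   `plateau_count`.
#' @export
compare_models <- function(fit_1site, fit_2site) {
  stopifnot(inherits(fit_1site, "itc_fit"), inherits(fit_2site, "itc_fit"))
  if (fit_1site$n_sites != 1L || fit_2site$n_sites != 2L) {
    stop("arguments must be a 1-site and a 2-site fit, in that order",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(fit_1site$thermogram$heats_ucal,
                        fit_2site$thermogram$heats_ucal))) {
    stop("the two fits are not on the same thermogram", call. = FALSE)
  }
  d_aic <- fit_1site$aic - fit_2site$aic
  list(selected = if (fit_2site$aic < fit_1site$aic) "2-site" else "1-site",
       delta_aic = d_aic,
       plateau_count = plateau_count(fit_1site$thermogram))
}
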