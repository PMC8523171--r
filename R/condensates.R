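#' Classify cellular compartments by TDP-43 and mRNA content
#'
#' Two-channel intensity gating of detected objects into the three classes
#' seen after stress: mRNA-rich/protein-rich stress granules
#' (`TDP43_RICH_SG`), mRNA-rich/protein-poor stress granules
#' (`TDP43_POOR_SG`) and mRNA-poor protein condensates (`TDP43_CONDENSATE`);
#' objects below both thresholds are `UNCLASSIFIED`. Thresholds can be given
#' directly or derived automatically as a quantile (default the 75th
#' percentile) of a reference condition, which makes the gating invariant
#' to a common rescaling of intensities.
#'
#' @param records Data frame with columns `object_id`, `cell_id`,
#'   `condition`, `location` (`"nucleus"`/`"cytoplasm"`), `tdp_intensity`,
#'   `mrna_intensity`, `area_px`.
#' @param tdp_threshold,mrna_threshold Positive numbers, or `"auto"`.
#' @param reference_condition Condition whose intensities anchor the auto
#'   thresholds (default the first condition present).
#' @param auto_quantile Quantile used for auto thresholds.
#' @return List with `classes` (factor per object, levels
#'   `TDP43_RICH_SG`, `TDP43_POOR_SG`, `TDP43_CONDENSATE`, `UNCLASSIFIED`),
#'   `counts` (condition x class table) and `thresholds` (the values used).
#' @export
classify_objects <- function(records, tdp_threshold = "auto",
                             mrna_threshold = "auto",
                             reference_condition = NULL,
                             auto_quantile = 0.75) {
  records <- validate_objects(records)
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  if (is.null(reference_condition)) {
    reference_condition <- records$condition[1L]
  }
  ref <- records[records$condition == reference_condition, ]
  if (nrow(ref) == 0L) stop("reference condition not present", call. = FALSE)
  resolve <- function(thr, channel) {
    if (identical(thr, "auto")) {
      stats::quantile(ref[[channel]], auto_quantile, names = FALSE)
    } else {
      if (!is.numeric(thr) || thr <= 0) {
        stop("thresholds must be positive or \"auto\"", call. = FALSE)
      }
      thr
    }
  }
  t_t <- resolve(tdp_threshold, "tdp_intensity")
  t_m <- resolve(mrna_threshold, "mrna_intensity")
  hi_t <- records$tdp_intensity >= t_t
  hi_m <- records$mrna_intensity >= t_m
  lab <- ifelse(hi_m & hi_t, "TDP43_RICH_SG",
                ifelse(hi_m, "TDP43_POOR_SG",
                       ifelse(hi_t, "TDP43_CONDENSATE", "UNCLASSIFIED")))
  classes <- factor(lab, levels = c("TDP43_RICH_SG", "TDP43_POOR_SG",
                                    "TDP43_CONDENSATE", "UNCLASSIFIED"))
  list(classes = classes,
       counts = table(condition = records$condition, class = classes),
       thresholds = c(tdp = t_t, mrna = t_m))
}

validate_objects <- function(records) {
  required <- c("object_id", "cell_id", "condition", "location",
                "tdp_intensity", "mrna_intensity", "area_px")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("`records` lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$tdp_intensity < 0) || any(records$mrna_intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (any(records$area_px < 1)) stop("`area_px` must be >= 1", call. = FALSE)
  bad <- !records$location %in% c("nucleus", "cytoplasm")
  if (any(bad)) stop("`location` must be 'nucleus' or 'cytoplasm'", call. = FALSE)
  records
}

#' Per-group intensity summaries with condition comparisons
#'
#' Median, quartiles and n per group (violin-plot style summaries), plus
#' Welch and, when a pairing variable is supplied, paired t-tests between
#' named condition pairs. Zero-variance comparisons are flagged degenerate
#' instead of erroring: two identical groups report `t = 0, p = 1`, and a
#' constant shift between zero-variance groups reports `p = 0`.
#'
#' @param records Object data frame (see [classify_objects()]).
#' @param value Column to summarize (default `"tdp_intensity"`).
#' @param group_keys Character vector of grouping columns.
#' @param compare Optional list of length-2 character vectors naming
#'   condition pairs to test.
#' @param pairing Optional column name identifying paired replicates; when
#'   present, paired t-tests are used for pairs with complete pairing.
#' @return List with `summary` (data frame: group, n, q25, median, q75,
#'   mean, sd) and `tests` (data frame of comparisons, or NULL).
#' @export
intensity_summary <- function(records, value = "tdp_intensity",
                              group_keys = "condition", compare = NULL,
                              pairing = NULL) {
  if (!all(group_keys %in% names(records))) {
    stop("grouping keys not all present", call. = FALSE)
  }
  if (!value %in% names(records)) stop("value column not present", call. = FALSE)
  key <- interaction(records[group_keys], drop = TRUE, sep = "/")
  v <- records[[value]]
  sm <- do.call(rbind, lapply(levels(key), function(g) {
    x <- v[key == g]
    data.frame(group = g, n = length(x),
               q25 = stats::quantile(x, 0.25, names = FALSE),
               median = stats::median(x),
               q75 = stats::quantile(x, 0.75, names = FALSE),
               mean = mean(x), sd = stats::sd(x))
  }))
  tests <- NULL
  if (!is.null(compare)) {
    tests <- do.call(rbind, lapply(compare, function(pair) {
      xa <- v[records$condition == pair[1]]
      xb <- v[records$condition == pair[2]]
      if (length(xa) < 2L || length(xb) < 2L) {
        return(data.frame(a = pair[1], b = pair[2], method = "skipped",
                          statistic = NA_real_, p_value = NA_real_,
                          degenerate = TRUE))
      }
      paired_ok <- !is.null(pairing) && pairing %in% names(records) &&
        length(xa) == length(xb)
      degen <- stats::sd(xa) == 0 && stats::sd(xb) == 0
      if (degen) {
        same <- length(xa) == length(xb) && all(sort(xa) == sort(xb))
        return(data.frame(a = pair[1], b = pair[2], method = "degenerate",
                          statistic = if (same) 0 else Inf,
                          p_value = if (same) 1 else 0, degenerate = TRUE))
      }
      tt <- stats::t.test(xa, xb, paired = paired_ok)
      data.frame(a = pair[1], b = pair[2],
                 method = if (paired_ok) "paired t" else "Welch t",
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, degenerate = FALSE)
    }))
  }
  list(summary = sm, tests = tests)
}

#' Nucleo-cytoplasmic distribution slope
#'
#' Least-squares slope through the origin of cytoplasmic versus nuclear
#' mean TDP-43 intensity across cells of one condition:
#' `b = sum(nuclear * cytoplasmic) / sum(nuclear^2)`. A reduced slope
#' indicates nuclear retention of the protein. A free-intercept ordinary
#' regression is available via `intercept = TRUE`. The confidence interval
#' is a percentile bootstrap over cells.
#'
#' @param cells Data frame with columns `cell_id`, `condition`,
#'   `nuclear_mean`, `cytoplasmic_mean` (>= 3 cells).
#' @param intercept Fit a free intercept instead of forcing the origin.
#' @param n_boot Bootstrap replicates for the CI (0 disables).
#' @param level Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return List with `slope`, `intercept` (0 unless requested), `ci`
#'   (length-2 vector or NULL) and `n_cells`.
#' @export
nucleocytoplasmic_slope <- function(cells, intercept = FALSE, n_boot = 500,
                                    level = 0.95, seed = NULL) {
  required <- c("cell_id", "condition", "nuclear_mean", "cytoplasmic_mean")
  if (!all(required %in% names(cells))) {
    stop("`cells` lacks required columns", call. = FALSE)
  }
  if (nrow(cells) < 3L) stop("need at least 3 cells", call. = FALSE)
  if (any(cells$nuclear_mean < 0) || any(cells$cytoplasmic_mean < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (all(cells$nuclear_mean == 0)) {
    stop("all nuclear means are zero; slope undefined", call. = FALSE)
  }
  est <- function(d) {
    if (intercept) {
      unname(stats::coef(stats::lm(cytoplasmic_mean ~ nuclear_mean, data = d)))
    } else {
      c(0, sum(d$nuclear_mean * d$cytoplasmic_mean) / sum(d$nuclear_mean^2))
    }
  }
  co <- est(cells)
  ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    bs <- replicate(n_boot, {
      d <- cells[sample(nrow(cells), replace = TRUE), ]
      if (all(d$nuclear_mean == 0)) NA_real_ else est(d)[2L]
    })
    alpha <- (1 - level) / 2
    ci <- stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  }
  list(slope = co[2L], intercept = co[1L], ci = ci, n_cells = nrow(cells))
}
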