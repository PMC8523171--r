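make_records <- function(tdp, mrna, condition = "wildtype") {
  n <- length(tdp)
  data.frame(object_id = sprintf("o%03d", seq_len(n)),
             cell_id = sprintf("c%03d", (seq_len(n) - 1) %/% 5 + 1),
             condition = condition,
             location = rep(c("cytoplasm", "nucleus"), length.out = n),
             tdp_intensity = tdp, mrna_intensity = mrna,
             area_px = 10L)
}

test_that("the two-channel gate maps intensities to the expected classes", {
  t_t <- 100; t_m <- 200
  rec <- make_records(tdp = c(200, 0, 200, 50),
                      mrna = c(400, 400, 50, 50))
  cl <- classify_objects(rec, t_t, t_m)
  expect_equal(as.character(cl$classes),
               c("TDP43_RICH_SG", "TDP43_POOR_SG", "TDP43_CONDENSATE",
                 "UNCLASSIFIED"))
  expect_equal(sum(cl$counts), nrow(rec))
  expect_equal(unname(cl$thresholds), c(t_t, t_m))
  expect_error(classify_objects(rec[0, ], t_t, t_m), "empty")
  expect_error(classify_objects(rec, -1, t_m), "positive")
})

test_that("every object gets exactly one class and counts partition n", {
  g <- gen_objects(n_objects = 500, seed = 8)
  cl <- classify_objects(g$records)
  expect_false(anyNA(cl$classes))
  expect_length(cl$classes, 500)
  expect_equal(sum(cl$counts), 500)
})

test_that("auto-quantile gating is invariant to a common intensity rescale", {
  g <- gen_objects(n_objects = 400, seed = 3)
  cl1 <- classify_objects(g$records)
  rec2 <- g$records
  rec2$tdp_intensity <- rec2$tdp_intensity * 1000
  rec2$mrna_intensity <- rec2$mrna_intensity * 1000
  cl2 <- classify_objects(rec2)
  expect_identical(cl1$classes, cl2$classes)
})

test_that("well-separated synthetic mixtures are recovered at >= 98%", {
  g <- gen_objects(n_objects = 1000, seed = 42)  # 5-sigma class separation
  # gate at the geometric midpoint of the two modes
  mid <- exp((log(500) + log(500) - 5 * 0.25) / 2)
  cl <- classify_objects(g$records, mid, mid)
  expect_gte(mean(as.character(cl$classes) == as.character(g$truth)), 0.98)
})

test_that("intensity summaries report quartiles and guarded t-tests", {
  rec <- make_records(tdp = c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15),
                      mrna = rep(1, 10),
                      condition = rep(c("a", "b"), each = 5))
  out <- intensity_summary(rec, compare = list(c("a", "b")))
  expect_equal(out$summary$median, c(3, 13))
  expect_equal(out$summary$n, c(5, 5))
  expect_equal(out$tests$method, "Welch t")
  expect_lt(out$tests$p_value, 0.01)

  # identical groups: degenerate, t = 0 and p = 1
  same <- make_records(tdp = rep(c(7, 7, 7), 2), mrna = rep(1, 6),
                       condition = rep(c("a", "b"), each = 3))
  t_same <- intensity_summary(same, compare = list(c("a", "b")))$tests
  expect_true(t_same$degenerate)
  expect_equal(t_same$statistic, 0)
  expect_equal(t_same$p_value, 1)

  # constant shift with zero variance: flagged, p -> 0
  shift <- make_records(tdp = c(rep(7, 3), rep(9, 3)), mrna = rep(1, 6),
                        condition = rep(c("a", "b"), each = 3))
  t_shift <- intensity_summary(shift, compare = list(c("a", "b")))$tests
  expect_true(t_shift$degenerate)
  expect_equal(t_shift$p_value, 0)

  # undersized group: test skipped, not errored
  tiny <- make_records(tdp = c(1, 2, 3), mrna = rep(1, 3),
                       condition = c("a", "a", "b"))
  expect_equal(intensity_summary(tiny, compare = list(c("a", "b")))$tests$method,
               "skipped")
})

test_that("a simulated 1-SD shift at n = 50 is detected in >= 95% of trials", {
  set.seed(17)
  hits <- replicate(200, {
    rec <- make_records(tdp = c(rnorm(50, 10, 2), rnorm(50, 12, 2)),
                        mrna = rep(1, 100),
                        condition = rep(c("a", "b"), each = 50))
    intensity_summary(rec, compare = list(c("a", "b")))$tests$p_value < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the nucleo-cytoplasmic slope has its closed-form limits", {
  cells <- data.frame(cell_id = sprintf("c%d", 1:10), condition = "wt",
                      nuclear_mean = seq(10, 100, by = 10),
                      cytoplasmic_mean = seq(10, 100, by = 10))
  expect_equal(nucleocytoplasmic_slope(cells, n_boot = 0)$slope, 1)
  cells0 <- cells; cells0$cytoplasmic_mean <- 0
  expect_equal(nucleocytoplasmic_slope(cells0, n_boot = 0)$slope, 0)
  badnuc <- cells; badnuc$nuclear_mean <- 0
  expect_error(nucleocytoplasmic_slope(badnuc, n_boot = 0), "nuclear")
  expect_error(nucleocytoplasmic_slope(cells[1:2, ], n_boot = 0), "3 cells")
})

test_that("slope estimation is scale-equivariant and matches lm through the origin", {
  g <- gen_cells(n_cells = 80, slope = 0.6, seed = 4)
  fit <- nucleocytoplasmic_slope(g$cells, n_boot = 200, seed = 1)
  lm_ref <- unname(coef(lm(cytoplasmic_mean ~ 0 + nuclear_mean,
                           data = g$cells)))
  expect_equal(fit$slope, lm_ref, tolerance = 1e-12)
  expect_true(fit$ci[1] <= fit$slope && fit$slope <= fit$ci[2])
  scaled <- g$cells
  scaled$cytoplasmic_mean <- scaled$cytoplasmic_mean * 3
  expect_equal(nucleocytoplasmic_slope(scaled, n_boot = 0)$slope, 3 * fit$slope,
               tolerance = 1e-12)
  # free-intercept variant is available
  fi <- nucleocytoplasmic_slope(g$cells, intercept = TRUE, n_boot = 0)
  expect_equal(fi$slope,
               unname(coef(lm(cytoplasmic_mean ~ nuclear_mean,
                              data = g$cells))[2]), tolerance = 1e-12)
})

test_that("the planted slope is recovered from noisy synthetic cells", {
  errs <- vapply(1:20, function(s) {
    g <- gen_cells(n_cells = 150, slope = 0.6, noise_cv = 0.10, seed = s)
    nucleocytoplasmic_slope(g$cells, n_boot = 0)$slope - 0.6
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 0.02), 0.9)
  # noise-free generation gives the slope back exactly
  g0 <- gen_cells(n_cells = 50, slope = 0.6, noise_cv = 0, seed = 2)
  expect_equal(nucleocytoplasmic_slope(g0$cells, n_boot = 0)$slope, 0.6,
               tolerance = 1e-12)
})
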