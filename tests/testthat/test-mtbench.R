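flat_profile <- function(n = 100, level = 100, pixel = 120) {
  two_channel_profile(rep(level, n), rep(level, n), pixel_size_nm = pixel)
}

# boxcar enrichment of the RFP channel over pixels (start+1)..end (1-based)
boxcar_profile <- function(n = 100, start = 40, len = 10, enr = 1.3,
                           level = 100) {
  rfp <- rep(level, n)
  rfp[(start + 1):(start + len)] <- level * enr
  two_channel_profile(rep(level, n), rfp)
}

test_that("the band-pass suppresses shading-scale structure and can be disabled", {
  n <- 256
  x_nm <- (seq_len(n) - 0.5) * 120
  params <- detection_params(shading_period_nm = 4800,
                             smoothing_period_nm = 480)
  # sinusoid slower than the shading cutoff is removed almost entirely
  slow <- 100 + 50 * sin(2 * pi * x_nm / 10240)
  pf <- two_channel_profile(slow, rep(100, n))
  out <- preprocess_profile(pf, params)
  amp_in <- diff(range(slow))
  amp_out <- diff(range(out$intensity_gfp + mean(slow)))
  expect_lt(amp_out / amp_in, 0.01)

  # disabled filters with a zero background quantile are the identity
  ident <- detection_params(shading_period_nm = Inf, smoothing_period_nm = 0,
                            background_quantile = 0)
  sig <- c(rep(0, 10), abs(sin(seq_len(90))))  # min is exactly 0
  pf2 <- two_channel_profile(sig, sig + 1)
  out2 <- preprocess_profile(pf2, ident)
  expect_equal(out2$intensity_gfp, sig, tolerance = 1e-12)

  # white noise loses variance to the smoothing cut
  set.seed(5)
  for (rep in 1:50) {
    noise <- 100 + rnorm(n, sd = 10)
    pf3 <- two_channel_profile(noise, rep(100, n))
    out3 <- preprocess_profile(pf3, params)
    expect_lt(stats::var(out3$intensity_gfp), stats::var(noise))
  }
})

test_that("preprocessing rejects profiles shorter than the filter support", {
  pf <- two_channel_profile(rep(100, 10), rep(100, 10))  # 1.2 um path
  expect_error(preprocess_profile(pf, detection_params(shading_period_nm = 4800)),
               "shorter")
})

test_that("the ratio track is scale-free and channel-symmetric", {
  pf <- boxcar_profile()
  r <- ratio_track(pf)
  # proportional channels sit exactly at baseline 1
  prop <- two_channel_profile(pf$intensity_rfp * 3.7, pf$intensity_rfp)
  expect_equal(ratio_track(prop), rep(1, 100))
  # swapping channels inverts the track pointwise
  swapped <- two_channel_profile(pf$intensity_rfp, pf$intensity_gfp)
  expect_equal(ratio_track(swapped), 1 / r, tolerance = 1e-12)
  expect_error(ratio_track(two_channel_profile(rep(0, 10), rep(1, 10))),
               "zero")
})

test_that("a planted step reads out at its planted enrichment", {
  pf <- boxcar_profile(enr = 1.3, start = 40, len = 10)
  r <- ratio_track(pf)
  inside <- r[42:49]
  outside <- r[c(1:40, 51:100)]
  expect_equal(unique(round(inside / outside[1], 10)), 1.3)
})

test_that("compartment detection applies the 20%/720 nm rule literally", {
  params <- detection_params()
  base <- rep(1, 100)
  expect_equal(nrow(detect_compartments(base, params)), 0L)

  r10 <- base; r10[41:50] <- 1.3
  calls <- detect_compartments(r10, params)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$enriched_channel, "RFP")
  expect_equal(c(calls$start_px, calls$end_px), c(40L, 50L))
  expect_equal(calls$length_nm, 1200)
  expect_equal(calls$enrichment, 1.3)

  r5 <- base; r5[41:45] <- 1.3     # 600 nm: below the length rule
  expect_equal(nrow(detect_compartments(r5, params)), 0L)
  r6 <- base; r6[41:46] <- 1.3     # 720 nm exactly: kept
  expect_equal(nrow(detect_compartments(r6, params)), 1L)
  rlow <- base; rlow[41:60] <- 1.15  # below the 20% threshold
  expect_equal(nrow(detect_compartments(rlow, params)), 0L)
  redge <- base; redge[41:60] <- 1.2  # exactly 20%: inclusive
  expect_equal(nrow(detect_compartments(redge, params)), 1L)

  # GFP enrichment is the reciprocal side of the same rule
  g <- base; g[21:30] <- 1 / 1.4
  gcalls <- detect_compartments(g, params)
  expect_equal(gcalls$enriched_channel, "GFP")
  expect_equal(gcalls$enrichment, 1.4)
})

test_that("detection is invariant to channel scaling and symmetric under swap", {
  pf <- boxcar_profile(enr = 1.5, start = 30, len = 12)
  calls <- call_profile(pf, preprocess = "none")
  scaled <- two_channel_profile(pf$intensity_gfp * 0.01,
                                pf$intensity_rfp * 250)
  calls_scaled <- call_profile(scaled, preprocess = "none")
  expect_equal(calls_scaled$start_px, calls$start_px)
  expect_equal(calls_scaled$enrichment, calls$enrichment, tolerance = 1e-10)

  swapped <- two_channel_profile(pf$intensity_rfp, pf$intensity_gfp)
  calls_sw <- call_profile(swapped, preprocess = "none")
  expect_equal(calls_sw$start_px, calls$start_px)
  expect_equal(calls_sw$end_px, calls$end_px)
  expect_equal(calls_sw$enrichment, calls$enrichment, tolerance = 1e-10)
  expect_equal(calls_sw$enriched_channel,
               ifelse(calls$enriched_channel == "RFP", "GFP", "RFP"))
})

test_that("condition summaries count, pool and rescale per 0.5 mm", {
  profiles <- list(boxcar_profile(n = 1042), boxcar_profile(n = 1041))
  # ~0.25 mm total path at 120 nm/px
  calls <- do.call(rbind, lapply(profiles, call_profile, preprocess = "none"))
  sm <- summarize_condition(calls, profiles, "demo")
  expect_equal(sm$n_compartments, 2L)
  expect_equal(sm$total_length_nm, (1042 + 1041) * 120)
  expect_equal(sm$n_per_reference_length, 2 * 5e5 / sm$total_length_nm)
  # mean-centered ratio reads a hair below the planted 1.3 because the
  # compartment itself lifts the channel mean
  expect_equal(sm$enrichment_values, c(1.3, 1.3), tolerance = 0.01)
  empty <- summarize_condition(call_profile(flat_profile(), preprocess = "none"),
                               list(flat_profile()), "flat")
  expect_equal(empty$n_compartments, 0L)
  expect_length(empty$enrichment_values, 0L)
  expect_error(summarize_condition(calls, list(), "none"), "at least one")
})

test_that("KS statistic hits its boundary cases", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p_value, 1)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  expect_error(ks_two_sample(numeric(), 1:3), "non-empty")
})

test_that("exact KS p-values match full permutation enumeration", {
  set.seed(13)
  for (sizes in list(c(5, 5), c(3, 7), c(4, 6), c(6, 7), c(2, 5))) {
    a <- rnorm(sizes[1])
    b <- rnorm(sizes[2], mean = 0.8)
    got <- ks_two_sample(a, b, method = "exact")
    oracle <- ks_permutation_oracle(a, b)
    expect_equal(got$statistic, oracle$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, oracle$p_value, tolerance = 1e-12)
  }
  # asymptotic branch engages when enumeration is infeasible
  big <- ks_two_sample(rnorm(5), rnorm(600), method = "auto")
  expect_equal(big$method, "asymptotic")
  expect_error(ks_two_sample(rnorm(5), rnorm(600), method = "exact"),
               "not feasible")
})
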