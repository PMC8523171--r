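test_that("binding polynomial matches hand-computed values", {
  m <- binding_model(kd = c(1e-6, 1e-6))
  expect_equal(binding_polynomial(m, 0)$Z, 1)
  # beta1 p = beta2 p^2 = 1 at p = Kd = 1 uM
  expect_equal(binding_polynomial(m, 1e-6)$Z, 3)
  expect_error(binding_model(kd = c(1e-6, -1)), "positive")
})

test_that("species fractions match hand-computed distributions", {
  m <- binding_model(kd = c(1e-6, 1e-6))
  expect_equal(unname(species_distribution(m, 0)), c(1, 0, 0))
  expect_equal(unname(species_distribution(m, 1e-6)), rep(1 / 3, 3))
  # two identical independent sites half occupied -> binomial(2, 1/2)
  mi <- binding_model_intrinsic(k = 2e-6, omega = 1)
  expect_equal(unname(species_distribution(mi, 2e-6)), c(0.25, 0.5, 0.25),
               tolerance = 1e-12)
})

test_that("macroscopic species fractions equal brute-force microstate enumeration", {
  set.seed(11)
  for (rep in 1:250) {
    n <- sample(2:4, 1)
    k <- 10^runif(1, -8, -5)
    omega <- 10^runif(1, -1.5, 2.5)
    p <- 10^runif(1, -9, -4)
    m <- binding_model(macroscopic_kd(n, k, omega))
    f_macro <- unname(species_distribution(m, p))
    f_micro <- microstate_fractions(n, k, omega, p)
    expect_equal(f_macro, f_micro, tolerance = 1e-10)
    expect_equal(sum(f_macro), 1, tolerance = 1e-12)
  }
})

test_that("equilibrate handles the degenerate totals exactly", {
  m <- binding_model(kd = c(1e-6, 1e-6))
  expect_equal(equilibrate(m, 1e-5, 0)$protein_free, 1e-5)
  st <- equilibrate(m, 0, 1e-5)
  expect_equal(st$protein_free, 0)
  expect_equal(st$complex_conc, c(1e-5, 0, 0))
})

test_that("equilibrate agrees with the closed-form cubic root", {
  m <- binding_model(kd = c(1e-6, 1e-6))
  st <- equilibrate(m, 1e-5, 1e-5)
  expect_equal(st$protein_free, cubic_protein_free(1e-6, 1e-6, 1e-5, 1e-5),
               tolerance = 1e-9)
  set.seed(7)
  for (rep in 1:50) {
    kd <- 10^runif(2, -9, -4)
    P <- 10^runif(1, -7, -4)
    R <- 10^runif(1, -7, -4)
    st <- equilibrate(binding_model(kd), P, R)
    expect_equal(st$protein_free, cubic_protein_free(kd[1], kd[2], P, R),
                 tolerance = 1e-8)
  }
})

test_that("equilibrate conserves protein and lattice to 1e-9 relative", {
  set.seed(21)
  for (rep in 1:1000) {
    n <- sample(1:4, 1)
    m <- binding_model(10^runif(n, -9, -4))
    P <- 10^runif(1, -8, -3)
    R <- 10^runif(1, -8, -3)
    st <- equilibrate(m, P, R)
    bound <- sum(seq_len(n) * st$complex_conc[-1L])
    expect_equal(st$protein_free + bound, P, tolerance = 1e-9)
    expect_equal(sum(st$complex_conc), R, tolerance = 1e-9)
    expect_true(all(st$complex_conc >= 0) && st$protein_free >= 0)
  }
})

test_that("free protein is monotone in the totals", {
  m <- binding_model(kd = c(2e-6, 5e-7))
  P_grid <- seq(1e-6, 3e-5, length.out = 20)
  p_up <- vapply(P_grid, function(P) equilibrate(m, P, 1e-5)$protein_free,
                 numeric(1))
  expect_true(all(diff(p_up) > 0))
  R_grid <- seq(0, 3e-5, length.out = 20)
  p_down <- vapply(R_grid, function(R) equilibrate(m, 1.5e-5, R)$protein_free,
                   numeric(1))
  expect_true(all(diff(p_down) < 0))
})

test_that("cooperativity ratio and omega follow the statistical-factor convention", {
  expect_equal(cooperativity_ratio(binding_model(c(1, 4)))$ratio, 0.25)
  expect_equal(cooperativity_ratio(binding_model(c(1, 4)))$omega, 1)
  expect_equal(cooperativity_ratio(binding_model(c(1e-6, 1e-6)))$omega, 4)
  # omega = 4 * ratio applied to the tandem-RRM reference ratio
  expect_equal(cooperativity_ratio(binding_model(c(128, 1)))$omega, 512)
  # identical independent sites give omega exactly 1 for any intrinsic k
  for (k in 10^seq(-9, -4)) {
    expect_equal(cooperativity_ratio(binding_model_intrinsic(k, 1))$omega, 1)
  }
  expect_error(cooperativity_ratio(binding_model(1e-6)), "two-site")
})

test_that("discreteness index separates all-or-none from binomial filling", {
  R <- 1e-9  # trace lattice: protein_free tracks protein_total
  series <- 10^seq(-9, -3, length.out = 400)
  ind <- occupancy_titration(binding_model_intrinsic(1e-6, 1), series, R)
  expect_equal(ind$discreteness_index, 0.5, tolerance = 1e-3)
  allornone <- occupancy_titration(binding_model(c(1e-6, 1e-12)), series, R)
  expect_gt(allornone$discreteness_index, 0.99)
  # matched overall affinity sqrt(Kd1 Kd2): strong cooperativity is more discrete
  coop <- occupancy_titration(binding_model(c(4e-6, 31.25e-9)), series, R)
  matched <- occupancy_titration(
    binding_model_intrinsic(sqrt(4e-6 * 31.25e-9) * 2, 1), series, R)
  expect_gt(coop$discreteness_index, matched$discreteness_index)
  expect_error(occupancy_titration(binding_model(1e-6), c(2e-6, 1e-6), R),
               "increasing")
})

test_that("equilibration is invariant to consistent unit rescaling", {
  st_m <- equilibrate(binding_model(c(2e-6, 5e-7)), 1.5e-5, 1e-5)
  st_um <- equilibrate(binding_model(c(2, 0.5)), 15, 10)  # everything in uM
  expect_equal(st_um$protein_free * 1e-6, st_m$protein_free, tolerance = 1e-9)
  expect_equal(st_um$complex_conc * 1e-6, st_m$complex_conc, tolerance = 1e-9)
})
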