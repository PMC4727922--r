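# Deterministic layer: occupancy, thresholds, steady state, regimes,
# omega rescaling.

test_that("promoter occupancy follows the cooperative binding isotherm", {
  p <- fig2_params()
  expect_identical(tf_occupancy(0, p), 0)
  expect_gt(tf_occupancy(1e6, p), 1 - 1e-12)
  # direct arithmetic: f = 30, h = 5, k_out/k_in = 63300
  expect_equal(tf_occupancy(30, p), 30^5 / (30^5 + 63300), tolerance = 1e-12)
  expect_equal(tf_occupancy(30, p), 0.9974, tolerance = 1e-4)
  # strictly increasing
  f <- seq(0, 50, by = 0.5)
  expect_true(all(diff(tf_occupancy(f, p)) > 0))
  expect_error(tf_occupancy(-1, p), "must be >= 0")
})

test_that("occupancy inversion is exact and round-trips", {
  p <- fig2_params()
  # half-saturation symmetry
  expect_equal(occupancy_inverse(0.5, p), 63300^(1 / 5), tolerance = 1e-12)
  # closed-form inversion at the promoter-saturation convention
  expect_equal(occupancy_inverse(0.99, p), (0.99 / 0.01 * 63300)^(1 / 5),
               tolerance = 1e-12)
  expect_equal(occupancy_inverse(0.99, p), 22.9, tolerance = 1e-2)
  # round trip across the working range
  f <- c(0.1, 1, 5, 12, 22.9, 30, 100)
  expect_equal(occupancy_inverse(tf_occupancy(f, p), p), f,
               tolerance = 1e-8)
  expect_error(occupancy_inverse(1.2, p), "must lie in")
  expect_error(occupancy_inverse(-0.1, p), "must lie in")
})

test_that("repression thresholds match the closed form", {
  p <- fig2_params()
  # direct arithmetic on the threshold formula with the fig2 rates
  expect_equal(mirna_threshold(p, 1),
               (0.1 / 0.002) * (1 + 5e-4 / (0.5 + 3e-4)), tolerance = 1e-12)
  expect_equal(mirna_threshold(p, 1), 50.05, tolerance = 1e-4)
  expect_equal(mirna_threshold(p, 2),
               (0.1 / 0.001) * (1 + 1e-3 / (1 + 4e-4)), tolerance = 1e-12)
  expect_equal(mirna_threshold(p, 2), 100.1, tolerance = 1e-4)
  # no dissociation: threshold reduces to d/k+
  p0 <- decoupled_params()
  p0$kplus1 <- 0.002
  expect_equal(mirna_threshold(p0, 1), 0.1 / 0.002)
  # decoupled ceRNA: infinite threshold sentinel
  expect_identical(mirna_threshold(decoupled_params(), 2), Inf)
})

test_that("sigmoidal gain hits its landmark points and decreases", {
  p <- fig2_params()
  mu0 <- mirna_threshold(p, 1)
  expect_equal(cerna_gain(0, p, 1), 1)
  expect_equal(cerna_gain(mu0, p, 1), 0.5)
  expect_equal(cerna_gain(9 * mu0, p, 1), 0.1)
  mu <- seq(0, 500, by = 5)
  expect_true(all(diff(cerna_gain(mu, p, 1)) < 0))
  expect_error(cerna_gain(-1, p, 1), "must be >= 0")
})

test_that("steady state reduces to birth-death laws when decoupled", {
  p <- decoupled_params(b1 = 100, b2 = 80, beta = 50)
  ss <- steady_state(p, c(0.5, 0.25, 0.8))
  expect_equal(ss$m1, 100 * 0.5 / 0.1)
  expect_equal(ss$m2, 80 * 0.25 / 0.1)
  expect_equal(ss$mu, 50 * 0.8 / 0.1)
  expect_equal(ss$c1, 0)
  expect_equal(ss$c2, 0)
  # no repressor: free ceRNA levels, zero miRNA
  p2 <- fig2_params()
  p2$beta <- 0
  ss2 <- steady_state(p2, c(0.5, 0.71, 0.9))
  expect_equal(ss2$mu, 0)
  expect_equal(ss2$m1, 120 * 0.5 / 0.1)
  expect_equal(ss2$m2, 100 * 0.71 / 0.1)
})

test_that("steady state is self-consistent on varied parameter draws", {
  set.seed(11)
  p <- fig2_params()
  for (rep in 1:20) {
    q <- p
    q$b1 <- runif(1, 10, 200); q$b2 <- runif(1, 10, 200)
    q$beta <- runif(1, 10, 200)
    q$kplus1 <- exp(runif(1, -8, 2)); q$kplus2 <- exp(runif(1, -8, 2))
    q$kappa1 <- exp(runif(1, -6, 2)); q$kappa2 <- exp(runif(1, -6, 2))
    n <- runif(3, 0.05, 0.99)
    ss <- steady_state(q, n)
    # substitute back into the stationary conditions
    expect_equal(ss$m1 * (q$d1 + q$kplus1 * ss$mu),
                 q$b1 * n[1] + q$kminus1 * ss$c1, tolerance = 1e-7)
    expect_equal(ss$m2 * (q$d2 + q$kplus2 * ss$mu),
                 q$b2 * n[2] + q$kminus2 * ss$c2, tolerance = 1e-7)
    expect_equal(ss$mu * (q$delta + q$kplus1 * ss$m1 + q$kplus2 * ss$m2),
                 q$beta * n[3] + (q$kminus1 + q$kappa1) * ss$c1 +
                   (q$kminus2 + q$kappa2) * ss$c2, tolerance = 1e-7)
    expect_equal(ss$c1 * (q$sigma1 + q$kminus1 + q$kappa1),
                 q$kplus1 * ss$mu * ss$m1, tolerance = 1e-7)
    # the sigmoidal-gain closed form agrees with the solved state
    expect_equal(ss$m1, q$b1 * n[1] / q$d1 * cerna_gain(ss$mu, q, 1),
                 tolerance = 1e-7)
    expect_true(all(as.numeric(ss) >= 0))
  }
})

test_that("cross-talk is positive and repression monotone", {
  p <- fig2_params()
  f1 <- seq(0, 30, length.out = 25)
  m2 <- vapply(f1, function(f)
    steady_state(p, c(tf_occupancy(f, p), 0.71, 0.9))$m2, numeric(1))
  mu <- vapply(f1, function(f)
    steady_state(p, c(tf_occupancy(f, p), 0.71, 0.9))$mu, numeric(1))
  expect_true(all(diff(m2) >= -1e-9))  # target derepressed by the competitor
  expect_true(all(diff(mu) <= 1e-9))   # free miRNA pool titrated away
  # target decreases as the miRNA transcription rate grows
  m2_beta <- vapply(seq(10, 300, length.out = 15), function(b) {
    q <- p; q$beta <- b
    steady_state(q, c(0.5, 0.71, 0.9))$m2
  }, numeric(1))
  expect_true(all(diff(m2_beta) < 0))
})

test_that("regime classification respects the ratio band", {
  expect_identical(classify_regime(0, 100), "free")
  expect_identical(classify_regime(100, 100), "susceptible")
  expect_identical(classify_regime(100 * 100, 100), "repressed")
  # configurable band
  expect_identical(classify_regime(5, 100, ratio_band = 10), "free")
  expect_identical(classify_regime(5, 100, ratio_band = 30), "susceptible")
})

test_that("omega rescaling acts only on delta and the binding rates", {
  p <- cerna_preset("fig9", "mirna")$params
  expect_identical(rescale_omega(p, 1), p)
  q <- rescale_omega(p, 0.5)
  expect_equal(q$delta, p$delta / 2)
  expect_equal(q$kplus1, p$kplus1 / 2)
  expect_equal(q$kplus2, p$kplus2 / 2)
  same <- setdiff(names(p), c("delta", "kplus1", "kplus2"))
  expect_identical(q[same], p[same])
  expect_error(rescale_omega(p, 0), "positive")
  expect_error(rescale_omega(p, -1), "positive")
})

test_that("the mean response is omega-invariant when return fluxes are small", {
  pre <- cerna_preset("fig9", "mirna")
  f1 <- c(0, 2, 5, 10, 15, 22.9)
  m2_ref <- vapply(f1, function(f)
    steady_state(pre$params,
                 c(tf_occupancy(f, pre$params), 0.99, 0.99))$m2, numeric(1))
  for (om in c(0.1, 10)) {
    q <- rescale_omega(pre$params, om)
    for (i in seq_along(f1)) {
      ss <- steady_state(q, c(tf_occupancy(f1[i], q), 0.99, 0.99))
      n <- ss$occupancy
      # verify the two smallness conditions actually hold here
      expect_lt(q$kminus2 * ss$c2, 0.01 * q$b2 * n["n2"])
      expect_lt((q$kminus1 + q$kappa1) * ss$c1 +
                  (q$kminus2 + q$kappa2) * ss$c2,
                0.01 * q$beta * n["nmu"])
      expect_equal(ss$m2, m2_ref[i], tolerance = 0.01)
    }
  }
})

test_that("parameter configs round-trip through JSON and YAML", {
  p <- fig2_params()
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_params(p, path)
    q <- read_params(path)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
    unlink(path)
  }
  expect_error(read_params(tempfile(fileext = ".txt")), "not found")
})
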