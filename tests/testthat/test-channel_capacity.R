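# Small-noise Gaussian capacity machinery against closed forms.

test_that("a constant-noise linear channel has the analytic capacity", {
  a <- 12; s2 <- 25; fr <- c(2, 10)
  f <- seq(fr[1], fr[2], length.out = 60)
  cv <- synthetic_curve(f, a * f, rep(s2, length(f)))
  oi <- optimal_input(cv)
  Z_exact <- a * diff(fr) / sqrt(2 * pi * exp(1) * s2)
  expect_equal(attr(oi, "Z"), Z_exact, tolerance = 1e-6)
  expect_equal(channel_capacity(oi), log2(Z_exact), tolerance = 1e-6)
  # the optimal input is uniform
  expect_lt(diff(range(oi$density)) / mean(oi$density), 1e-6)
  expect_equal(sum(oi$density[-1] * diff(oi$f)), 1, tolerance = 1e-3)
})

test_that("a Poissonian channel matches the closed-form limit", {
  # variance = mean, monotone response: Z has a closed form by change of
  # variables, which poisson_limit_capacity() encodes
  f <- seq(0.5, 20, length.out = 120)
  m <- 40 + 30 * f  # spans [55, 640]
  cv <- synthetic_curve(f, m, m)
  I_quad <- channel_capacity(optimal_input(cv))
  I_exact <- poisson_limit_capacity(min(m), max(m))
  expect_equal(I_quad, I_exact, tolerance = 1e-3)
  # also against the explicit integral expression
  expect_equal(I_exact,
               log2(2 / sqrt(2 * pi * exp(1)) * (sqrt(640) - sqrt(55))),
               tolerance = 1e-12)
})

test_that("capacity is clamped at one distinguishable level", {
  expect_equal(channel_capacity(1), 0)
  expect_equal(channel_capacity(4), 2)
  expect_equal(channel_capacity(0.5), 0)
  expect_error(channel_capacity(-1))
  # closed-form zero of the Poisson limit at m_max = 2*pi*e/4
  expect_equal(poisson_limit_capacity(0, 2 * pi * exp(1) / 4), 0,
               tolerance = 1e-12)
  expect_gt(poisson_limit_capacity(0, 2 * pi * exp(1) / 4 + 1), 0)
  expect_error(poisson_limit_capacity(5, 5), "m_min < m_max")
})

test_that("a flat response transmits nothing", {
  f <- seq(1, 10, length.out = 30)
  cv <- synthetic_curve(f, rep(100, 30), rep(100, 30))
  expect_warning(oi <- optimal_input(cv), "flat response")
  expect_equal(attr(oi, "Z"), 0)
  expect_equal(channel_capacity(oi), 0)
})

test_that("deterministic response curves refuse the Gaussian machinery", {
  rc <- response_curve(cerna_preset("fig2"), estimator = "deterministic",
                       n_points = 12)
  expect_error(optimal_input(rc), "positive response variance")
})

test_that("semi-analytic mutual information converges to log2 Z", {
  # log2 Z is the small-noise approximation of the capacity; the exact
  # Gaussian-channel MI under p_opt sits slightly above it and the gap
  # closes as the noise shrinks
  f <- seq(1, 9, length.out = 50)
  m <- 50 * f
  gap <- vapply(c(400, 25, 1), function(s2) {
    cv <- synthetic_curve(f, m, rep(s2, 50))
    oi <- optimal_input(cv)
    mutual_information(cv, oi) - log2(attr(oi, "Z"))
  }, numeric(1))
  expect_true(all(diff(gap) < 0))      # gap shrinks with the noise
  expect_lt(abs(gap[2]), 0.05)
  expect_lt(abs(gap[3]), 0.02)         # small-noise consistency
})

test_that("histogram plug-in MI recovers limiting cases", {
  set.seed(31)
  # independence
  f <- runif(4000, 0, 10)
  m <- rnorm(4000, 50, 5)
  # the plug-in estimator is biased upward by ~(cells)/(2 N ln 2)
  expect_lt(mutual_information(f, m), 0.15)
  # deterministic bijection over 4 equiprobable levels
  lv <- sample(1:4, 4000, replace = TRUE)
  expect_equal(mutual_information(lv + 0.0, lv * 10 + 0.0), 2,
               tolerance = 0.01)
  expect_error(mutual_information(numeric(0), numeric(0)), "non-empty")
  expect_error(mutual_information(rep(1, 5), 1:5), "distinct input")
})

test_that("a compressed response at equal noise carries less information", {
  f <- seq(0, 10, length.out = 80)
  s2 <- rep(49, 80)
  direct <- synthetic_curve(f, 100 + 40 * f, s2)
  # same endpoints squeezed through a shallow sigmoid: smaller slope over
  # most of the range at identical output noise
  squash <- synthetic_curve(f, 100 + 400 * plogis((f - 5) / 2.5), s2)
  I_direct <- channel_capacity(optimal_input(direct))
  I_squash <- channel_capacity(optimal_input(squash))
  expect_lt(I_squash, I_direct)
})

test_that("quadrature is stable under input-grid doubling", {
  prem <- cerna_preset("fig9", "mirna")
  pret <- cerna_preset("fig9", "tf")
  z1 <- attr(optimal_input(response_curve(prem, n_points = 50)), "Z")
  z2 <- attr(optimal_input(response_curve(prem, n_points = 100)), "Z")
  expect_lt(abs(z2 - z1) / z1, 0.005)
})

test_that("matched-output reconstruction spans the requested range", {
  pt <- cerna_preset("fig9", "tf")$params
  nr <- match_tf_input_range(pt, c(11.5, 200))
  expect_equal(pt$b2 * nr[1] / pt$d2, 11.5, tolerance = 1e-9)
  expect_equal(pt$b2 * nr[2] / pt$d2, 200, tolerance = 1e-9)
  # unreachable upper target is clamped below promoter saturation
  nr2 <- match_tf_input_range(pt, c(11.5, 1e5))
  expect_lt(nr2[2], 1)
  expect_error(match_tf_input_range(pt, c(1e5, 2e5)), "not reachable")
})

test_that("channel comparison wires curves, inputs and capacities together", {
  cc <- compare_channels(cerna_preset("fig9", "mirna"),
                         cerna_preset("fig9", "tf"), n_points = 30)
  expect_s3_class(cc, "cerna_capacity")
  expect_equal(cc$dI, cc$I_tf - cc$I_mirna)
  expect_gt(cc$I_tf, 0)
  expect_gt(cc$I_mirna, 0)
  # identical decoupled channels are symmetric
  pd <- decoupled_params()
  mir <- list(params = pd, channel = "mirna",
              fixed = c(n2 = 0.5, nmu = 0), input_n_range = c(0, 0.99))
  tfc <- list(params = pd, channel = "tf",
              fixed = c(n1 = 0.5, nmu = 0), input_n_range = c(0, 0.99))
  # the miRNA channel is disconnected without binding: flat curve
  rc <- response_curve(pd, channel = "mirna", fixed = c(n2 = 0.5, nmu = 0),
                       n_points = 20)
  expect_lt(diff(range(rc$m2)), 1e-8)
  # while the direct channel sees the full Hill response
  rt <- response_curve(pd, channel = "tf", fixed = c(n1 = 0.5, nmu = 0),
                       n_points = 20)
  expect_equal(rt$m2, pd$b2 * rt$n / pd$d2, tolerance = 1e-8)
})

test_that("capacity summaries export as JSON", {
  cc <- compare_channels(cerna_preset("fig9", "mirna"),
                         cerna_preset("fig9", "tf"), n_points = 25)
  path <- tempfile(fileext = ".json")
  export_capacity_json(cc, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$I_tf_bits, cc$I_tf, tolerance = 1e-12)
  expect_equal(j$aov_mirna, cc$aov_mirna, tolerance = 1e-12)
  unlink(path)
})
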