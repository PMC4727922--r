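# Exact stochastic simulation: reaction bookkeeping, reproducibility,
# stationary statistics against closed-form birth-death laws.

test_that("the reaction system encodes the 14 mass-action channels", {
  p <- fig2_params()
  rs <- reaction_system(p, c(0.5, 0.71, 0.9))
  expect_identical(nrow(rs$stoich), 14L)
  expect_identical(ncol(rs$stoich), 5L)
  # synthesis propensities are the frozen-occupancy constants
  a0 <- rs$propensity(c(0, 0, 0, 0, 0))
  expect_equal(unname(a0[1:3]), c(120 * 0.5, 100 * 0.71, 100 * 0.9))
  expect_true(all(a0[4:14] == 0))
  # mass-action association propensity at (m1 = 2, mu = 3)
  a <- rs$propensity(c(2, 0, 3, 0, 0))
  expect_equal(unname(a[7]), 0.002 * 3 * 2)
  # catalytic decay returns the miRNA, stoichiometric decay does not
  expect_identical(unname(rs$stoich["cat_1", ]), c(0, 0, 1, -1, 0))
  expect_identical(unname(rs$stoich["stoich_1", ]), c(0, 0, 0, -1, 0))
  # the association/dissociation pair moves (m, mu) <-> c
  expect_identical(unname(rs$stoich["assoc_1", ]), c(-1, 0, -1, 1, 0))
  expect_identical(unname(rs$stoich["dissoc_2", ]), c(0, 1, 1, 0, -1))
})

test_that("decoupling zeroes the association channels", {
  rs <- reaction_system(decoupled_params(), c(0.5, 0.5, 0.5))
  a <- rs$propensity(c(10, 10, 10, 0, 0))
  expect_equal(unname(a[7:8]), c(0, 0))
})

test_that("trajectories are reproducible and structurally valid", {
  p <- fig2_params()
  rs <- reaction_system(p, c(0.5, 0.71, 0.9))
  t1 <- simulate_ssa(rs, t_end = 30, seed = 7)
  t2 <- simulate_ssa(rs, t_end = 30, seed = 7)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$states, t2$states)
  t3 <- simulate_ssa(rs, t_end = 30, seed = 8)
  expect_false(identical(t1$times, t3$times))
  # strictly increasing event times, non-negative integer states
  expect_true(all(diff(t1$times) > 0))
  expect_true(all(t1$states >= 0))
  # consecutive states differ by exactly the fired reaction's stoichiometry
  jumps <- diff(t1$states)
  expect_true(all(jumps == rs$stoich[t1$reaction, ]))
})

test_that("an empty system with no synthesis is absorbing", {
  p <- decoupled_params(b1 = 0, b2 = 0, beta = 0)
  rs <- reaction_system(p, c(0, 0, 0))
  tr <- simulate_ssa(rs, t_end = 100, seed = 1,
                     initial = c(0, 0, 0, 0, 0))
  expect_identical(nrow(tr$states), 1L)
  st <- stationary_stats(tr, burn_in = 0)
  expect_equal(st$mean, rep(0, 5))
  expect_equal(st$var, rep(0, 5))
  expect_true(all(is.na(st$fano)))
})

test_that("time-weighted statistics handle degenerate paths", {
  p <- decoupled_params(b1 = 0, b2 = 0, beta = 0)
  rs <- reaction_system(p, c(0, 0, 0))
  tr <- simulate_ssa(rs, t_end = 10, seed = 1, initial = c(4, 0, 0, 0, 0))
  # only decay events of m1; wait: b=0 so m1 decays to 0 then absorbs
  st <- stationary_stats(tr, burn_in = 0)
  expect_true(all(st$var >= 0))
  expect_error(stationary_stats(tr, burn_in = 1e6), "smaller than")
})

test_that("birth-death reduction matches the Poisson stationary law", {
  # decoupled target: synthesis 99/min, decay 0.1/min -> Poisson(990)
  p <- decoupled_params(b1 = 0, b2 = 100, beta = 0)
  rs <- reaction_system(p, c(0, 0.99, 0))
  reps <- 4
  means <- fanos <- numeric(reps)
  ev <- 0
  for (r in seq_len(reps)) {
    mom <- cernacap:::ssa_moments(rs, t_end = 4000, seed = 100 + r,
                                  burn_in = 200)
    means[r] <- mom$mean["m2"]
    fanos[r] <- mom$cov["m2", "m2"] / mom$mean["m2"]
    ev <- ev + mom$n_events
  }
  expect_gt(ev, 1e6)
  se_mean <- sd(means) / sqrt(reps)
  se_fano <- sd(fanos) / sqrt(reps)
  expect_lt(abs(mean(means) - 990), 3 * se_mean + 1e-9)
  expect_lt(abs(mean(fanos) - 1), 3 * se_fano + 1e-9)
})

test_that("the empirical stationary law of a birth-death species is Poisson", {
  # chi-square goodness of fit on near-independent strided samples,
  # Bonferroni over the three decoupled species
  p <- decoupled_params(b1 = 30, b2 = 50, beta = 20)
  rs <- reaction_system(p, c(0.5, 0.5, 0.5))  # means 150, 250, 100
  tr <- simulate_ssa(rs, t_end = 30000, seed = 42, max_events = 5e6)
  stride <- seq(200, tr$t_final, by = 60)  # ~6 relaxation times apart
  idx <- findInterval(stride, tr$times)
  alpha <- 0.01 / 3
  for (sp in c("m1", "m2", "mu")) {
    xs <- tr$states[idx, sp]
    lam <- mean(xs)
    # bin into intervals with expected counts >= 5
    qs <- unique(qpois(seq(0, 1, length.out = 12), lam))
    br <- c(-0.5, qs[-c(1, length(qs))] + 0.5, Inf)
    obs <- table(cut(xs, br))
    pr <- diff(ppois(c(-1, qs[-c(1, length(qs))], Inf), lam))
    chi <- sum((as.numeric(obs) - length(xs) * pr)^2 / (length(xs) * pr))
    pval <- pchisq(chi, df = length(obs) - 2, lower.tail = FALSE)
    expect_gt(pval, alpha)
  }
})

test_that("moment scans pool replicates and respect the master seed", {
  p <- fig2_params()
  fg <- c(5, 12)
  s1 <- moment_scan(p, "mirna", fg, fixed = c(n2 = 0.71, nmu = 0.9),
                    replicates = 2, seed = 5, t_end = 300, burn_in = 50)
  s2 <- moment_scan(p, "mirna", fg, fixed = c(n2 = 0.71, nmu = 0.9),
                    replicates = 2, seed = 5, t_end = 300, burn_in = 50)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 4L)  # 2 grid points x 2 species
  expect_true(all(c("mean", "se_mean", "var", "fano") %in% names(s1)))
  # decoupled channel carries no signal: flat mean in f1
  pd <- decoupled_params()
  sd_ <- moment_scan(pd, "mirna", c(1, 20), fixed = c(n2 = 0.5, nmu = 0.5),
                     replicates = 3, seed = 9, t_end = 2000, burn_in = 200)
  m2 <- sd_[sd_$species == "m2", ]
  expect_lt(abs(m2$mean[1] - m2$mean[2]),
            3 * sqrt(m2$se_mean[1]^2 + m2$se_mean[2]^2) + 1e-9)
})

test_that("trajectories export to tidy CSV", {
  p <- fig2_params()
  rs <- reaction_system(p, c(0.5, 0.71, 0.9))
  tr <- simulate_ssa(rs, t_end = 5, seed = 3)
  path <- tempfile(fileext = ".csv")
  export_csv(tr, path)
  df <- read.csv(path)
  expect_identical(names(df), c("time", "m1", "m2", "mu", "c1", "c2"))
  expect_identical(nrow(df), length(tr$times))
  unlink(path)
})
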