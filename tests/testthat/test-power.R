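mu1 <- c(400, 450, 500)

test_that("fixed-noncentrality power: null case and planning-table cells", {
  expect_equal(power_ncf(2, 44, 0, 0.05), 0.05, tolerance = 1e-12)
  expect_equal(power_ncf(3, 10, 0, 0.10), 0.10, tolerance = 1e-12)
  d2_48 <- effect_size_delta2(mu1, 7500)
  d2_15 <- effect_size_delta2(mu1, 1900)
  expect_equal(round(power_ncf(2, 44, 48 * d2_48, 0.05), 4), 0.8136)
  expect_equal(round(power_ncf(2, 11, 15 * d2_15, 0.05), 4), 0.8108)
  expect_error(power_ncf(0, 10, 1), "design too small")
})

test_that("Beta-mixture power: degenerate cases and convergence reporting", {
  p0 <- power_exact_mixture(2, 20, 0, P = 1, alpha = 0.05)
  expect_equal(as.numeric(p0), 0.05, tolerance = 1e-12)
  p <- power_exact_mixture(2, 59, 10.6, P = 1, alpha = 0.05)
  expect_true(as.numeric(p) > 0.05 && as.numeric(p) < 1)
  expect_true(attr(p, "nodes") >= 256)
  expect_error(power_exact_mixture(2, 20, -1, 1), "nonnegative")
  expect_error(power_exact_mixture(2, 20, 1, 1, nodes = 8), "at least 16")
})

test_that("quadrature agrees with a Monte-Carlo Beta average on random tuples", {
  set.seed(42)
  for (i in 1:5) {
    c_ <- sample(1:3, 1); nu <- sample(10:80, 1); P <- sample(1:8, 1)
    Gamma <- runif(1, 0.5, 25); alpha <- runif(1, 0.01, 0.1)
    q <- as.numeric(power_exact_mixture(c_, nu, Gamma, P, alpha))
    b <- rbeta(2e5, (nu + 1) / 2, P / 2)
    mc <- mean(power_ncf(c_, nu, Gamma * b, alpha))
    expect_equal(q, mc, tolerance = 2e-3)
  }
})

test_that("exact ANCOVA power reproduces the published table cells", {
  e_99 <- ancova_effect(mu1, 9900)
  e_75 <- ancova_effect(mu1, 7500)
  e_19 <- ancova_effect(mu1, 1900)
  # converged value 0.811559 sits on the fourth-decimal rounding boundary;
  # asserted to within one unit in the fourth decimal
  expect_equal(power_ancova(ancova_design(21, G = 3, P = 1), e_99, "exact")$power,
               0.8115, tolerance = 1e-4)
  expect_equal(round(power_ancova(ancova_design(16, G = 3, P = 1), e_75,
                                  "exact")$power, 4), 0.8042)
  expect_equal(round(power_ancova(ancova_design(6, G = 3, P = 1), e_19,
                                  "exact")$power, 4), 0.8751)
  # depression-intervention worked example
  e6 <- ancova_effect(c(7.5366, 11.9849, 13.9785), 29.0898)
  expect_equal(round(power_ancova(ancova_design(10, G = 3, P = 1), e6,
                                  "exact")$power, 4), 0.6145)
})

test_that("approximate ANCOVA power matches the fixed-noncentrality values", {
  expect_equal(round(power_ancova(ancova_design(16, G = 3, P = 1),
                                  ancova_effect(mu1, 7500), "approx")$power, 4),
               0.8136)
  expect_equal(round(power_ancova(ancova_design(5, G = 3, P = 1),
                                  ancova_effect(mu1, 1900), "approx")$power, 4),
               0.8108)
  # null effect: power collapses to alpha
  p0 <- power_ancova(ancova_design(8, G = 3, P = 1),
                     ancova_effect(c(5, 5, 5), 10), "approx")
  expect_equal(p0$power, 0.05, tolerance = 1e-12)
})

test_that("ANOVA reference power matches published cells and the rho = 0 identity", {
  expect_equal(round(power_anova(63, 3, effect_size_delta2(mu1, 7500),
                                 rho = 0.5)$power, 4), 0.8148)
  expect_equal(round(power_anova(96, 3, effect_size_delta2(c(410, 450, 490), 9900),
                                 rho = 0.1)$power, 4), 0.8119)
  # at rho = 0 the noncentrality equals Lambda_A; only df2 differs
  d2 <- effect_size_delta2(mu1, 7500)
  pa <- power_anova(48, 3, d2, rho = 0)
  expect_equal(pa$noncentrality, 48 * d2)
  expect_equal(pa$df2, 45)
  expect_equal(pa$power, power_ncf(2, 45, 48 * d2, 0.05))
  expect_error(power_anova(48, 3, d2, rho = 1), "correlation")
})

test_that("exact power is strictly below approximate power for positive effects", {
  set.seed(9)
  checked <- 0
  while (checked < 12) {
    G <- sample(2:5, 1); P <- sample(1:8, 1); n <- sample(5:30, 1)
    mu <- rnorm(G, 0, 2); if (max(mu) - min(mu) < 0.5) mu[1] <- mu[1] + 2
    e <- ancova_effect(mu, runif(1, 0.5, 5))
    d <- ancova_design(n, G = G, P = P)
    # keep the noncentrality in the unsaturated range where the gap is visible
    if (d$N_T * e$gamma2 <= 1 || d$N_T * e$gamma2 > 25) next
    checked <- checked + 1
    pe <- power_ancova(d, e, "exact")$power
    pa <- power_ancova(d, e, "approx")$power
    expect_true(pa - pe > 1e-6)
  }
})

test_that("power increases with sample size and effect size, toward 1", {
  e <- ancova_effect(mu1, 7500)
  for (m in c("exact", "approx")) {
    pw <- sapply(c(5, 10, 20, 40), function(n)
      power_ancova(ancova_design(n, G = 3, P = 1), e, m)$power)
    expect_true(all(diff(pw) > 0))
    expect_gt(pw[4], 0.99)
  }
  # increasing in delta^2 at fixed design
  d <- ancova_design(10, G = 3, P = 1)
  pw2 <- sapply(c(12000, 7500, 3000, 1000), function(s2)
    power_ancova(d, ancova_effect(mu1, s2), "exact")$power)
  expect_true(all(diff(pw2) > 0))
})

test_that("exact power decreases as covariates are added at fixed N_T", {
  e <- ancova_effect(mu1, 7500)
  pw <- sapply(1:8, function(P)
    power_ancova(ancova_design(16, G = 3, P = P), e, "exact")$power)
  expect_true(all(diff(pw) < 0))
})
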