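test_that("equal-slope solve has the identity-covariance closed form and round-trips", {
  expect_equal(solve_equal_slope(0.5, P = 1, sigma2 = 7500), 50)
  expect_equal(solve_equal_slope(0, P = 3, sigma2 = 2), 0)
  set.seed(8)
  for (i in 1:20) {
    rho <- runif(1, 0, 0.95); P <- sample(1:6, 1); s2 <- rexp(1) + 0.2
    A <- matrix(rnorm(P * P), P); Sigma <- crossprod(A) + diag(P)
    b <- solve_equal_slope(rho, P, s2, Sigma)
    bb <- rep(b, P)
    bSb <- drop(crossprod(bb, Sigma %*% bb))
    expect_equal(sqrt(bSb / (bSb + s2)), rho, tolerance = 1e-12)
  }
  expect_error(solve_equal_slope(1, 1, 1), "correlation")
})

test_that("dataset generation is deterministic per replicate and streams differ", {
  d <- ancova_design(5, G = 3, P = 2)
  sp <- simulation_spec(d, mu = c(1, 2, 3), sigma2 = 4, rho = 0.6,
                        n_reps = 100, seed = 99)
  expect_identical(generate_dataset(sp, 3), generate_dataset(sp, 3))
  expect_false(identical(generate_dataset(sp, 1), generate_dataset(sp, 2)))
  # master seed participates
  sp2 <- simulation_spec(d, mu = c(1, 2, 3), sigma2 = 4, rho = 0.6,
                         n_reps = 100, seed = 100)
  expect_false(identical(generate_dataset(sp, 1), generate_dataset(sp2, 1)))
})

test_that("the generator reduces to the deterministic model when noise vanishes", {
  d <- ancova_design(4, G = 3, P = 1)
  sp <- simulation_spec(d, mu = c(10, 20, 30), sigma2 = 1e-18, beta = 0,
                        n_reps = 100, seed = 5)
  dat <- generate_dataset(sp, 1)
  expect_equal(dat$y, c(10, 20, 30)[dat$group], tolerance = 1e-6)
})

test_that("generated data attain the requested response-covariate correlation", {
  d <- ancova_design(2000, G = 3, P = 1)
  sp <- simulation_spec(d, mu = c(0, 0, 0), sigma2 = 29, rho = 0.9,
                        n_reps = 100, seed = 17)
  dat <- generate_dataset(sp, 1)
  r <- cor(dat$y, dat$x1 * sp$beta)
  expect_lt(abs(r - 0.9), 3 / sqrt(6000))  # ~3 SE at N = 6000
  expect_equal(sp$sigma2_Y, sum(sp$beta^2) + 29)
})

test_that("non-normal covariate families standardize to zero mean and unit variance", {
  for (fam in c("exponential", "gamma", "laplace", "lognormal", "uniform",
                "discrete_uniform")) {
    cm <- covariate_model(fam, P = 2)
    d <- ancova_design(4000, G = 2, P = 2)
    sp <- simulation_spec(d, mu = c(0, 0), sigma2 = 1, rho = 0.5,
                          covariates = cm, n_reps = 100, seed = 23)
    X <- as.matrix(generate_dataset(sp, 1)[c("x1", "x2")])
    tol <- if (fam == "lognormal") 0.15 else 0.06  # heavy tail converges slowly
    expect_equal(unname(colMeans(X)), c(0, 0), tolerance = tol)
    expect_equal(unname(apply(X, 2, sd)), c(1, 1), tolerance = tol)
  }
})

test_that("empirical power tracks the exact formula and reports exact analytic errors", {
  d <- ancova_design(6, G = 3, P = 1)
  sp <- simulation_spec(d, mu = c(400, 450, 500), sigma2 = 1900, rho = 0.9,
                        n_reps = 1500, seed = 31)
  res <- empirical_power(sp, alpha = 0.05)
  expect_equal(res$mc_se,
               sqrt(res$empirical_power * (1 - res$empirical_power) / 1500))
  expect_equal(res$errors, res$analytic - res$empirical_power)
  expect_lt(abs(res$empirical_power - res$analytic[["exact"]]),
            3.2 * res$mc_se)
  expect_equal(res$regenerated, 0L)
})

test_that("empirical power is invariant to the covariate mean vector and covariance", {
  d <- ancova_design(6, G = 3, P = 2)
  base <- simulation_spec(d, mu = c(400, 450, 500), sigma2 = 1900,
                          rho = 0.9, n_reps = 1200, seed = 47)
  shifted <- simulation_spec(d, mu = c(400, 450, 500), sigma2 = 1900,
                             beta = solve_equal_slope(0.9, 2, 1900,
                                                      4 * diag(2)) * c(1, 1),
                             covariates = covariate_model(
                               "multinormal", P = 2, theta = c(50, -20),
                               Sigma = 4 * diag(2)),
                             n_reps = 1200, seed = 48)
  r1 <- empirical_power(base)
  r2 <- empirical_power(shifted)
  expect_equal(r1$analytic["exact"], r2$analytic["exact"], tolerance = 1e-10)
  se <- sqrt(r1$mc_se^2 + r2$mc_se^2)
  expect_lt(abs(r1$empirical_power - r2$empirical_power), 3 * se)
})

test_that("simulation specs validate their inputs", {
  d <- ancova_design(5, G = 3, P = 1)
  expect_error(simulation_spec(d, mu = c(1, 2), sigma2 = 1, rho = 0.5,
                               n_reps = 100, seed = 1), "per group")
  expect_error(simulation_spec(d, mu = c(1, 2, 3), sigma2 = 1, n_reps = 100,
                               seed = 1), "beta.*rho|rho")
  expect_error(simulation_spec(d, mu = c(1, 2, 3), sigma2 = 1, rho = 0.5,
                               n_reps = 10, seed = 1), "at least 100")
  expect_error(simulation_spec(d, mu = c(1, 2, 3), sigma2 = 1, rho = 0.5,
                               covariates = covariate_model("gamma", P = 2),
                               n_reps = 100, seed = 1), "match the design")
})
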