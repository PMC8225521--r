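#' Covariate model for simulation
#'
#' Describes the joint distribution of the `P` covariates used by the
#' Monte-Carlo engine.  The multinormal family takes a mean vector `theta`
#' and covariance `Sigma`; the non-normal families draw i.i.d. components
#' and, when `standardize = TRUE` (the default), are linearly transformed to
#' zero mean and unit variance using their theoretical moments so that the
#' implied response-covariate correlation is comparable across families.
#'
#' @param family One of `"multinormal"`, `"exponential"`, `"gamma"`,
#'   `"laplace"`, `"lognormal"`, `"uniform"`, `"discrete_uniform"`.
#' @param P Number of covariates.
#' @param theta Mean vector (multinormal; default zero).
#' @param Sigma Covariance matrix (multinormal; default identity).
#' @param params Named list of family parameters: `rate` (exponential,
#'   default 1), `shape`/`rate` (gamma, default 2/1), `scale` (laplace,
#'   default 1), `meanlog`/`sdlog` (lognormal, default 0/1), `min`/`max`
#'   (uniform, default 0/1), `support` (discrete_uniform, default `1:5`).
#' @param standardize Standardize non-normal draws to zero mean, unit
#'   variance (default `TRUE`).
#' @return An object of class `"covariate_model"`.
#' @examples
#' covariate_model("multinormal", P = 2)
#' covariate_model("gamma", P = 1, params = list(shape = 3, rate = 2))
#' @export
covariate_model <- function(family = c("multinormal", "exponential", "gamma",
                                       "laplace", "lognormal", "uniform",
                                       "discrete_uniform"),
                            P = 1L, theta = NULL, Sigma = NULL,
                            params = list(), standardize = TRUE) {
  family <- match.arg(family)
  P <- as.integer(P)
  if (P < 1L) stop("at least 1 covariate is required")
  if (family == "multinormal") {
    if (is.null(theta)) theta <- rep(0, P)
    if (is.null(Sigma)) Sigma <- diag(P)
    Sigma <- as.matrix(Sigma)
    if (length(theta) != P || !all(dim(Sigma) == P))
      stop("`theta`/`Sigma` dimensions must match P")
    if (max(abs(Sigma - t(Sigma))) > 1e-10) stop("`Sigma` must be symmetric")
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("`Sigma` must be positive definite")
  }
  defaults <- switch(family,
    multinormal = list(),
    exponential = list(rate = 1),
    gamma = list(shape = 2, rate = 1),
    laplace = list(scale = 1),
    lognormal = list(meanlog = 0, sdlog = 1),
    uniform = list(min = 0, max = 1),
    discrete_uniform = list(support = 1:5))
  params <- utils::modifyList(defaults, params)
  structure(
    list(family = family, P = P, theta = theta, Sigma = Sigma,
         params = params, standardize = isTRUE(standardize)),
    class = "covariate_model"
  )
}

## Theoretical mean and sd of one i.i.d. component, for standardization.
.cov_moments <- function(model) {
  p <- model$params
  switch(model$family,
    exponential = c(mean = 1 / p$rate, sd = 1 / p$rate),
    gamma = c(mean = p$shape / p$rate, sd = sqrt(p$shape) / p$rate),
    laplace = c(mean = 0, sd = p$scale * sqrt(2)),
    lognormal = {
      m <- exp(p$meanlog + p$sdlog^2 / 2)
      c(mean = m, sd = m * sqrt(exp(p$sdlog^2) - 1))
    },
    uniform = c(mean = (p$min + p$max) / 2, sd = (p$max - p$min) / sqrt(12)),
    discrete_uniform = {
      s <- p$support
      c(mean = mean(s), sd = sqrt(mean((s - mean(s))^2)))
    },
    stop("no closed-form moments for family ", model$family))
}

## Draw an n x P covariate matrix from the model.
.draw_covariates <- function(model, n) {
  P <- model$P
  if (model$family == "multinormal") {
    Z <- matrix(stats::rnorm(n * P), n, P)
    return(sweep(Z %*% chol(model$Sigma), 2, model$theta, `+`))
  }
  p <- model$params
  x <- switch(model$family,
    exponential = stats::rexp(n * P, rate = p$rate),
    gamma = stats::rgamma(n * P, shape = p$shape, rate = p$rate),
    laplace = {
      u <- stats::runif(n * P) - 0.5
      -p$scale * sign(u) * log(1 - 2 * abs(u))
    },
    lognormal = stats::rlnorm(n * P, meanlog = p$meanlog, sdlog = p$sdlog),
    uniform = stats::runif(n * P, min = p$min, max = p$max),
    discrete_uniform = sample(p$support, n * P, replace = TRUE))
  X <- matrix(x, n, P)
  if (model$standardize) {
    mo <- .cov_moments(model)
    X <- (X - mo["mean"]) / mo["sd"]
  }
  X
}

## Effective covariance of the covariate vector as generated (identity for
## standardized i.i.d. non-normal components).
.cov_sigma <- function(model) {
  if (model$family == "multinormal") return(model$Sigma)
  if (model$standardize) return(diag(model$P))
  mo <- .cov_moments(model)
  diag(model$P) * mo["sd"]^2
}

#' Common slope attaining a target response-covariate correlation
#'
#' With equal slopes `beta_1 = ... = beta_P = beta*` and covariate
#' covariance `Sigma`, the squared correlation between the response and the
#' covariate combination is `beta' Sigma beta / (beta' Sigma beta +
#' sigma^2)`.  This solves for `beta*` given a target `rho`; for `Sigma =
#' I_P` the closed form is `beta* = sqrt(rho^2 sigma^2 / ((1 - rho^2) P))`.
#'
#' @param rho Target correlation in `[0, 1)`.
#' @param P Number of covariates.
#' @param sigma2 Error variance of the ANCOVA model.
#' @param Sigma Covariate covariance matrix (default identity).
#' @return The common slope `beta*` (nonnegative scalar).
#' @examples
#' solve_equal_slope(0.5, P = 1, sigma2 = 7500)  # 50
#' @export
solve_equal_slope <- function(rho, P, sigma2, Sigma = diag(P)) {
  if (rho < 0 || rho >= 1) stop("impossible correlation: `rho` must lie in [0, 1)")
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  if (rho == 0) return(0)
  s <- sum(Sigma)  # 1' Sigma 1
  if (s <= 0) stop("`Sigma` must be positive definite")
  sqrt(rho^2 * sigma2 / ((1 - rho^2) * s))
}

#' Simulation specification for the Monte-Carlo engine
#'
#' Bundles a design, population parameters, slopes (given directly or solved
#' from a target correlation via [solve_equal_slope()]), a covariate model,
#' the replicate count and the master seed.
#'
#' @param design An [ancova_design()] object.
#' @param mu Group intercepts (length `G`).
#' @param sigma2 Error variance.
#' @param beta Slope vector of length `P`; give either `beta` or `rho`.
#' @param rho Target response-covariate correlation from which equal slopes
#'   are solved.
#' @param covariates A [covariate_model()]; default standard multinormal.
#' @param n_reps Number of Monte-Carlo replicates (at least 100).
#' @param seed Master seed for the per-replicate RNG streams.
#' @param contrast Contrast matrix; default omnibus.
#' @return An object of class `"simulation_spec"`, including the implied
#'   `rho` and marginal response variance `sigma2_Y = beta' Sigma beta +
#'   sigma2`.
#' @examples
#' d <- ancova_design(sizes = 6, G = 3, P = 1)
#' simulation_spec(d, mu = c(400, 450, 500), sigma2 = 7500, rho = 0.5,
#'                 n_reps = 200, seed = 7)
#' @export
simulation_spec <- function(design, mu, sigma2, beta = NULL, rho = NULL,
                            covariates = NULL, n_reps = 10000L, seed = 1L,
                            contrast = NULL) {
  stopifnot(inherits(design, "ancova_design"))
  mu <- as.numeric(mu)
  if (length(mu) != design$G) stop("`mu` must have one entry per group")
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  if (is.null(covariates)) covariates <- covariate_model("multinormal", P = design$P)
  stopifnot(inherits(covariates, "covariate_model"))
  if (covariates$P != design$P)
    stop("covariate model P must match the design")
  Sigma <- .cov_sigma(covariates)
  if (is.null(beta)) {
    if (is.null(rho)) stop("give either `beta` or `rho`")
    beta <- rep(solve_equal_slope(rho, design$P, sigma2, Sigma), design$P)
  }
  beta <- as.numeric(beta)
  if (length(beta) != design$P) stop("`beta` must have one slope per covariate")
  bSb <- drop(crossprod(beta, Sigma %*% beta))
  sigma2_Y <- bSb + sigma2
  rho_implied <- sqrt(bSb / sigma2_Y)
  if (rho_implied >= 1) stop("implied correlation must lie in [0, 1)")
  n_reps <- as.integer(n_reps)
  if (n_reps < 100L) stop("`n_reps` must be at least 100")
  if (is.null(contrast)) contrast <- contr_omnibus(design$G)
  contrast <- validate_contrast(contrast, design$G)
  structure(
    list(design = design, mu = mu, sigma2 = sigma2, beta = beta,
         covariates = covariates, n_reps = n_reps, seed = as.integer(seed),
         contrast = contrast, rho = rho_implied, sigma2_Y = sigma2_Y),
    class = "simulation_spec"
  )
}

## Per-replicate RNG streams: L'Ecuyer-CMRG substreams spawned from the
## master seed, so replicate `i` sees the same stream regardless of
## execution order.
.stream_root <- function(seed) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  root <- get(".Random.seed", envir = globalenv())
  RNGkind(old_kind[1], old_kind[2], old_kind[3])
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  root
}

.stream_for_rep <- function(root, rep_index) {
  s <- root
  for (i in seq_len(rep_index)) s <- parallel::nextRNGStream(s)
  s
}

## Draw one dataset with the RNG state already positioned.
.draw_dataset <- function(spec) {
  d <- spec$design
  g <- rep(seq_len(d$G), d$sizes)
  X <- .draw_covariates(spec$covariates, d$N_T)
  eps <- stats::rnorm(d$N_T, sd = sqrt(spec$sigma2))
  y <- spec$mu[g] + drop(X %*% spec$beta) + eps
  out <- data.frame(group = g, y = y)
  colnames(X) <- paste0("x", seq_len(d$P))
  cbind(out, as.data.frame(X))
}

#' Generate one synthetic ANCOVA dataset
#'
#' Draws covariates from the spec's covariate model, normal errors with
#' variance `sigma2`, and responses from the ANCOVA model.  Replicate
#' `rep_index` uses its own RNG substream derived from the master seed, so
#' datasets are reproducible and independent of the order in which
#' replicates are generated.
#'
#' @param spec A [simulation_spec()] object.
#' @param rep_index Positive replicate index.
#' @return A data frame with columns `group`, `y`, `x1..xP`.
#' @examples
#' d <- ancova_design(sizes = 5, G = 3, P = 1)
#' sp <- simulation_spec(d, mu = c(0, 0, 0), sigma2 = 1, rho = 0.5,
#'                       n_reps = 100, seed = 42)
#' head(generate_dataset(sp, 1))
#' @export
generate_dataset <- function(spec, rep_index = 1L) {
  stopifnot(inherits(spec, "simulation_spec"), rep_index >= 1)
  root <- .stream_root(spec$seed)
  s <- .stream_for_rep(root, as.integer(rep_index))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  assign(".Random.seed", s, envir = globalenv())
  .draw_dataset(spec)
}

#' Empirical power or type-I error by Monte-Carlo simulation
#'
#' Generates `n_reps` datasets under the spec, computes the Wald statistic
#' for each, and reports the proportion exceeding the central-F critical
#' value `F_{c, nu, alpha}`, together with its Monte-Carlo standard error
#' and the three analytic powers (exact, approximate, ANOVA) for the same
#' design.  Replicates with singular `S_XX` are regenerated within their
#' stream and counted; more than 1% regenerations aborts.
#'
#' @param spec A [simulation_spec()] object.
#' @param alpha Significance level.
#' @return An object of class `"simulation_result"`: list with
#'   `empirical_power`, `mc_se`, `n_reps`, `analytic` (named vector of
#'   exact/approx/anova powers), `errors` (analytic minus empirical),
#'   `regenerated`.
#' @examples
#' d <- ancova_design(sizes = 6, G = 3, P = 1)
#' sp <- simulation_spec(d, mu = c(400, 450, 500), sigma2 = 1900, rho = 0.9,
#'                       n_reps = 200, seed = 11)
#' empirical_power(sp)
#' @export
empirical_power <- function(spec, alpha = 0.05) {
  stopifnot(inherits(spec, "simulation_spec"))
  d <- spec$design
  c_rows <- nrow(spec$contrast)
  crit <- stats::qf(alpha, c_rows, d$nu, lower.tail = FALSE)
  root <- .stream_root(spec$seed)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))

  reject <- logical(spec$n_reps)
  regenerated <- 0L
  s <- root
  for (i in seq_len(spec$n_reps)) {
    s <- parallel::nextRNGStream(s)
    assign(".Random.seed", s, envir = globalenv())
    repeat {
      dat <- .draw_dataset(spec)
      w <- tryCatch(
        wald_test(fit_ancova(dat, covariates = paste0("x", seq_len(d$P))),
                  spec$contrast),
        error = function(e) NULL)
      if (!is.null(w)) break
      regenerated <- regenerated + 1L
      if (regenerated > 0.01 * spec$n_reps)
        stop("more than 1% of replicates had singular S_XX; check the spec")
    }
    reject[i] <- unname(w$statistic) > crit
  }

  p_hat <- mean(reject)
  eff <- ancova_effect(spec$mu, spec$sigma2, weights = d$weights)
  analytic <- c(
    exact = power_ancova(d, eff, "exact")$power,
    approx = power_ancova(d, eff, "approx")$power,
    anova = power_anova(d$N_T, d$G, eff$delta2, spec$rho, alpha)$power)
  structure(
    list(empirical_power = p_hat,
         mc_se = sqrt(p_hat * (1 - p_hat) / spec$n_reps),
         n_reps = spec$n_reps,
         analytic = analytic,
         errors = analytic - p_hat,
         regenerated = regenerated),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo power: %.4f (se %.4f, %d replicates",
              x$empirical_power, x$mc_se, x$n_reps))
  if (x$regenerated > 0) cat(sprintf(", %d regenerated", x$regenerated))
  cat(")\n")
  cat("  analytic: ",
      paste(sprintf("%s %.4f (err %+.4f)", names(x$analytic), x$analytic,
                    x$errors), collapse = ", "), "\n")
  invisible(x)
}
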