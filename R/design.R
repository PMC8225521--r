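#' Design specification for a one-way ANCOVA
#'
#' Bundles the structural constants of a one-way ANCOVA design: the number of
#' treatment groups `G`, the number of covariates `P`, the per-group sample
#' sizes, and the significance level.  The error degrees of freedom
#' `nu = N_T - G - P` are derived and must be at least 1.
#'
#' @param sizes Integer vector of per-group sample sizes `N_1, ..., N_G`
#'   (each at least 2), or a single integer giving a common per-group size
#'   when `G` is supplied.
#' @param P Number of covariates (at least 1).
#' @param alpha Significance level in (0, 1).
#' @param G Number of groups; required only when `sizes` has length 1.
#'
#' @return An object of class `"ancova_design"`: a list with elements `G`,
#'   `P`, `sizes`, `N_T`, `nu`, `alpha` and the allocation weights
#'   `weights = sizes / N_T`.
#'
#' @examples
#' ancova_design(sizes = 21, G = 3, P = 1)
#' ancova_design(sizes = c(10, 12, 14), P = 2, alpha = 0.01)
#' @export
ancova_design <- function(sizes, P, alpha = 0.05, G = NULL) {
  if (length(sizes) == 1L) {
    if (is.null(G)) stop("`G` is required when `sizes` is a single value")
    sizes <- rep(as.integer(sizes), G)
  }
  sizes <- as.integer(sizes)
  G <- length(sizes)
  P <- as.integer(P)
  if (G < 2L) stop("invalid design: at least 2 groups are required")
  if (P < 1L) stop("invalid design: at least 1 covariate is required")
  if (any(sizes < 2L)) stop("invalid design: every group needs N_i >= 2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)")
  N_T <- sum(sizes)
  nu <- N_T - G - P
  if (nu < 1L) stop("design too small: error degrees of freedom N_T - G - P < 1")
  structure(
    list(G = G, P = P, sizes = sizes, N_T = N_T, nu = nu, alpha = alpha,
         weights = sizes / N_T),
    class = "ancova_design"
  )
}

#' @export
print.ancova_design <- function(x, ...) {
  cat("One-way ANCOVA design\n")
  cat("  groups G       :", x$G, "\n")
  cat("  covariates P   :", x$P, "\n")
  cat("  group sizes    :", paste(x$sizes, collapse = ", "),
      sprintf(" (N_T = %d)\n", x$N_T))
  cat("  error df nu    :", x$nu, "\n")
  cat("  alpha          :", x$alpha, "\n")
  invisible(x)
}

#' Omnibus (all-groups-equal) contrast matrix
#'
#' Builds the `(G - 1) x G` contrast matrix `(1, -I)` whose rows compare the
#' first group with each of the remaining groups.  The hypothesis `C mu = 0`
#' with this matrix is the omnibus test of equality of all adjusted group
#' means.
#'
#' @param G Number of groups (at least 2).
#' @return A numeric matrix with `G - 1` rows and `G` columns, full row rank,
#'   each row summing to zero.
#' @examples
#' contr_omnibus(3)
#' @export
contr_omnibus <- function(G) {
  G <- as.integer(G)
  if (length(G) != 1L || is.na(G) || G < 2L)
    stop("invalid design: `G` must be an integer >= 2")
  cbind(1, -diag(G - 1L))
}

## Contrast validation: full row rank (tolerance-based QR) and zero row sums
## to absolute tolerance 1e-10, as required for the treatment-effect
## hypothesis to be invariant to the covariate adjustment.
validate_contrast <- function(C, G, tol = 1e-10) {
  C <- as.matrix(C)
  if (!is.numeric(C)) stop("contrast matrix must be numeric")
  if (ncol(C) != G)
    stop(sprintf("contrast matrix has %d columns; design has G = %d groups",
                 ncol(C), G))
  c_rows <- nrow(C)
  if (c_rows < 1L || c_rows > G - 1L)
    stop("contrast matrix must have between 1 and G - 1 rows")
  if (any(abs(rowSums(C)) > tol))
    stop("contrast rows must each sum to zero")
  if (qr(C)$rank < c_rows)
    stop("contrast matrix is not of full row rank")
  C
}

#' Effect specification: group intercepts, error variance and contrast
#'
#' Collects the population quantities that drive power: the group intercepts
#' `mu_1, ..., mu_G`, the ANCOVA error variance `sigma^2`, the allocation
#' weights `q_i` and a contrast matrix.  The standardized effect sizes
#' `gamma^2` (general contrast) and `delta^2` (omnibus) are computed at
#' construction.
#'
#' @param mu Numeric vector of G group intercepts (response units).
#' @param sigma2 Error variance of the ANCOVA model, `> 0`.
#' @param weights Allocation proportions `q_i = N_i / N_T`; default equal.
#' @param contrast Contrast matrix with G columns and zero row sums; default
#'   [contr_omnibus()].
#'
#' @return An object of class `"ancova_effect"`: a list with `mu`, `sigma2`,
#'   `weights`, `contrast`, `G`, and the effect sizes `gamma2` and `delta2`.
#' @examples
#' eff <- ancova_effect(mu = c(400, 450, 500), sigma2 = 7500)
#' eff$delta2   # 0.2222...
#' @export
ancova_effect <- function(mu, sigma2, weights = NULL, contrast = NULL) {
  mu <- as.numeric(mu)
  G <- length(mu)
  if (G < 2L) stop("at least 2 group intercepts are required")
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop("invalid variance: `sigma2` must be a positive scalar")
  if (is.null(weights)) weights <- rep(1 / G, G)
  if (length(weights) != G || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("`weights` must be positive and sum to 1")
  if (is.null(contrast)) contrast <- contr_omnibus(G)
  contrast <- validate_contrast(contrast, G)
  structure(
    list(mu = mu, sigma2 = sigma2, weights = weights, contrast = contrast,
         G = G,
         gamma2 = effect_size_gamma2(mu, sigma2, contrast, weights),
         delta2 = effect_size_delta2(mu, sigma2, weights)),
    class = "ancova_effect"
  )
}

#' @export
print.ancova_effect <- function(x, ...) {
  cat("ANCOVA effect specification\n")
  cat("  intercepts mu  :", paste(format(x$mu), collapse = ", "), "\n")
  cat("  sigma^2        :", format(x$sigma2), "\n")
  cat("  weights q      :", paste(format(round(x$weights, 4)), collapse = ", "), "\n")
  cat("  contrast rows  :", nrow(x$contrast), "\n")
  cat("  gamma^2        :", format(x$gamma2), "\n")
  cat("  delta^2        :", format(x$delta2), "\n")
  invisible(x)
}

#' Standardized effect size for a general contrast
#'
#' Computes `gamma^2 = sigma_gamma^2 / sigma^2` where
#' `sigma_gamma^2 = (C mu)' (C Q C')^{-1} (C mu)` and
#' `Q = diag(1/q_1, ..., 1/q_G)`.  With the omnibus contrast this equals the
#' allocation-weighted variance of the intercepts over `sigma^2`, i.e.
#' [effect_size_delta2()].
#'
#' @param mu Numeric vector of group intercepts.
#' @param sigma2 Error variance, `> 0`.
#' @param contrast Contrast matrix (default omnibus).
#' @param weights Allocation proportions (default equal).
#' @return Nonnegative scalar; zero iff `C mu = 0`.
#' @examples
#' effect_size_gamma2(c(400, 450, 500), 9900)  # 0.1684 to 4 d.p.
#' @export
effect_size_gamma2 <- function(mu, sigma2,
                               contrast = contr_omnibus(length(mu)),
                               weights = NULL) {
  mu <- as.numeric(mu)
  G <- length(mu)
  if (sigma2 <= 0) stop("invalid variance: `sigma2` must be positive")
  if (is.null(weights)) weights <- rep(1 / G, G)
  C <- validate_contrast(contrast, G)
  cm <- drop(C %*% mu)
  CQC <- C %*% (t(C) / weights)  # C Q C' with Q = diag(1/q)
  sol <- tryCatch(solve(CQC, cm),
                  error = function(e) stop("malformed contrast: C Q C' is singular"))
  drop(crossprod(cm, sol)) / sigma2
}

#' Omnibus effect size delta-squared
#'
#' Computes `delta^2 = sigma_delta^2 / sigma^2`, where `sigma_delta^2` is the
#' allocation-weighted variance of the group intercepts about their weighted
#' mean.  This is the ANCOVA analogue of the ANOVA signal-to-noise ratio
#' `f^2`, and equals [effect_size_gamma2()] evaluated at the omnibus
#' contrast.
#'
#' @inheritParams effect_size_gamma2
#' @return Nonnegative scalar; zero iff all intercepts are equal.
#' @examples
#' effect_size_delta2(c(400, 450, 500), 7500)  # 0.2222 to 4 d.p.
#' @export
effect_size_delta2 <- function(mu, sigma2, weights = NULL) {
  mu <- as.numeric(mu)
  G <- length(mu)
  if (sigma2 <= 0) stop("invalid variance: `sigma2` must be positive")
  if (is.null(weights)) weights <- rep(1 / G, G)
  if (length(weights) != G || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("`weights` must be positive and sum to 1")
  mu_tilde <- sum(weights * mu)
  sum(weights * (mu - mu_tilde)^2) / sigma2
}

#' Noncentrality law under random multinormal covariates
#'
#' Under multinormal covariates the noncentrality parameter of the Wald
#' statistic is not a constant but the random variable
#' `Lambda = Gamma * B` with `Gamma = N_T * gamma^2` and
#' `B ~ Beta((nu + 1)/2, P/2)`.  This function returns the parameters of
#' that mixing law for a given design and effect.
#'
#' @param design An [ancova_design()] object.
#' @param effect An [ancova_effect()] object with the same number of groups.
#'   The allocation weights of the design (derived from its group sizes)
#'   are used; the effect's free-standing weights are only for planning
#'   without a concrete design.
#' @return An object of class `"noncentrality_law"`: list with `Gamma`,
#'   `beta_a = (nu + 1)/2`, `beta_b = P/2`, plus `df1` (contrast rank) and
#'   `nu`.
#' @examples
#' d <- ancova_design(sizes = 21, G = 3, P = 1)
#' e <- ancova_effect(c(400, 450, 500), 9900)
#' noncentrality_law(d, e)
#' @export
noncentrality_law <- function(design, effect) {
  stopifnot(inherits(design, "ancova_design"), inherits(effect, "ancova_effect"))
  if (design$G != effect$G)
    stop("inconsistent inputs: design and effect specify different G")
  gamma2 <- effect_size_gamma2(effect$mu, effect$sigma2, effect$contrast,
                               weights = design$weights)
  structure(
    list(Gamma = design$N_T * gamma2,
         beta_a = (design$nu + 1) / 2,
         beta_b = design$P / 2,
         df1 = nrow(effect$contrast),
         nu = design$nu),
    class = "noncentrality_law"
  )
}

#' @export
print.noncentrality_law <- function(x, ...) {
  cat("Noncentrality law: Lambda = Gamma * B,  B ~ Beta(a, b)\n")
  cat(sprintf("  Gamma = %.6g,  a = %.6g,  b = %.6g  (df1 = %d, nu = %d)\n",
              x$Gamma, x$beta_a, x$beta_b, x$df1, x$nu))
  invisible(x)
}
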