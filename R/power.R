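#' Power of the Wald test at a fixed noncentrality
#'
#' Upper-tail probability of a noncentral `F(df1, df2, ncp)` variate beyond
#' the central-F critical value `F_{df1, df2, alpha}`.  This is the power of
#' the general linear hypothesis test when the covariate values — and hence
#' the noncentrality parameter — are treated as fixed.
#'
#' @param df1 Numerator degrees of freedom (contrast rank), `>= 1`.
#' @param df2 Denominator (error) degrees of freedom, `>= 1`.
#' @param ncp Noncentrality parameter, `>= 0`.
#' @param alpha Significance level in (0, 1).
#' @return Power in `[alpha, 1)`; equals `alpha` when `ncp = 0`.
#' @examples
#' power_ncf(2, 44, 48 * 0.2222, 0.05)  # 0.8136
#' @export
power_ncf <- function(df1, df2, ncp, alpha = 0.05) {
  if (any(df1 < 1) || any(df2 < 1))
    stop("design too small: degrees of freedom must be >= 1")
  if (any(ncp < 0)) stop("noncentrality must be nonnegative")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  crit <- stats::qf(alpha, df1, df2, lower.tail = FALSE)
  stats::pf(crit, df1, df2, ncp = ncp, lower.tail = FALSE)
}

## Gauss-Legendre quadrature of the fixed-covariate power against the Beta
## mixing law, in quantile space: with B = qbeta(u; a, b) the expectation is
## int_0^1 Psi(Gamma * qbeta(u)) du, which absorbs the Beta density and its
## endpoint singularity at B -> 1 when b = P/2 = 1/2.
.beta_mix_quad <- function(df1, nu, Gamma, P, alpha, nodes) {
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  b <- stats::qbeta(gl$x, (nu + 1) / 2, P / 2)
  sum(gl$w * power_ncf(df1, nu, Gamma * b, alpha))
}

#' Exact power as a Beta mixture of noncentral-F tail probabilities
#'
#' Computes `E_B[ P{ F(df1, nu, Gamma * B) > F_{df1, nu, alpha} } ]` where
#' `B ~ Beta((nu + 1)/2, P/2)` is the mixing variable induced by treating the
#' covariates as multinormal random variables.  The expectation is evaluated
#' by Gauss-Legendre quadrature in the quantile domain of the Beta law, and
#' convergence is verified by node doubling.
#'
#' @param df1 Numerator degrees of freedom (contrast rank).
#' @param nu Error degrees of freedom `N_T - G - P`.
#' @param Gamma Scale of the noncentrality law, `N_T * gamma^2 >= 0`.
#' @param P Number of covariates, `>= 1`.
#' @param alpha Significance level in (0, 1).
#' @param nodes Initial number of quadrature nodes (at least 16; default 128).
#' @param tol Absolute node-doubling tolerance (default 1e-6).
#' @return Power in `[alpha, 1)`, with attribute `"nodes"` recording the
#'   final node count.
#' @examples
#' power_exact_mixture(2, 59, 63 * 0.1684, P = 1, alpha = 0.05)
#' @export
power_exact_mixture <- function(df1, nu, Gamma, P, alpha = 0.05,
                                nodes = 128L, tol = 1e-6) {
  if (Gamma < 0) stop("`Gamma` must be nonnegative")
  if (P < 1) stop("at least 1 covariate is required")
  if (nu < 1) stop("design too small: nu must be >= 1")
  if (nodes < 16L) stop("`nodes` must be at least 16")
  if (Gamma == 0) {  # integrand is constant alpha
    return(structure(power_ncf(df1, nu, 0, alpha), nodes = as.integer(nodes)))
  }
  est <- .beta_mix_quad(df1, nu, Gamma, P, alpha, nodes)
  max_nodes <- 4096L
  repeat {
    nodes2 <- 2L * nodes
    est2 <- .beta_mix_quad(df1, nu, Gamma, P, alpha, nodes2)
    if (abs(est2 - est) <= tol) break
    if (nodes2 >= max_nodes)
      stop("quadrature failed to converge: node-doubling change ",
           format(abs(est2 - est)), " exceeds tolerance ", format(tol))
    nodes <- nodes2
    est <- est2
  }
  structure(est2, nodes = nodes2)
}

.power_result <- function(method, power, df1, df2, noncentrality,
                          nodes = NA_integer_) {
  structure(
    list(method = method, power = as.numeric(power), df1 = df1, df2 = df2,
         noncentrality = noncentrality, quadrature_nodes = nodes),
    class = "ancova_power"
  )
}

#' @export
print.ancova_power <- function(x, ...) {
  lab <- c(fixed = "fixed-covariate", exact = "exact (Beta mixture)",
           approx = "approximate (Cohen-style)", anova = "ANOVA")[x$method]
  cat(sprintf("%s power: %.4f\n", lab, x$power))
  cat(sprintf("  df = (%d, %d), noncentrality = %.6g\n",
              x$df1, x$df2, x$noncentrality))
  if (!is.na(x$quadrature_nodes))
    cat(sprintf("  quadrature nodes = %d\n", x$quadrature_nodes))
  invisible(x)
}

#' Power of an ANCOVA design: exact and approximate methods
#'
#' Computes the power of the Wald test of `C mu = 0` for a one-way ANCOVA
#' design.  Method `"exact"` accounts for the randomness of the covariates:
#' the noncentrality parameter is `N_T * gamma^2 * B` with
#' `B ~ Beta((nu + 1)/2, P/2)`, and power is the Beta-mixture expectation of
#' noncentral-F tail probabilities.  Method `"approx"` is the conventional
#' fixed-noncentrality calculation at `Lambda_A = N_T * gamma^2`, which
#' always overstates the exact power because `0 < B < 1`.
#'
#' @param design An [ancova_design()] object.
#' @param effect An [ancova_effect()] object (same `G`).
#' @param method `"exact"` or `"approx"`.
#' @param nodes Quadrature nodes for the exact method.
#' @return An object of class `"ancova_power"` with elements `method`,
#'   `power`, `df1`, `df2`, `noncentrality` and (exact method)
#'   `quadrature_nodes`.
#' @examples
#' d <- ancova_design(sizes = 16, G = 3, P = 1)
#' e <- ancova_effect(c(400, 450, 500), 7500)
#' power_ancova(d, e, method = "exact")    # 0.8042
#' power_ancova(d, e, method = "approx")   # 0.8136
#' @export
power_ancova <- function(design, effect, method = c("exact", "approx"),
                         nodes = 128L) {
  method <- match.arg(method)
  law <- noncentrality_law(design, effect)
  if (method == "exact") {
    p <- power_exact_mixture(law$df1, law$nu, law$Gamma, design$P,
                             design$alpha, nodes = nodes)
    .power_result("exact", p, law$df1, law$nu, law$Gamma,
                  nodes = attr(p, "nodes"))
  } else {
    .power_result("approx",
                  power_ncf(law$df1, law$nu, law$Gamma, design$alpha),
                  law$df1, law$nu, law$Gamma)
  }
}

#' Power of the omnibus ANOVA F test with a variance-reducing covariate
#'
#' Reference method that ignores the ANCOVA degrees-of-freedom adjustment:
#' power of the omnibus F test on `(G - 1, N_T - G)` degrees of freedom with
#' noncentrality `Lambda_O = (1 - rho^2) * N_T * delta^2`, where `delta^2` is
#' measured against the ANCOVA error variance `sigma^2 = (1 - rho^2) *
#' sigma_Y^2` and `rho` is the correlation between the response and the
#' covariate combination.  Equivalently `Lambda_O = N_T * sigma_delta^2 /
#' sigma_Y^2`.
#'
#' @param N_T Total sample size.
#' @param G Number of groups.
#' @param delta2 Omnibus effect size against the ANCOVA error variance.
#' @param rho Response-covariate correlation in `[0, 1)`.
#' @param alpha Significance level.
#' @return An object of class `"ancova_power"` with `method = "anova"`.
#' @examples
#' power_anova(63, 3, 0.2222, rho = 0.5)  # 0.8148
#' @export
power_anova <- function(N_T, G, delta2, rho, alpha = 0.05) {
  if (rho < 0 || rho >= 1) stop("invalid correlation: `rho` must lie in [0, 1)")
  if (delta2 < 0) stop("`delta2` must be nonnegative")
  Lambda_O <- (1 - rho^2) * N_T * delta2
  .power_result("anova", power_ncf(G - 1, N_T - G, Lambda_O, alpha),
                G - 1, N_T - G, Lambda_O)
}
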