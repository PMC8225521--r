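#' Minimum sample size attaining a target power
#'
#' Finds the smallest first-group size `N_1` — with the remaining groups set
#' by a priori allocation ratios `N_i = ceiling(N_1 * r_i)` — whose implied
#' design reaches the target power under one of the three planning methods:
#' the exact Beta-mixture ANCOVA power, the approximate (Cohen-style) ANCOVA
#' power, or the ANOVA reference power.  The search scans `N_1` upward in
#' steps of 1 from the smallest feasible value (every `N_i >= 2` and
#' `nu >= 1`), so the returned design is minimal even if rounding of the
#' ratio-implied sizes makes power locally non-monotone.
#'
#' @param method One of `"exact"`, `"approx"`, `"anova"`.
#' @param effect An [ancova_effect()] object carrying intercepts, error
#'   variance and contrast.  Allocation weights are re-derived from the
#'   realized group sizes at every candidate.
#' @param P Number of covariates (exact/approx methods).
#' @param ratios Allocation ratios `r_1 = 1, r_2, ..., r_G`; default
#'   balanced.
#' @param target_power Target power in `(alpha, 1)`.
#' @param alpha Significance level.
#' @param rho Response-covariate correlation; required for `method =
#'   "anova"` and ignored otherwise.
#' @param nodes Quadrature nodes for the exact method.
#' @param cap Abort if `N_T` exceeds this bound (default `1e6`), e.g. for a
#'   null effect.
#' @return An object of class `"ancova_samplesize"`: list with `method`,
#'   `per_group_sizes`, `N_T`, `achieved_power`, `target_power`, `alpha`,
#'   `iterations`.
#' @examples
#' e <- ancova_effect(c(400, 450, 500), 7500)
#' solve_sample_size("approx", e, P = 1, target_power = 0.80)$N_T  # 48
#' solve_sample_size("anova", e, P = 1, target_power = 0.80, rho = 0.5)$N_T  # 63
#' @export
solve_sample_size <- function(method = c("exact", "approx", "anova"),
                              effect, P = 1L, ratios = NULL,
                              target_power = 0.80, alpha = 0.05,
                              rho = NULL, nodes = 128L, cap = 1e6) {
  method <- match.arg(method)
  stopifnot(inherits(effect, "ancova_effect"))
  G <- effect$G
  if (is.null(ratios)) ratios <- rep(1, G)
  if (length(ratios) != G || any(ratios <= 0))
    stop("`ratios` must be positive with one entry per group")
  if (abs(ratios[1] - 1) > 1e-12) stop("`ratios` must have r_1 = 1")
  if (target_power <= alpha || target_power >= 1)
    stop("`target_power` must lie in (alpha, 1)")
  if (method == "anova") {
    if (is.null(rho)) stop("`rho` is required for the anova method")
    if (rho < 0 || rho >= 1) stop("invalid correlation: `rho` must lie in [0, 1)")
  }
  P <- as.integer(P)

  power_at <- function(sizes) {
    N_T <- sum(sizes)
    switch(method,
      exact = {
        d <- ancova_design(sizes, P = P, alpha = alpha)
        power_ancova(d, .reweight(effect, sizes), "exact", nodes = nodes)$power
      },
      approx = {
        d <- ancova_design(sizes, P = P, alpha = alpha)
        power_ancova(d, .reweight(effect, sizes), "approx")$power
      },
      anova = {
        delta2 <- effect_size_delta2(effect$mu, effect$sigma2,
                                     weights = sizes / N_T)
        power_anova(N_T, G, delta2, rho, alpha)$power
      })
  }
  feasible <- function(sizes) {
    N_T <- sum(sizes)
    df2 <- if (method == "anova") N_T - G else N_T - G - P
    all(sizes >= 2L) && df2 >= 1L
  }
  sizes_for <- function(n1) as.integer(ceiling(n1 * ratios))

  n1 <- 2L
  while (!feasible(sizes_for(n1))) n1 <- n1 + 1L
  iterations <- 0L
  repeat {
    sizes <- sizes_for(n1)
    iterations <- iterations + 1L
    pw <- power_at(sizes)
    if (pw >= target_power) break
    n1 <- n1 + 1L
    if (sum(sizes_for(n1)) > cap)
      stop("sample size search diverged: target power unreachable below cap")
  }
  structure(
    list(method = method, per_group_sizes = sizes, N_T = sum(sizes),
         achieved_power = pw, target_power = target_power, alpha = alpha,
         iterations = iterations),
    class = "ancova_samplesize"
  )
}

## Rebuild the effect with weights implied by realized group sizes; the
## contrast and population parameters are unchanged.
.reweight <- function(effect, sizes) {
  ancova_effect(effect$mu, effect$sigma2, weights = sizes / sum(sizes),
                contrast = effect$contrast)
}

#' @export
print.ancova_samplesize <- function(x, ...) {
  cat(sprintf("Minimum sample size (%s method)\n", x$method))
  cat("  per-group sizes :", paste(x$per_group_sizes, collapse = ", "),
      sprintf(" (N_T = %d)\n", x$N_T))
  cat(sprintf("  achieved power  : %.4f (target %.2f, alpha %.3g)\n",
              x$achieved_power, x$target_power, x$alpha))
  invisible(x)
}
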