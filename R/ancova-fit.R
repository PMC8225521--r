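#' Fit a one-way ANCOVA by least squares
#'
#' Fits the model `Y_ij = mu_i + sum_k X_kij beta_k + e_ij` with common
#' slopes pooled across groups.  Slopes are `beta_hat = S_XX^{-1} S_XY` from
#' the within-group centered cross-products; intercepts are
#' `mu_hat_i = Ybar_i - sum_k Xbar_ki beta_hat_k`; the error variance
#' estimate is `SSE / nu` with `nu = N_T - G - P`.  The fit also carries the
#' covariance factors `V` (for intercepts) and `V*` (for adjusted means)
#' needed by the Wald test.
#'
#' @param data A data frame holding one row per subject.
#' @param group Name of the group column (integer or string labels; mapped
#'   to 1..G in first-appearance order).
#' @param response Name of the numeric response column.
#' @param covariates Character vector of covariate column names; default all
#'   remaining columns.
#'
#' @return An object of class `"ancova_fit"`: list with `mu_hat`,
#'   `beta_hat`, `adjusted_means`, `sse`, `sigma2_hat`, `nu`, `S_XX`,
#'   `S_XY`, `group_means_x` (P x G), `grand_mean_x`, `V`, `V_star`,
#'   `sizes`, `G`, `P`, `N_T`, `group_levels`.
#'
#' @examples
#' set.seed(1)
#' d <- data.frame(group = rep(1:3, each = 5), x1 = rnorm(15))
#' d$y <- c(10, 12, 14)[d$group] + 2 * d$x1 + rnorm(15)
#' fit <- fit_ancova(d)
#' fit$beta_hat
#' @export
fit_ancova <- function(data, group = "group", response = "y",
                       covariates = NULL) {
  if (!all(c(group, response) %in% names(data)))
    stop("`data` must contain columns '", group, "' and '", response, "'")
  if (is.null(covariates))
    covariates <- setdiff(names(data), c(group, response))
  if (length(covariates) < 1L) stop("at least 1 covariate column is required")
  g <- factor(data[[group]], levels = unique(data[[group]]))
  y <- as.numeric(data[[response]])
  X <- as.matrix(data[covariates])
  storage.mode(X) <- "double"
  if (anyNA(y) || anyNA(X) || anyNA(g)) stop("missing values are not supported")

  G <- nlevels(g)
  P <- ncol(X)
  sizes <- as.integer(table(g))
  if (G < 2L) stop("invalid design: at least 2 groups are required")
  if (any(sizes < 2L)) stop("invalid design: every group needs N_i >= 2")
  N_T <- length(y)
  nu <- N_T - G - P
  if (nu < 1L) stop("too few observations: N_T - G - P < 1")

  Ybar <- as.numeric(tapply(y, g, mean))
  Xbar <- t(rowsum(X, g) / sizes)            # P x G matrix of group means
  yc <- y - Ybar[as.integer(g)]
  Xc <- X - t(Xbar)[as.integer(g), , drop = FALSE]
  S_XX <- crossprod(Xc)
  S_XY <- drop(crossprod(Xc, yc))

  if (kappa(S_XX, exact = TRUE) > 1e10)
    warning("S_XX is ill-conditioned (condition number > 1e10); ",
            "covariates may be nearly collinear")
  beta_hat <- tryCatch(drop(solve(S_XX, S_XY)),
                       error = function(e) stop("collinear covariates: S_XX is singular"))

  mu_hat <- Ybar - drop(crossprod(Xbar, beta_hat))
  M <- colMeans(X)
  Xbar_c <- Xbar - M                          # Xbar - M 1_G'
  adjusted_means <- Ybar - drop(crossprod(Xbar_c, beta_hat))
  sse <- sum(yc^2) - sum(S_XY * beta_hat)
  sigma2_hat <- sse / nu

  D <- diag(1 / sizes, nrow = G)
  V <- D + crossprod(Xbar, solve(S_XX, Xbar))
  V_star <- D + crossprod(Xbar_c, solve(S_XX, Xbar_c))
  dimnames(V) <- dimnames(V_star) <- NULL

  structure(
    list(mu_hat = unname(mu_hat), beta_hat = unname(beta_hat),
         adjusted_means = unname(adjusted_means),
         sse = sse, sigma2_hat = sigma2_hat, nu = nu,
         S_XX = S_XX, S_XY = S_XY,
         group_means_x = unname(Xbar), grand_mean_x = unname(M),
         V = V, V_star = V_star,
         sizes = sizes, G = G, P = P, N_T = N_T,
         group_levels = levels(g)),
    class = "ancova_fit"
  )
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("One-way ANCOVA fit\n")
  cat(sprintf("  groups: %d (%s), covariates: %d, N_T = %d\n",
              x$G, paste(x$group_levels, collapse = ", "), x$P, x$N_T))
  cat("  intercepts mu_hat :", paste(format(round(x$mu_hat, 4)), collapse = ", "), "\n")
  cat("  slopes beta_hat   :", paste(format(round(x$beta_hat, 4)), collapse = ", "), "\n")
  cat("  adjusted means    :", paste(format(round(x$adjusted_means, 4)), collapse = ", "), "\n")
  cat(sprintf("  sigma2_hat = %.6g on nu = %d df\n", x$sigma2_hat, x$nu))
  invisible(x)
}

#' Wald test of a linear hypothesis about treatment effects
#'
#' Computes the Wald statistic
#' `W = (C mu_hat)' (C V C')^{-1} (C mu_hat) / (c * sigma2_hat)` for a
#' contrast matrix `C` with `c` rows, and its p-value from the central
#' `F(c, nu)` null distribution.  Because contrast rows sum to zero, the
#' identical value results from the adjusted-mean form with `V*`; both are
#' computed and cross-checked.  The divisor is the contrast rank `c`, which
#' for the omnibus contrast equals `G - 1`; only this divisor is consistent
#' with the `F(c, nu)` null law for sub-maximal contrasts.
#'
#' @param fit An [fit_ancova()] object.
#' @param contrast Contrast matrix with `G` columns and zero row sums;
#'   default the omnibus contrast.
#' @return An object of classes `"ancova_wald"` and `"htest"` with
#'   `statistic` (W), `parameter` (df), `p.value`, and the contrast used.
#' @examples
#' set.seed(1)
#' d <- data.frame(group = rep(1:3, each = 8), x1 = rnorm(24))
#' d$y <- c(10, 13, 16)[d$group] + 1.5 * d$x1 + rnorm(24, sd = 2)
#' wald_test(fit_ancova(d))
#' @export
wald_test <- function(fit, contrast = NULL) {
  stopifnot(inherits(fit, "ancova_fit"))
  if (is.null(contrast)) contrast <- contr_omnibus(fit$G)
  C <- validate_contrast(contrast, fit$G)
  c_rows <- nrow(C)

  quad <- function(est, Vmat) {
    cm <- drop(C %*% est)
    sol <- tryCatch(solve(C %*% tcrossprod(Vmat, C), cm),
                    error = function(e) stop("degenerate design: C V C' is singular"))
    drop(crossprod(cm, sol))
  }
  q_int <- quad(fit$mu_hat, fit$V)
  q_adj <- quad(fit$adjusted_means, fit$V_star)
  if (abs(q_int - q_adj) > 1e-6 * max(1, abs(q_int)))
    warning("intercept and adjusted-mean forms of the Wald quadratic disagree")

  W <- q_int / (c_rows * fit$sigma2_hat)
  p <- stats::pf(W, c_rows, fit$nu, lower.tail = FALSE)
  structure(
    list(statistic = c(W = W),
         parameter = c(df1 = c_rows, df2 = fit$nu),
         p.value = p,
         method = "Wald test for ANCOVA treatment effects",
         data.name = deparse(substitute(fit)),
         contrast = C),
    class = c("ancova_wald", "htest")
  )
}
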