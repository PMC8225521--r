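# Shared oracles and fixture builders, independent of the package internals.

# Random small ANCOVA dataset with known structure.
random_dataset <- function(seed, G = 3, n = 5, P = 2, mu = seq_len(G) * 2,
                           beta = seq_len(P) / 2, sigma = 1) {
  set.seed(seed)
  g <- rep(seq_len(G), each = n)
  X <- matrix(rnorm(G * n * P), ncol = P,
              dimnames = list(NULL, paste0("x", seq_len(P))))
  y <- mu[g] + drop(X %*% beta) + rnorm(G * n, sd = sigma)
  cbind(data.frame(group = g, y = y), as.data.frame(X))
}

# Brute-force dummy-coded least-squares fit via lm(); the reference for
# intercepts, slopes, SSE.
lm_oracle <- function(dat) {
  P <- sum(grepl("^x", names(dat)))
  fml <- stats::as.formula(paste(
    "y ~ 0 + factor(group) +", paste(paste0("x", seq_len(P)), collapse = "+")))
  fit <- stats::lm(fml, data = dat)
  G <- length(unique(dat$group))
  cf <- stats::coef(fit)
  list(mu = unname(cf[seq_len(G)]), beta = unname(cf[-seq_len(G)]),
       sse = sum(stats::resid(fit)^2), fit = fit)
}

# Classical full-vs-reduced-model ANCOVA F statistic for the omnibus test.
full_reduced_F <- function(dat) {
  P <- sum(grepl("^x", names(dat)))
  xs <- paste(paste0("x", seq_len(P)), collapse = "+")
  full <- stats::lm(stats::as.formula(paste("y ~ factor(group) +", xs)), dat)
  red <- stats::lm(stats::as.formula(paste("y ~", xs)), dat)
  G <- length(unique(dat$group))
  sse_f <- sum(stats::resid(full)^2)
  sse_r <- sum(stats::resid(red)^2)
  df2 <- nrow(dat) - G - P
  ((sse_r - sse_f) / (G - 1)) / (sse_f / df2)
}

# Wald quadratic for an arbitrary contrast straight from lm()'s vcov, as an
# independent route to W.
lm_wald <- function(dat, C) {
  orc <- lm_oracle(dat)
  G <- ncol(C)
  V <- stats::vcov(orc$fit)[seq_len(G), seq_len(G)]
  cm <- drop(C %*% orc$mu)
  s2 <- orc$sse / stats::df.residual(orc$fit)
  drop(crossprod(cm, solve(C %*% (V / s2) %*% t(C), cm))) / (nrow(C) * s2)
}
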