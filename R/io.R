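#' Read an ANCOVA dataset from a delimited text file
#'
#' Reads a header-bearing CSV (comma) or TSV (tab; extensions `.tsv`/`.txt`)
#' file with one row per subject and validates the columns needed by
#' [fit_ancova()].
#'
#' @param file Path to the file.
#' @param group Group column name (default `"group"`).
#' @param response Response column name (default `"y"`).
#' @param covariates Covariate column names; default all remaining columns.
#' @return A data frame with the group column first, then the response, then
#'   the covariates.
#' @export
read_ancova_data <- function(file, group = "group", response = "y",
                             covariates = NULL) {
  if (!file.exists(file)) stop("cannot read file: ", file)
  sep <- if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
  dat <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c(group, response) %in% names(dat)))
    stop("file must contain columns '", group, "' and '", response, "'")
  if (is.null(covariates))
    covariates <- setdiff(names(dat), c(group, response))
  if (!all(covariates %in% names(dat)))
    stop("missing covariate columns: ",
         paste(setdiff(covariates, names(dat)), collapse = ", "))
  dat[c(group, response, covariates)]
}

#' Planning grid over the number of covariates
#'
#' For a marginal response variance `sigma2_Y` and correlation `rho`, the
#' ANCOVA error variance is `sigma2 = (1 - rho^2) * sigma2_Y`.  For each `P`
#' this computes the minimum balanced total sample size and the achieved
#' power under the three planning methods (ANOVA reference, approximate
#' ANCOVA, exact ANCOVA), reproducing the deterministic columns of a
#' power/sample-size planning table.
#'
#' @param mu Group intercepts.
#' @param sigma2_Y Marginal variance of the response, `> 0`.
#' @param rho Response-covariate correlation in `[0, 1)`.
#' @param P Integer vector of covariate counts (default `1:10`).
#' @param alpha Significance level.
#' @param target_power Target power.
#' @param nodes Quadrature nodes for the exact method.
#' @return A data frame with one row per `P`: columns `P`, `N_TO`, `power_O`,
#'   `N_TA`, `power_A`, `N_TE`, `power_E`.
#' @examples
#' power_table_grid(c(400, 450, 500), 10000, rho = 0.5, P = 1:2)
#' @export
power_table_grid <- function(mu, sigma2_Y, rho, P = 1:10, alpha = 0.05,
                             target_power = 0.80, nodes = 128L) {
  if (sigma2_Y <= 0) stop("`sigma2_Y` must be positive")
  if (rho < 0 || rho >= 1) stop("invalid correlation: `rho` must lie in [0, 1)")
  sigma2 <- (1 - rho^2) * sigma2_Y
  eff <- ancova_effect(mu, sigma2)
  rows <- lapply(as.integer(P), function(p) {
    so <- solve_sample_size("anova", eff, P = p, target_power = target_power,
                            alpha = alpha, rho = rho)
    sa <- solve_sample_size("approx", eff, P = p, target_power = target_power,
                            alpha = alpha)
    se <- solve_sample_size("exact", eff, P = p, target_power = target_power,
                            alpha = alpha, nodes = nodes)
    data.frame(P = p,
               N_TO = so$N_T, power_O = so$achieved_power,
               N_TA = sa$N_T, power_A = sa$achieved_power,
               N_TE = se$N_T, power_E = se$achieved_power)
  })
  do.call(rbind, rows)
}

#' Write small synthetic example datasets and a parameter manifest
#'
#' Generates small ANCOVA datasets (3 groups of 10, one with `P = 1` and one
#' with `P = 2` covariates) from known population parameters using the
#' Monte-Carlo engine, writes them as CSV under `out_dir`, and writes a
#' `manifest.csv` recording the true intercepts, error variance, slopes and
#' implied correlation of each file.  Rerunning with the same seed rewrites
#' identical files.
#'
#' @param seed Master seed.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(
    list(name = "depression_p1", n = 10, P = 1,
         mu = c(7.5, 12.0, 14.0), sigma2 = 29, rho = 0.5),
    list(name = "depression_p2", n = 10, P = 2,
         mu = c(7.5, 12.0, 14.0), sigma2 = 29, rho = 0.5))
  paths <- character(0)
  manifest <- list()
  for (k in seq_along(cfg)) {
    cc <- cfg[[k]]
    d <- ancova_design(sizes = cc$n, G = length(cc$mu), P = cc$P)
    sp <- simulation_spec(d, mu = cc$mu, sigma2 = cc$sigma2, rho = cc$rho,
                          n_reps = 100L, seed = seed + k)
    dat <- generate_dataset(sp, rep_index = 1L)
    f <- file.path(out_dir, paste0(cc$name, ".csv"))
    utils::write.csv(dat, f, row.names = FALSE)
    paths <- c(paths, f)
    manifest[[k]] <- data.frame(
      file = basename(f), G = d$G, P = cc$P, n_per_group = cc$n,
      mu = paste(cc$mu, collapse = ";"), sigma2 = cc$sigma2,
      beta = paste(signif(sp$beta, 10), collapse = ";"),
      rho = sp$rho, sigma2_Y = sp$sigma2_Y, seed = seed + k)
  }
  mf <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, manifest), mf, row.names = FALSE)
  invisible(c(paths, mf))
}
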