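#' Maximum-likelihood fit of a single normal distribution
#'
#' The one-cluster null model of the phenotype distribution. The variance is
#' the MLE (divisor `n`), floored at `vfloor_rel` times the sample variance
#' (or a tiny absolute floor when the sample is degenerate) so the
#' log-likelihood stays finite.
#'
#' @param x Numeric vector, length >= 2.
#' @param vfloor_rel Relative variance floor (see [fit_mixture2()]).
#' @return List with `mu`, `sigma2`, `loglik`, and `n`.
#' @export
fit_normal <- function(x, vfloor_rel = 1e-6) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 observations")
  n <- length(x)
  mu <- mean(x)
  s2 <- sum((x - mu)^2) / n
  floor_val <- if (s2 > 0) vfloor_rel * s2 else 1e-12
  if (s2 < floor_val || s2 == 0) {
    warning("zero variance; variance floor applied")
    s2 <- floor_val
  }
  ll <- sum(stats::dnorm(x, mu, sqrt(s2), log = TRUE))
  list(mu = mu, sigma2 = s2, loglik = ll, n = n)
}

#' Fit a two-component normal mixture by EM with restarts
#'
#' The two-cluster alternative model. EM is run from a schedule of starting
#' points — the single-normal MLE itself (a fixed point, which guarantees the
#' mixture log-likelihood is never below the one-cluster log-likelihood), a
#' symmetric split of that solution, a lower/upper-half quantile split, and
#' random assignments — and the best solution is kept. Component variances
#' are floored at `vfloor_rel` times the sample variance to stop the
#' likelihood diverging when a component collapses onto a data point.
#'
#' @param x Numeric vector, length >= 4.
#' @param restarts Total number of EM starts (default 10).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param maxit Maximum EM iterations per start (default 1000).
#' @param vfloor_rel Relative variance floor (default 1e-6).
#' @param var_ratio_min Smallest allowed ratio between the component
#'   variances (default 0.01). This Hathaway-style relative constraint keeps
#'   the likelihood bounded away from spurious solutions in which one
#'   component collapses onto a single observation; genuinely tight clusters
#'   with comparable spreads (including two point masses) remain feasible.
#' @param seed Optional integer seed for the random restarts.
#' @return List of class `mixture2_fit`: `weights`, `means`, `variances`,
#'   `loglik`, `n_restarts_used`, `converged`, plus the nested
#'   `normal_loglik` and the `variance_floor` actually used.
#' @export
fit_mixture2 <- function(x, restarts = 10, tol = 1e-8, maxit = 1000,
                         vfloor_rel = 1e-6, var_ratio_min = 0.01,
                         seed = NULL) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("too few observations for two components")
  if (!is.null(seed)) set.seed(seed)
  fit <- cpp_fit_mixture2(x, as.integer(restarts), tol, as.integer(maxit),
                          vfloor_rel, var_ratio_min)
  structure(fit, class = "mixture2_fit")
}

#' Likelihood-ratio statistic for two clusters versus one
#'
#' \eqn{\lambda = 2(\ell_{mix} - \ell_{normal})}, clipped at zero. Because
#' the single normal is nested in the mixture and the EM restart schedule
#' includes the nested solution, the statistic is non-negative by
#' construction.
#'
#' @inheritParams fit_mixture2
#' @return The scalar statistic.
#' @export
lrt_statistic <- function(x, restarts = 10, tol = 1e-8, maxit = 1000,
                          vfloor_rel = 1e-6, var_ratio_min = 0.01,
                          seed = NULL) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("too few observations for two components")
  if (!is.null(seed)) set.seed(seed)
  cpp_lambda(x, as.integer(restarts), tol, as.integer(maxit), vfloor_rel,
             var_ratio_min)
}

#' Parametric-bootstrap test of two phenotype clusters versus one
#'
#' The mixture-vs-normal likelihood-ratio statistic has no usable asymptotic
#' null distribution (the mixture weight sits on the boundary), so the null
#' is built empirically: `B` datasets of the observed size are simulated from
#' the fitted single normal, each is refit with the identical EM
#' configuration, and the p-value is the add-one estimator
#' \eqn{(n_{exceed} + 1)/(B + 1)} — never exactly zero, with attainable
#' minimum \eqn{1/(B+1)}.
#'
#' @inheritParams fit_mixture2
#' @param B Number of bootstrap datasets (default 100000, as in a full-scale
#'   analysis; reduce for interactive work).
#' @param seed Integer seed; required for a reproducible null.
#' @return List of class `mixture_lrt`: `lambda_obs`, `B`, `n_exceed`,
#'   `p_value`, `seed`, plus the two fitted models.
#' @export
bootstrap_cluster_test <- function(x, B = 100000, seed = 1, restarts = 10,
                                   tol = 1e-8, maxit = 1000,
                                   vfloor_rel = 1e-6, var_ratio_min = 0.01) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("too few observations for two components")
  if (B < 1) stop("B must be >= 1")
  set.seed(seed)
  null_fit <- fit_normal(x, vfloor_rel)
  mix_fit <- fit_mixture2(x, restarts, tol, maxit, vfloor_rel, var_ratio_min)
  lambda_obs <- max(0, 2 * (mix_fit$loglik - null_fit$loglik))
  lambdas <- cpp_bootstrap_lambdas(length(x), null_fit$mu, null_fit$sigma2,
                                   as.integer(B), as.integer(restarts), tol,
                                   as.integer(maxit), vfloor_rel,
                                   var_ratio_min)
  n_exceed <- sum(lambdas >= lambda_obs)
  structure(list(lambda_obs = lambda_obs, B = as.integer(B),
                 n_exceed = n_exceed,
                 p_value = (n_exceed + 1) / (B + 1),
                 seed = seed, normal_fit = null_fit, mixture_fit = mix_fit),
            class = "mixture_lrt")
}

#' @export
print.mixture_lrt <- function(x, ...) {
  cat(sprintf("Two-cluster vs one-cluster parametric-bootstrap LRT\n"))
  cat(sprintf("  lambda = %.4f, B = %d, n_exceed = %d, p = %.6g\n",
              x$lambda_obs, x$B, x$n_exceed, x$p_value))
  invisible(x)
}

#' Select a maximal subset of minimally related individuals
#'
#' Keeps individuals so that no retained pair is more closely related than
#' `max_phi` (default 0.125, the avuncular kinship coefficient — i.e. "no
#' relationships closer than avuncular"). Pairs above the threshold form a
#' conflict graph; the individual involved in the most conflicts is removed
#' repeatedly until none remain. Ties are broken by removing the
#' lexicographically last identifier, which makes the result deterministic.
#' The greedy rule yields a maximal (not always maximum) subset.
#'
#' @param ids Character vector of individual identifiers.
#' @param kinship Kinship object from [kinship_from_pedigree()], or a named
#'   symmetric matrix of kinship coefficients covering `ids`.
#' @param max_phi Largest tolerated pairwise kinship coefficient.
#' @return Character vector of retained identifiers (in input order).
#' @export
min_related_subset <- function(ids, kinship, max_phi = 0.125) {
  if (length(ids) == 0L) return(character(0))
  phi <- if (inherits(kinship, "kinship_matrix")) kinship$phi else kinship
  if (!all(ids %in% rownames(phi))) stop("kinship must cover all individuals")
  ids <- as.character(ids)
  keep <- ids
  repeat {
    sub <- phi[keep, keep, drop = FALSE]
    conflict <- sub > max_phi
    diag(conflict) <- FALSE
    deg <- rowSums(conflict)
    if (all(deg == 0)) break
    worst <- keep[deg == max(deg)]
    drop_id <- worst[order(worst)][length(worst)]
    keep <- setdiff(keep, drop_id)
  }
  ids[ids %in% keep]
}

#' Size-matched subsampling comparison of clustering strength
#'
#' Emulates comparing a small, strongly clustered sample against groups with
#' larger samples: draws `m` simple random subsamples of size `k` from the
#' pool of (minimally related) phenotype values, computes the
#' mixture-vs-normal statistic on each, and counts how many reach or exceed a
#' reference statistic (e.g. the lambda observed in the small clustered
#' group).
#'
#' @param x_pool Numeric phenotype values of the pool.
#' @param lambda_ref Reference statistic to compare against.
#' @param m Number of subsamples (default 1000).
#' @param k Subsample size (default 8).
#' @inheritParams fit_mixture2
#' @return List of class `subsample_result`: `n_subsamples`,
#'   `subsample_size`, `statistics`, `n_more_extreme`, `seed`.
#' @export
subsample_comparison <- function(x_pool, lambda_ref, m = 1000, k = 8,
                                 seed = 1, restarts = 10, tol = 1e-8,
                                 maxit = 1000, vfloor_rel = 1e-6,
                                 var_ratio_min = 0.01) {
  x_pool <- as.numeric(x_pool)
  if (length(x_pool) < k) stop("pool smaller than subsample size")
  set.seed(seed)
  stats_vec <- cpp_subsample_lambdas(x_pool, as.integer(m), as.integer(k),
                                     as.integer(restarts), tol,
                                     as.integer(maxit), vfloor_rel,
                                     var_ratio_min)
  structure(list(n_subsamples = as.integer(m), subsample_size = as.integer(k),
                 statistics = stats_vec,
                 n_more_extreme = sum(stats_vec >= lambda_ref),
                 lambda_ref = lambda_ref, seed = seed),
            class = "subsample_result")
}
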