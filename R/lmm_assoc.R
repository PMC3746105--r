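#' Rank-based inverse-normal transformation
#'
#' Maps phenotype values to a standard normal scale: ranks (average rank for
#' ties) are transformed through \eqn{\Phi^{-1}((r - 0.5)/n)}. Order is
#' preserved, so the transform is invariant to monotone transformations of
#' the raw values (absent ties).
#'
#' @param x Numeric vector, length >= 2, with some variation.
#' @return Numeric vector of the same length.
#' @export
quantile_normalize <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 observations")
  if (length(unique(x)) == 1L) stop("phenotype has no variation")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 0.5) / length(x))
}

#' Adjusted age covariate
#'
#' Two times age divided by the species' maximum age, giving a unitless value
#' in `[0, 2]` that is comparable across species with different lifespans.
#'
#' @param age Age in years, `0 <= age <= max_age`.
#' @param max_age Species maximum age in years (> 0).
#' @return Numeric vector in `[0, 2]`.
#' @export
adjusted_age <- function(age, max_age) {
  if (any(max_age <= 0)) stop("max_age must be positive")
  if (any(age < 0 | age > max_age)) stop("age must lie in [0, max_age]")
  2 * age / max_age
}

#' Encode a two-species label as a categorical phenotype
#'
#' For the interspecific test the phenotype is the species itself, coded 2
#' for the brown-iris species ("black") and 1 for the blue-iris species
#' ("blue-eyed"), used raw (not quantile-normalized).
#'
#' @param labels Character vector of species labels.
#' @param levels Named numeric vector mapping label -> code; default
#'   `c(black = 2, "blue-eyed" = 1)`.
#' @return Numeric vector of codes.
#' @export
encode_species <- function(labels, levels = c(black = 2, "blue-eyed" = 1)) {
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), names(levels))
  if (length(unknown)) stop("unknown species label: ",
                            paste(unknown, collapse = ", "))
  y <- unname(levels[labels])
  if (length(unique(y)) == 1L) stop("phenotype has no variation")
  y
}

# Profiled REML criterion for the variance ratio, on the eigenbasis of K.
# yt, Xt are U'y and U'X; d the eigenvalues of K.
.reml_crit <- function(loglam, yt, Xt, d, reml = TRUE) {
  v <- exp(loglam) * d + 1
  sw <- 1 / sqrt(v)
  Xw <- Xt * sw
  yw <- yt * sw
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw)) return(-Inf)
  res <- qr.resid(qrX, yw)
  rss <- sum(res^2)
  n <- length(yt); p <- ncol(Xt)
  ldV <- sum(log(v))
  if (reml) {
    ldX <- 2 * sum(log(abs(diag(qr.R(qrX)))))
    -0.5 * (ldV + ldX + (n - p) * log(rss))
  } else {
    -0.5 * (ldV + n * log(rss))
  }
}

#' Linear mixed-model Wald association test
#'
#' Fits \eqn{y = W\alpha + x\beta + u + \epsilon} with
#' \eqn{u \sim N(0, \sigma_g^2 K)} and
#' \eqn{\epsilon \sim N(0, \sigma_e^2 I)}. The variance ratio
#' \eqn{\lambda = \sigma_g^2 / \sigma_e^2} is estimated by REML through a
#' one-dimensional Brent search over \eqn{\log\lambda \in [-10, 10]}, made
#' cheap by rotating the model onto the eigenbasis of `K` so every candidate
#' \eqn{\lambda} costs one weighted least squares solve. \eqn{\hat\beta} and
#' its standard error come from generalized least squares at
#' \eqn{\hat\lambda}; the Wald statistic \eqn{\hat\beta^2 / se^2} is referred
#' to chi-square(1) (a large-sample reference — interpret small-sample
#' p-values with care).
#'
#' Missing genotype values are mean-imputed per variant (`missing =
#' "impute"`, the default) or the individuals dropped (`missing = "drop"`).
#' A focal predictor that is constant after missing-data handling yields an
#' all-`NA` result row rather than an error, mirroring how monomorphic
#' variants are reported.
#'
#' @param y Numeric phenotype vector.
#' @param x Focal predictor (genotype dosages in 0/1/2, possibly with `NA`,
#'   or a covariate).
#' @param W Fixed-effect design matrix including the intercept; default
#'   intercept only.
#' @param K Relatedness matrix (from [relatedness()]), or `NULL` for the
#'   identity.
#' @param lambda Fix the variance ratio instead of estimating it (e.g. `0`
#'   reduces the fit to ordinary least squares); `NULL` (default) estimates
#'   by REML (or ML with `reml = FALSE`).
#' @param reml Use REML (default) or ML for the variance ratio.
#' @param missing `"impute"` or `"drop"`.
#' @param eigen_K Optional precomputed `eigen(K, symmetric = TRUE)`; lets a
#'   scan over many variants factor `K` once.
#' @param variant_id Label copied into the result.
#' @return One-row data frame: `variant`, `beta`, `se`, `wald`, `p`,
#'   `lambda_hat`, `n_used`.
#' @export
lmm_wald <- function(y, x, W = NULL, K = NULL, lambda = NULL, reml = TRUE,
                     missing = c("impute", "drop"), eigen_K = NULL,
                     variant_id = "x") {
  missing <- match.arg(missing)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  W <- as.matrix(W)
  if (nrow(W) != n || length(x) != n) stop("dimension mismatch")
  x <- as.numeric(x)

  keep <- rep(TRUE, n)
  if (anyNA(x)) {
    if (missing == "impute") {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
    } else {
      keep <- !is.na(x)
    }
  }
  na_row <- data.frame(variant = variant_id, beta = NA_real_, se = NA_real_,
                       wald = NA_real_, p = NA_real_, lambda_hat = NA_real_,
                       n_used = sum(keep), stringsAsFactors = FALSE)
  if (sum(keep) < ncol(W) + 2L) return(na_row)
  yk <- y[keep]; xk <- x[keep]; Wk <- W[keep, , drop = FALSE]
  if (stats::var(xk) == 0) return(na_row)

  if (is.null(K)) {
    U <- diag(length(yk))
    d <- rep(0, length(yk))  # identity handled as lambda*0 + 1
    yt <- yk
    Xt <- cbind(Wk, x = xk)
  } else {
    Kk <- K[keep, keep, drop = FALSE]
    e <- if (!is.null(eigen_K) && all(keep)) eigen_K
         else eigen(Kk, symmetric = TRUE)
    d <- pmax(e$values, 0)
    yt <- crossprod(e$vectors, yk)[, 1]
    Xt <- crossprod(e$vectors, cbind(Wk, x = xk))
  }
  X_unrot <- cbind(Wk, x = xk)
  if (qr(X_unrot)$rank < ncol(X_unrot)) stop("singular fixed-effect design")

  if (is.null(lambda)) {
    if (is.null(K) || all(d == d[1])) {
      lam_hat <- 0  # ratio not identifiable when K is (a multiple of) I
    } else {
      opt <- stats::optimize(.reml_crit, c(-10, 10), yt = yt, Xt = Xt, d = d,
                             reml = reml, maximum = TRUE, tol = 1e-8)
      lam_hat <- exp(opt$maximum)
    }
  } else {
    lam_hat <- lambda
  }

  v <- lam_hat * d + 1
  sw <- 1 / sqrt(v)
  Xw <- Xt * sw
  yw <- yt * sw
  XtX <- crossprod(Xw)
  XtXinv <- solve(XtX)
  beta_all <- XtXinv %*% crossprod(Xw, yw)
  res <- yw - Xw %*% beta_all
  nk <- length(yw); p <- ncol(Xw)
  sigma2_e <- sum(res^2) / (nk - p)
  j <- ncol(Xw)  # focal predictor is the last column
  beta <- beta_all[j]
  se <- sqrt(sigma2_e * XtXinv[j, j])
  wald <- (beta / se)^2
  data.frame(variant = variant_id, beta = beta, se = se, wald = wald,
             p = stats::pchisq(wald, df = 1, lower.tail = FALSE),
             lambda_hat = lam_hat, n_used = nk, stringsAsFactors = FALSE)
}

#' Screen candidate covariates one at a time
#'
#' Each candidate column is tested separately as the focal fixed effect in
#' the mixed model (intercept plus the candidate, kinship random effect);
#' candidates with Wald `p < alpha` are retained alongside the intercept in
#' the returned design.
#'
#' @param y Numeric phenotype vector.
#' @param candidates Matrix (or data frame) of candidate covariates, one per
#'   column, excluding the intercept.
#' @param K Relatedness matrix or `NULL`.
#' @param alpha Retention threshold (default 0.05).
#' @return List: `design` (matrix with intercept and retained columns),
#'   `screen` (per-candidate association rows).
#' @export
screen_covariates <- function(y, candidates, K = NULL, alpha = 0.05) {
  candidates <- as.matrix(candidates)
  if (ncol(candidates) > 0L && is.null(colnames(candidates)))
    colnames(candidates) <- paste0("cov", seq_len(ncol(candidates)))
  if (ncol(candidates) == 0L) {
    design <- cbind(intercept = rep(1, length(y)))
    return(list(design = design, screen = NULL, retained = character(0),
                alpha = alpha))
  }
  eig <- if (!is.null(K)) eigen(K, symmetric = TRUE) else NULL
  rows <- lapply(colnames(candidates), function(nm)
    lmm_wald(y, candidates[, nm], K = K, eigen_K = eig, variant_id = nm))
  screen <- do.call(rbind, rows)
  kept <- screen$variant[!is.na(screen$p) & screen$p < alpha]
  design <- cbind(intercept = rep(1, length(y)))
  for (nm in kept) {  # skip columns collinear with what is already retained
    cand <- cbind(design, candidates[, nm])
    if (qr(cand)$rank == ncol(cand)) {
      design <- cand
      colnames(design)[ncol(design)] <- nm
    } else {
      kept <- setdiff(kept, nm)
    }
  }
  list(design = design, screen = screen, retained = kept, alpha = alpha)
}

#' Per-variant association scan
#'
#' Runs [lmm_wald()] for every variant column; monomorphic (or otherwise
#' untestable) variants are reported as `NA` rows rather than dropped, so the
#' output has one row per input variant in input order.
#'
#' @param y Numeric phenotype vector.
#' @param genotypes Matrix of dosages (individuals x variants, values
#'   0/1/2/`NA`), with variant ids as column names.
#' @param W Fixed-effect design (intercept first); default intercept only.
#' @param K Relatedness matrix or `NULL` for identity.
#' @inheritParams lmm_wald
#' @return Data frame with columns `variant beta se wald p lambda_hat
#'   n_used`.
#' @export
association_scan <- function(y, genotypes, W = NULL, K = NULL, reml = TRUE,
                             missing = c("impute", "drop")) {
  missing <- match.arg(missing)
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) < 1L) stop("need at least one variant")
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("v", seq_len(ncol(genotypes)))
  eig <- if (!is.null(K)) eigen(K, symmetric = TRUE) else NULL
  rows <- lapply(colnames(genotypes), function(nm)
    lmm_wald(y, genotypes[, nm], W = W, K = K, reml = reml, missing = missing,
             eigen_K = eig, variant_id = nm))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
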