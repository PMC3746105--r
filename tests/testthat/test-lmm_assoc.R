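test_that("quantile normalization maps ranks through the normal quantiles", {
  got <- quantile_normalize(c(3, 1, 2))
  expect_equal(got, qnorm(c(5 / 6, 1 / 6, 3 / 6)), tolerance = 1e-12)
  # monotone-transform invariance without ties
  set.seed(8)
  x <- rnorm(25)
  expect_equal(quantile_normalize(exp(x)), quantile_normalize(x))
  # tie convention: average ranks
  expect_equal(quantile_normalize(c(5, 5, 7)),
               qnorm(c(1.5, 1.5, 3) / 3 - 0.5 / 3))
  expect_error(quantile_normalize(c(4, 4)), "no variation")
  expect_error(quantile_normalize(3), "at least 2")
})

test_that("adjusted age follows 2*age/max_age with range checks", {
  expect_equal(adjusted_age(10, 20), 1)
  expect_equal(adjusted_age(20, 20), 2)
  expect_equal(adjusted_age(0, 20), 0)
  expect_error(adjusted_age(5, 0), "positive")
  expect_error(adjusted_age(25, 20), "\\[0, max_age\\]")
})

test_that("species labels encode as 2 (black) / 1 (blue-eyed)", {
  expect_equal(encode_species(c("black", "blue-eyed")), c(2, 1))
  set.seed(2)
  labs <- sample(c("black", "blue-eyed"), 10, replace = TRUE)
  perm <- sample(10)
  expect_equal(encode_species(labs)[perm], encode_species(labs[perm]))
  expect_error(encode_species(c("black", "black")), "no variation")
  expect_error(encode_species(c("black", "ringtail")), "unknown species")
})

test_that("mixed model with K = I and lambda = 0 reproduces OLS exactly", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 30
    W <- cbind(1, rnorm(n))
    x <- rnorm(n)
    y <- 0.3 * x + W %*% c(1, -0.5) + rnorm(n)
    got <- lmm_wald(y, x, W = W, K = NULL, lambda = 0)
    fit <- lm(y ~ 0 + W + x)
    beta <- coef(fit)[["x"]]
    se <- sqrt(diag(vcov(fit)))[["x"]]
    expect_equal(got$beta, beta, tolerance = 1e-10)
    expect_equal(got$se, se, tolerance = 1e-10)
    expect_equal(got$p, pchisq((beta / se)^2, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("REML criterion on the eigenbasis equals a direct-matrix evaluation", {
  set.seed(31)
  ped <- gen_pedigree(synth_config(pedigree = list(
    n_founders = 8, n_generations = 2, n_offspring_per_gen = 8)), seed = 4)
  K <- relatedness(kinship_from_pedigree(ped))
  n <- nrow(K)
  y <- rnorm(n); x <- rnorm(n)
  X <- cbind(1, x)
  e <- eigen(K, symmetric = TRUE)
  yt <- crossprod(e$vectors, y)[, 1]
  Xt <- crossprod(e$vectors, X)
  d <- pmax(e$values, 0)
  direct_reml <- function(lam) {
    V <- lam * K + diag(n)
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    rss <- as.numeric(t(r) %*% Vi %*% r)
    -0.5 * (determinant(V)$modulus[1] + determinant(XtVX)$modulus[1] +
              (n - ncol(X)) * log(rss))
  }
  for (lam in c(0.01, 0.5, 2, 10)) {
    eig_val <- blueiris:::.reml_crit(log(lam), yt, Xt, d, reml = TRUE)
    expect_equal(eig_val, direct_reml(lam), tolerance = 1e-8)
  }
})

test_that("Wald p-values are invariant to affine rescaling of x and y", {
  set.seed(41)
  ped <- gen_pedigree(synth_config(pedigree = list(
    n_founders = 8, n_generations = 2, n_offspring_per_gen = 10)), seed = 6)
  K <- relatedness(kinship_from_pedigree(ped))
  n <- nrow(K)
  x <- rbinom(n, 2, 0.4)
  y <- 0.5 * x + rnorm(n)
  p0 <- lmm_wald(y, x, K = K)$p
  expect_equal(lmm_wald(y, 10 * x - 3, K = K)$p, p0, tolerance = 1e-6)
  expect_equal(lmm_wald(5 * y + 2, x, K = K)$p, p0, tolerance = 1e-6)
})

test_that("monomorphic or missing-heavy predictors give NA rows, not errors", {
  set.seed(51)
  n <- 20
  y <- rnorm(n)
  res <- lmm_wald(y, rep(1, n))
  expect_true(is.na(res$p) && is.na(res$beta))
  # mean imputation matches doing it by hand
  x <- rbinom(n, 2, 0.5); x[c(3, 7)] <- NA
  xi <- x; xi[is.na(xi)] <- mean(x, na.rm = TRUE)
  expect_equal(lmm_wald(y, x, missing = "impute")$p,
               lmm_wald(y, xi)$p)
  # dropping individuals instead
  drop_res <- lmm_wald(y, x, missing = "drop")
  expect_equal(drop_res$n_used, n - 2L)
  expect_error(lmm_wald(y, cbind(rnorm(n)), W = cbind(1, 1:n, 2 * (1:n))),
               "singular")
})

test_that("covariate screening keeps planted effects and drops noise", {
  set.seed(61)
  ped <- gen_pedigree(synth_config(pedigree = list(
    n_founders = 10, n_generations = 2, n_offspring_per_gen = 15)), seed = 3)
  K <- relatedness(kinship_from_pedigree(ped))
  n <- nrow(K)
  strong <- rnorm(n)
  noise <- rnorm(n)
  y <- 2 * strong + rnorm(n)
  sc <- screen_covariates(y, cbind(strong = strong, noise = noise), K = K)
  expect_true("strong" %in% sc$retained)
  expect_equal(colnames(sc$design)[1], "intercept")
  # no candidates -> intercept only
  sc0 <- screen_covariates(y, matrix(numeric(0), nrow = n, ncol = 0), K = K)
  expect_equal(colnames(sc0$design), "intercept")
})

test_that("association scan reports every variant, in order, NA for monomorphic", {
  set.seed(71)
  ped <- gen_pedigree(synth_config(pedigree = list(
    n_founders = 10, n_generations = 2, n_offspring_per_gen = 15)), seed = 8)
  gt <- gen_genotypes(ped, synth_config(genetics = list(
    n_variants = 6, causal_index = 2, founder_freq = 0.5, beta = 1.5)))
  ph <- gen_phenotypes(ped, gt, synth_config(genetics = list(
    n_variants = 6, causal_index = 2, founder_freq = 0.5, beta = 1.5)))
  G <- gt$dosages
  G[, 4] <- 0L  # monomorphic
  res <- association_scan(ph$y, G, K = ph$K)
  expect_equal(res$variant, colnames(G))
  expect_true(is.na(res$p[4]))
  expect_false(anyNA(res$p[-4]))
  # order invariance
  perm <- c(3, 1, 6, 2, 5, 4)
  res2 <- association_scan(ph$y, G[, perm], K = ph$K)
  expect_equal(res2$p, res$p[perm])
  # all monomorphic -> all NA
  allmono <- matrix(2L, nrow(G), 3, dimnames = list(rownames(G), paste0("m", 1:3)))
  expect_true(all(is.na(association_scan(ph$y, allmono, K = ph$K)$p)))
})

test_that("lambda_hat tracks the simulated variance ratio", {
  set.seed(81)
  cfg <- synth_config(pedigree = list(n_founders = 12, n_generations = 3,
                                      n_offspring_per_gen = 20),
                      genetics = list(n_variants = 1, causal_index = 1,
                                      founder_freq = 0.5, beta = 0))
  ped <- gen_pedigree(cfg)
  lam_hats <- sapply(c(0.2, 5), function(ratio) {
    cfg$phenotype$sigma2_g <- ratio
    cfg$phenotype$sigma2_e <- 1
    mean(replicate(20, {
      gt <- gen_genotypes(ped, cfg)
      ph <- gen_phenotypes(ped, gt, cfg)
      lmm_wald(ph$y, gt$dosages[, 1], K = ph$K)$lambda_hat
    }))
  })
  expect_lt(lam_hats[1], lam_hats[2])  # monotone recovery
})
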