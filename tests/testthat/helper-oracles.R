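# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the colour oracle derives its RGB->XYZ matrix
# from the sRGB primary chromaticities instead of hard-coded coefficients,
# and the mixture oracle maximizes the likelihood directly (grid + simplex
# polish) rather than by EM.

# sRGB (8-bit) -> CIE L*a*b*, scalar, from the published chromaticities:
# primaries R(0.64, 0.33), G(0.30, 0.60), B(0.15, 0.06), white D65
# (x = 0.3127, y = 0.3290), 2 degree observer.
oracle_srgb_to_lab <- function(rgb) {
  prim <- rbind(c(0.64, 0.33), c(0.30, 0.60), c(0.15, 0.06))
  wxy <- c(0.3127, 0.3290)
  Pxyz <- t(apply(prim, 1, function(p) c(p[1] / p[2], 1, (1 - p[1] - p[2]) / p[2])))
  Wxyz <- c(wxy[1] / wxy[2], 1, (1 - wxy[1] - wxy[2]) / wxy[2])
  M <- t(Pxyz * solve(t(Pxyz), Wxyz))
  out <- matrix(NA_real_, nrow = if (is.null(dim(rgb))) 1 else nrow(rgb), ncol = 3)
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  for (i in seq_len(nrow(rgb))) {
    lin <- numeric(3)
    for (k in 1:3) {
      c8 <- rgb[i, k] / 255
      lin[k] <- if (c8 <= 0.04045) c8 / 12.92 else ((c8 + 0.055) / 1.055)^2.4
    }
    xyz <- as.numeric(M %*% lin) / Wxyz
    fv <- numeric(3)
    for (k in 1:3) {
      fv[k] <- if (xyz[k] > (6 / 29)^3) xyz[k]^(1 / 3)
               else xyz[k] * (29 / 6)^2 / 3 + 4 / 29
    }
    out[i, ] <- c(116 * fv[2] - 16, 500 * (fv[1] - fv[2]), 200 * (fv[2] - fv[3]))
  }
  colnames(out) <- c("L", "a", "b")
  out
}

# Direct maximization of the two-component mixture log-likelihood: coarse
# grid over (w, mu1, mu2, s1, s2) followed by Nelder-Mead polish from the
# best grid points, over the same feasible set the EM uses (variance floor
# plus the relative variance-ratio constraint, applied by projection).
oracle_mix2_loglik <- function(x, vfloor_rel = 1e-6, var_ratio_min = 0.01) {
  n <- length(x)
  s2 <- sum((x - mean(x))^2) / n
  vfloor <- if (s2 > 0) vfloor_rel * s2 else 1e-12
  project <- function(v1, v2) {
    v1 <- max(v1, vfloor); v2 <- max(v2, vfloor)
    if (v1 < var_ratio_min * v2) v1 <- var_ratio_min * v2
    else if (v2 < var_ratio_min * v1) v2 <- var_ratio_min * v1
    c(v1, v2)
  }
  mix_ll <- function(w, m1, m2, v1, v2) {
    v <- project(v1, v2)
    sum(log(w * dnorm(x, m1, sqrt(v[1])) + (1 - w) * dnorm(x, m2, sqrt(v[2]))))
  }
  mus <- unique(quantile(x, seq(0, 1, length.out = 9)))
  vs <- s2 * c(0.01, 0.05, 0.2, 0.5, 1, 2)
  vs <- pmax(vs, vfloor)
  ws <- seq(0.1, 0.9, by = 0.2)
  grid <- expand.grid(w = ws, m1 = mus, m2 = mus, v1 = vs, v2 = vs)
  ll <- mapply(mix_ll, grid$w, grid$m1, grid$m2, grid$v1, grid$v2)
  top <- order(ll, decreasing = TRUE)[1:10]
  best <- max(ll)
  for (i in top) {
    par0 <- c(qlogis(grid$w[i]), grid$m1[i], grid$m2[i],
              log(grid$v1[i]), log(grid$v2[i]))
    neg <- function(p)
      -mix_ll(plogis(p[1]), p[2], p[3], exp(p[4]), exp(p[5]))
    opt <- optim(par0, neg, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    best <- max(best, -opt$value)
  }
  best
}

# Gene-dropping estimate of the kinship coefficient between two pedigree
# members: drop unique founder alleles down the pedigree many times and
# count identity-by-descent between randomly sampled alleles.
oracle_genedrop_phi <- function(ped, id1, id2, n_drops = 20000) {
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  same <- 0L
  for (r in seq_len(n_drops)) {
    alleles <- matrix(0L, nrow(ped), 2)
    next_allele <- 1L
    for (i in seq_len(nrow(ped))) {
      for (a in 1:2) {
        parent <- if (a == 1) ped$sire[i] else ped$dam[i]
        if (is.na(parent)) {
          alleles[i, a] <- next_allele
          next_allele <- next_allele + 1L
        } else {
          alleles[i, a] <- alleles[idx[[parent]], sample(1:2, 1)]
        }
      }
    }
    a1 <- alleles[idx[[id1]], sample(1:2, 1)]
    a2 <- alleles[idx[[id2]], sample(1:2, 1)]
    if (a1 == a2) same <- same + 1L
  }
  same / n_drops
}

# Hand-checkable six-member pedigree used in several tests:
# founders gf+gm -> sibs s1 (M), s2 (F), s3 (M); s2 x uf -> niece n1.
# So s1/s2 are full sibs, s1/n1 avuncular.
toy_pedigree6 <- function() {
  pedigree(id   = c("gf", "gm", "uf", "s1", "s2", "s3", "n1"),
           sire = c(NA,   NA,   NA,   "gf", "gf", "gf", "uf"),
           dam  = c(NA,   NA,   NA,   "gm", "gm", "gm", "s2"),
           sex  = c("M", "F", "M", "M", "F", "M", "F"))
}

# Small solid-colour iris image with a rectangular mask.
toy_image <- function(rgb = c(120, 100, 90), h = 8, w = 8, id = "toy") {
  px <- array(0L, dim = c(h, w, 3))
  for (k in 1:3) px[, , k] <- as.integer(rgb[k])
  mask <- matrix(FALSE, h, w)
  mask[2:(h - 1), 2:(w - 1)] <- TRUE
  iris_image(px, mask, image_id = id)
}

# Replace the pixel at linear mask index i with the given colour.
set_mask_pixel <- function(img, i, rgb) {
  idx <- which(img$mask)[i]
  for (k in 1:3) {
    ch <- img$pixels[, , k]
    ch[idx] <- as.integer(rgb[k])
    img$pixels[, , k] <- ch
  }
  img
}
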