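#' Default configuration for the synthetic study
#'
#' Returns a nested list describing every generator in one place. Defaults
#' mirror a realistic photographic-colorimetry study of blue-iris
#' pigmentation: group sample sizes of 8 lemurs, 33 captive and 19 wild
#' macaques, 119 humans, and 6 spider monkeys; small-ish photographs with
#' Gaussian sensor noise and planted specular highlights and shadows; a
#' multi-generation colony pedigree; a biallelic causal variant among null
#' variants; and phenotypes drawn from the same fixed-plus-kinship-random
#' effects model the association stage fits.
#'
#' @param seed Integer seed recorded in the config.
#' @param ... Named overrides for any top-level section (`image`,
#'   `pedigree`, `genetics`, `phenotype`, `clusters`), each a list merged
#'   over the defaults.
#' @return Nested list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    image = list(size = c(64, 64), center = c(32.5, 32.5), radii = c(22, 18),
                 base_lab = c(L = 45, a = 10, b = -5), noise_sd = 2,
                 n_highlight = 40, n_shadow = 25),
    pedigree = list(n_founders = 12, n_generations = 3,
                    n_offspring_per_gen = 14),
    genetics = list(n_variants = 11, causal_index = 6, founder_freq = 0.4,
                    beta = 1.25),
    phenotype = list(sigma2_g = 1, sigma2_e = 1,
                     alpha = c(age = -0.5, sex = 0, origin = 0.5),
                     max_age = 30),
    clusters = list(means = c(-7, 8), sds = c(1.5, 1.5), weights = c(0.5, 0.5),
                    n = 8),
    group_sizes = list(lemur = 8, macaque_captive = 33, macaque_wild = 19,
                       human = 119, spider_monkey = 6)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic iris photograph with known base colour
#'
#' Fills an elliptical iris region with a base colour specified in CIE
#' L*a*b* (converted to sRGB; out-of-gamut colours are an error), adds
#' i.i.d. Gaussian channel noise, then plants exactly `n_highlight`
#' all-channel bright (> 250) and `n_shadow` all-channel dark (< 10) pixels
#' inside the mask, emulating specular reflections and eyelid shadows. The
#' background outside the mask is neutral gray so gray-world white balancing
#' is a no-op in expectation.
#'
#' @param cfg A [synth_config()] (its `image` section is used).
#' @param image_id,encoding_tag Passed to [iris_image()].
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return List: `image` (an [iris_image()]), `true_lab` (the base L*, a*,
#'   b*), `n_planted` (`c(highlight, shadow)`).
#' @export
gen_iris_image <- function(cfg = synth_config(), image_id = "synthetic",
                           encoding_tag = "synthetic", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ic <- cfg$image
  h <- ic$size[1]; w <- ic$size[2]
  base_rgb <- as.numeric(lab_to_srgb(ic$base_lab))  # errors if out of gamut
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- ((rowg - ic$center[1]) / ic$radii[1])^2 +
    ((colg - ic$center[2]) / ic$radii[2])^2 <= 1
  n_mask <- sum(mask)
  if (ic$n_highlight + ic$n_shadow >= n_mask)
    stop("planted artifact count exceeds mask size")
  px <- array(128L, dim = c(h, w, 3))
  for (k in 1:3) {
    ch <- px[, , k]
    noise <- stats::rnorm(n_mask, 0, ic$noise_sd)
    ch[mask] <- round(base_rgb[k] + noise)
    px[, , k] <- pmin(pmax(ch, 10L), 250L)  # keep noise out of the cut classes
  }
  idx <- which(mask)
  planted <- sample(idx, ic$n_highlight + ic$n_shadow)
  hi <- planted[seq_len(ic$n_highlight)]
  lo <- planted[ic$n_highlight + seq_len(ic$n_shadow)]
  for (k in 1:3) {
    ch <- px[, , k]
    if (length(hi)) ch[hi] <- sample(251:255, length(hi), replace = TRUE)
    if (length(lo)) ch[lo] <- sample(0:9, length(lo), replace = TRUE)
    px[, , k] <- ch
  }
  storage.mode(px) <- "integer"
  list(image = iris_image(px, mask, image_id = image_id,
                          encoding_tag = encoding_tag),
       true_lab = ic$base_lab,
       n_planted = c(highlight = ic$n_highlight, shadow = ic$n_shadow))
}

#' Generate a random colony pedigree
#'
#' Founders (half assigned each sex) form generation 0; each later
#' generation adds offspring whose sire and dam are drawn uniformly from the
#' males and females of the previous generations, so every non-founder has
#' both parents earlier in the pedigree and the structure is acyclic by
#' construction.
#'
#' @param cfg A [synth_config()] (its `pedigree` section is used).
#' @param seed Optional seed.
#' @return A [pedigree()].
#' @export
gen_pedigree <- function(cfg = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pc <- cfg$pedigree
  if (pc$n_founders < 2) stop("need at least 2 founders")
  ids <- sprintf("F%02d", seq_len(pc$n_founders))
  sex <- rep(c("M", "F"), length.out = pc$n_founders)
  df <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                   sex = sex, gen = 0L, stringsAsFactors = FALSE)
  counter <- 0L
  for (g in seq_len(pc$n_generations)) {
    males <- df$id[df$sex == "M"]
    females <- df$id[df$sex == "F"]
    if (!length(males) || !length(females)) break
    for (j in seq_len(pc$n_offspring_per_gen)) {
      counter <- counter + 1L
      df <- rbind(df, data.frame(
        id = sprintf("I%03d", counter),
        sire = males[sample.int(length(males), 1L)],
        dam = females[sample.int(length(females), 1L)],
        sex = sample(c("M", "F"), 1L), gen = g,
        stringsAsFactors = FALSE))
    }
  }
  pedigree(df$id, df$sire, df$dam, sex = df$sex,
           group = ifelse(df$gen == 0L, "founder", "descendant"))
}

#' Drop Mendelian genotypes down a pedigree
#'
#' Founder haplotypes are i.i.d. Bernoulli(`founder_freq`) per variant;
#' every offspring inherits one uniformly chosen allele from each parent
#' (gene dropping). Returned dosages are derived-allele counts in 0/1/2.
#'
#' @param ped A [pedigree()].
#' @param cfg A [synth_config()] (its `genetics` section is used).
#' @param seed Optional seed.
#' @return List: `dosages` (individuals x variants matrix), `causal`
#'   (causal variant column name), `haplotypes` (individuals x variants x 2
#'   allele array).
#' @export
gen_genotypes <- function(ped, cfg = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc <- cfg$genetics
  n <- nrow(ped)
  nv <- gc$n_variants
  idx <- stats::setNames(seq_len(n), ped$id)
  hap <- array(0L, dim = c(n, nv, 2))
  for (i in seq_len(n)) {
    f <- ped$sire[i]; m <- ped$dam[i]
    for (a in 1:2) {
      parent <- if (a == 1L) f else m
      if (is.na(parent)) {
        hap[i, , a] <- stats::rbinom(nv, 1L, gc$founder_freq)
      } else {
        pick <- stats::rbinom(nv, 1L, 0.5) + 1L
        pi <- idx[[parent]]
        hap[i, , a] <- hap[cbind(pi, seq_len(nv), pick)]
      }
    }
  }
  dos <- matrix(hap[, , 1] + hap[, , 2], nrow = n, ncol = nv,
                dimnames = list(ped$id, paste0("v", seq_len(nv))))
  list(dosages = dos, causal = paste0("v", gc$causal_index), haplotypes = hap)
}

#' Generate phenotypes under the fixed-plus-kinship-random-effects model
#'
#' Draws \eqn{y = W\alpha + x_{causal}\beta + u + \epsilon} with
#' \eqn{u \sim N(0, \sigma_g^2 K)} (kinship-structured genetic random
#' effect) and \eqn{\epsilon \sim N(0, \sigma_e^2 I)}. Covariates (age, sex,
#' origin) are generated alongside so covariate screening can be exercised.
#'
#' @param ped A [pedigree()].
#' @param genotypes Result of [gen_genotypes()] (or a dosage matrix plus
#'   `causal` name).
#' @param cfg A [synth_config()] (its `phenotype` section is used).
#' @param seed Optional seed.
#' @return List: `y`, `covariates` (data frame with `age`, `adjusted_age`,
#'   `sex`, `origin`), `truth` (list `beta`, `sigma2_g`, `sigma2_e`,
#'   `alpha`, `causal`), `K`.
#' @export
gen_phenotypes <- function(ped, genotypes, cfg = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pc <- cfg$phenotype
  n <- nrow(ped)
  dos <- if (is.list(genotypes)) genotypes$dosages else genotypes
  causal <- if (is.list(genotypes)) genotypes$causal else cfg$genetics$causal_index
  kin <- kinship_from_pedigree(ped)
  K <- relatedness(kin)
  age <- stats::runif(n, 1, pc$max_age)
  adj_age <- adjusted_age(age, pc$max_age)
  sex <- as.numeric(ped$sex == "F")
  origin <- stats::rbinom(n, 1L, 0.5)
  W <- cbind(age = adj_age, sex = sex, origin = origin)
  fixed <- W %*% pc$alpha[colnames(W)]
  e <- eigen(K, symmetric = TRUE)
  d <- pmax(e$values, 0)
  u <- e$vectors %*% (sqrt(pc$sigma2_g * d) * stats::rnorm(n))
  eps <- stats::rnorm(n, 0, sqrt(pc$sigma2_e))
  x <- dos[, causal]
  y <- as.numeric(fixed + cfg$genetics$beta * x + u + eps)
  names(y) <- ped$id
  list(y = y,
       covariates = data.frame(id = ped$id, age = age, adjusted_age = adj_age,
                               sex = sex, origin = origin,
                               stringsAsFactors = FALSE),
       truth = list(beta = cfg$genetics$beta, sigma2_g = pc$sigma2_g,
                    sigma2_e = pc$sigma2_e, alpha = pc$alpha, causal = causal),
       K = K)
}

#' Draw a sample from a one- or two-component normal mixture
#'
#' Emulates the phenotype distributions the cluster test is applied to: a
#' two-component mixture (two phenotype clusters) or, when one weight is 1,
#' a single normal (one cluster).
#'
#' @param cfg A [synth_config()] (its `clusters` section is used: `means`,
#'   `sds`, `weights`, `n`).
#' @param seed Optional seed.
#' @return List: `x` (draws), `component` (1/2 labels).
#' @export
gen_cluster_sample <- function(cfg = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cc <- cfg$clusters
  if (abs(sum(cc$weights) - 1) > 1e-8 || any(cc$weights < 0))
    stop("weights must be non-negative and sum to 1")
  z <- sample(1:2, cc$n, replace = TRUE, prob = cc$weights)
  x <- stats::rnorm(cc$n, cc$means[z], cc$sds[z])
  list(x = x, component = z)
}

#' Generate an aligned haplotype set with planted variants
#'
#' Builds a random reference sequence, copies it into an outgroup (carrying
#' ancestral states throughout) and `n_haplotypes` ingroup haplotypes, then
#' plants biallelic substitutions at the requested offsets from the anchor
#' column, assigning the derived allele to a random subset of haplotypes at
#' the requested frequency (or to one group only for group-private
#' variants). Optional insertion columns — where the reference and outgroup
#' carry gaps — can be added to exercise gap-aware coordinate counting.
#'
#' @param offsets Integer offsets (relative to the anchor) at which to plant
#'   variants; must be distinct (a collision is an error).
#' @param n_haplotypes Number of ingroup haplotypes.
#' @param seq_length Ungapped reference length.
#' @param anchor_pos Ungapped reference position of the anchor.
#' @param derived_freq Derived-allele frequency per planted site (recycled).
#' @param groups Optional named group labels for the haplotypes.
#' @param private_group Optional group label: variants are then planted only
#'   within that group's haplotypes.
#' @param gap_columns Number of insertion columns (reference gap) to add at
#'   random positions.
#' @param seed Optional seed.
#' @return List: `aln` (an [aligned_haplotypes()]), `planted` (data frame of
#'   offsets, ancestral and derived bases, and realized derived counts).
#' @export
gen_alignment <- function(offsets = c(-6, 10), n_haplotypes = 12,
                          seq_length = 101, anchor_pos = 51,
                          derived_freq = 0.5, groups = NULL,
                          private_group = NULL, gap_columns = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (anyDuplicated(offsets)) stop("collision of planted sites")
  pos <- anchor_pos + offsets
  if (any(pos < 1L | pos > seq_length)) stop("planted site outside sequence")
  if (any(pos == anchor_pos) && !0 %in% offsets)
    stop("collision of planted sites")
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, seq_length, replace = TRUE)
  hap_ids <- sprintf("h%02d", seq_len(n_haplotypes))
  if (is.null(groups)) groups <- stats::setNames(rep("all", n_haplotypes), hap_ids)
  haps <- matrix(rep(ref, each = n_haplotypes), nrow = n_haplotypes,
                 dimnames = list(hap_ids, NULL))
  derived_freq <- rep_len(derived_freq, length(offsets))
  planted <- data.frame(offset = integer(0), ancestral = character(0),
                        derived = character(0), n_derived = integer(0))
  for (i in seq_along(pos)) {
    anc <- ref[pos[i]]
    der <- sample(setdiff(bases, anc), 1L)
    eligible <- if (is.null(private_group)) hap_ids
                else hap_ids[groups[hap_ids] == private_group]
    k <- max(1L, round(derived_freq[i] * length(eligible)))
    k <- min(k, length(eligible) - if (length(eligible) == n_haplotypes) 1L else 0L)
    carriers <- sample(eligible, k)
    haps[carriers, pos[i]] <- der
    planted <- rbind(planted, data.frame(
      offset = offsets[i], ancestral = anc, derived = der,
      n_derived = k, stringsAsFactors = FALSE))
  }
  # insertion columns: reference/outgroup gapped, ingroup carries a base
  anchor_col <- anchor_pos
  if (gap_columns > 0) {
    ins_at <- sort(sample(seq_len(seq_length - 1L), gap_columns))
    ref_g <- ref; hap_g <- haps
    for (j in rev(seq_along(ins_at))) {
      at <- ins_at[j]
      ref_g <- append(ref_g, "-", after = at)
      ins_base <- sample(bases, 1L)
      hap_g <- cbind(hap_g[, 1:at, drop = FALSE],
                     matrix(ins_base, n_haplotypes, 1),
                     hap_g[, -(1:at), drop = FALSE])
    }
    ref <- ref_g; haps <- hap_g
    anchor_col <- anchor_pos + sum(ins_at < anchor_pos)
  }
  seqs <- c(stats::setNames(paste(ref, collapse = ""), "outgroup"),
            stats::setNames(apply(haps, 1, paste, collapse = ""), hap_ids))
  aln <- aligned_haplotypes(seqs, outgroup_id = "outgroup",
                            anchor_column = anchor_col, groups = groups)
  list(aln = aln, planted = planted[order(planted$offset), , drop = FALSE])
}

#' Generate a complete synthetic study
#'
#' Ties the individual generators into one dataset shaped like the study the
#' pipeline was designed for: two lemur-like sister species photographed at
#' distinct base b* (a clustered, species-split phenotype), a macaque-like
#' group with continuous unimodal colour variation (the subsampling
#' comparison pool), and a pedigreed colony with genotypes at several
#' variants, one causal, whose kinship-structured quantitative phenotype
#' feeds the association scan. Every piece carries its ground truth.
#'
#' @param seed Integer seed controlling all stages.
#' @param delta_b Separation in base b* between the two species (default 15).
#' @param n_per_species Photographed individuals per species (default 4,
#'   i.e. 8 lemur-like individuals in total).
#' @param n_macaque Individuals in the continuous-variation group.
#' @param beta Causal-variant effect size for the association stage.
#' @param noise_sd Pixel channel noise sd.
#' @return List with elements `images` (list of [iris_image()]),
#'   `image_truth` (data frame id/group/true a*/true b*), `macaque_b`
#'   (continuous phenotype pool), `ped`, `genotypes`, `phenotypes`,
#'   `alignment`, and `config`.
#' @export
gen_study <- function(seed = 1, delta_b = 15, n_per_species = 4,
                      n_macaque = 20, beta = 1.25, noise_sd = 2) {
  set.seed(seed)
  base_b <- c(black = 8, `blue-eyed` = 8 - delta_b)
  images <- list(); truth <- list()
  for (sp in names(base_b)) {
    for (i in seq_len(n_per_species)) {
      id <- sprintf("%s_%02d", sub("-", "", sp), i)
      cfg_i <- synth_config(image = list(
        base_lab = c(L = 45, a = 10, b = base_b[[sp]] + stats::rnorm(1, 0, 1)),
        noise_sd = noise_sd))
      gen <- gen_iris_image(cfg_i, image_id = id, encoding_tag = "synthetic")
      images[[id]] <- gen$image
      truth[[id]] <- data.frame(individual_id = id, group = sp,
                                true_a = gen$true_lab[["a"]],
                                true_b = gen$true_lab[["b"]])
    }
  }
  macaque_b <- stats::rnorm(n_macaque, mean = 2, sd = 4)

  cfg <- synth_config(seed = seed,
                      genetics = list(n_variants = 11, causal_index = 6,
                                      founder_freq = 0.4, beta = beta),
                      pedigree = list(n_founders = 12, n_generations = 3,
                                      n_offspring_per_gen = 14))
  ped <- gen_pedigree(cfg)
  gt <- gen_genotypes(ped, cfg)
  ph <- gen_phenotypes(ped, gt, cfg)

  aln <- gen_alignment(
    offsets = c(-630, -76, -33, -6, 338), n_haplotypes = 14,
    seq_length = 1200, anchor_pos = 700, derived_freq = c(.2, .5, 1, .64, .3),
    groups = stats::setNames(rep(c("blue-eyed", "black"), each = 7),
                             sprintf("h%02d", 1:14)),
    private_group = NULL, gap_columns = 3)

  list(images = images, image_truth = do.call(rbind, truth),
       macaque_b = macaque_b, ped = ped, genotypes = gt, phenotypes = ph,
       alignment = aln, config = cfg)
}
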