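#' Quantify a set of photographs as median chromaticity
#'
#' Composition of the colorimetry steps over many photographs: optional
#' white balance, highlight/shadow filtering, sRGB to Lab conversion, and
#' median a*/b* summaries. Photographs whose iris region yields no usable
#' pixels (e.g. entirely in shadow) are excluded and logged with a reason,
#' mirroring how low-quality photographs are dropped from such studies;
#' unreadable files are likewise skipped. An error is raised only when every
#' photograph fails.
#'
#' @param images A list of [iris_image()] objects, or a data frame with
#'   columns `image`, `mask` (file paths) and optionally `id`,
#'   `encoding_tag`.
#' @param balance Apply gray-world white balance first (default TRUE).
#' @param low,high,channel_rule Passed to [filter_pixels()].
#' @return Data frame of [summarize_iris()] rows (one per retained
#'   photograph), with the exclusion log in attribute `"excluded"`.
#' @export
run_quantify <- function(images, balance = TRUE, low = 10, high = 250,
                         channel_rule = "all") {
  if (is.data.frame(images)) {
    paths <- images
    images <- lapply(seq_len(nrow(paths)), function(i) {
      tryCatch(
        read_iris_image(paths$image[i], paths$mask[i],
                        image_id = if ("id" %in% names(paths)) paths$id[i] else NULL,
                        encoding_tag = if ("encoding_tag" %in% names(paths))
                          paths$encoding_tag[i] else "unknown"),
        error = function(e) structure(conditionMessage(e), class = "read_failure"))
    })
  }
  rows <- list(); excluded <- list()
  for (img in images) {
    if (inherits(img, "read_failure")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(individual_id = NA_character_, reason = unclass(img))
      next
    }
    res <- tryCatch({
      img2 <- if (balance) white_balance(img) else img
      summarize_iris(img2, low = low, high = high, channel_rule = channel_rule)
    }, error = function(e)
      structure(list(id = img$image_id, msg = conditionMessage(e)),
                class = "quantify_failure"))
    if (inherits(res, "quantify_failure")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(individual_id = res$id, reason = res$msg)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("all photographs failed quantification")
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
                           else data.frame(individual_id = character(0),
                                           reason = character(0))
  out
}

#' Cluster tests per group and colour axis
#'
#' Runs the two-cluster-versus-one parametric-bootstrap test on median a*
#' and median b* within each group of a phenotype table. Groups with fewer
#' than four individuals are reported as skipped rather than erroring.
#'
#' @param phenotypes Data frame with columns `individual_id`, `median_a`,
#'   `median_b`, and `group`.
#' @param B Bootstrap replicates per test.
#' @param seed Base seed; each group x axis combination uses a distinct
#'   derived seed so tests are independent but reproducible.
#' @param ... Passed to [bootstrap_cluster_test()].
#' @return Data frame: `group`, `axis`, `n`, `lambda`, `B`, `n_exceed`,
#'   `p_value`, `skipped`.
#' @export
run_cluster_tests <- function(phenotypes, B = 999, seed = 1, ...) {
  stopifnot(all(c("median_a", "median_b", "group") %in% names(phenotypes)))
  combos <- expand.grid(group = unique(phenotypes$group), axis = c("a", "b"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    g <- combos$group[i]; ax <- combos$axis[i]
    x <- phenotypes[phenotypes$group == g, paste0("median_", ax)]
    if (length(x) < 4L)
      return(data.frame(group = g, axis = ax, n = length(x),
                        lambda = NA_real_, B = NA_integer_,
                        n_exceed = NA_integer_, p_value = NA_real_,
                        skipped = TRUE))
    res <- bootstrap_cluster_test(x, B = B, seed = seed + 1000L * i, ...)
    data.frame(group = g, axis = ax, n = length(x), lambda = res$lambda_obs,
               B = res$B, n_exceed = res$n_exceed, p_value = res$p_value,
               skipped = FALSE)
  })
  do.call(rbind, rows)
}

#' Covariate screening plus per-variant mixed-model association scan
#'
#' End-to-end association stage: checks id consistency across inputs,
#' derives the relatedness matrix from the pedigree (falling back to the
#' identity, with a warning, when no pedigree is supplied), quantile
#' normalizes the phenotype unless it is categorical, screens the candidate
#' covariates, and scans every variant.
#'
#' @param y Named phenotype vector (names are individual ids), or unnamed
#'   with ids taken from `genotypes` rows.
#' @param genotypes Dosage matrix, individuals x variants, rownames = ids.
#' @param covariates Optional data frame of candidate covariates with an
#'   `id` column.
#' @param ped Optional [pedigree()] covering the individuals.
#' @param normalize Quantile normalize `y` first (default TRUE; set FALSE
#'   for categorical phenotypes such as species codes).
#' @param alpha Covariate screening threshold.
#' @return List: `assoc` (association table, one row per variant in input
#'   order), `screen` (covariate screening table), `retained` (covariate
#'   names kept), `K`.
#' @export
run_association <- function(y, genotypes, covariates = NULL, ped = NULL,
                            normalize = TRUE, alpha = 0.05) {
  genotypes <- as.matrix(genotypes)
  ids <- rownames(genotypes)
  if (is.null(ids)) stop("genotype matrix must have individual ids as rownames")
  if (!is.null(names(y))) {
    missing_ids <- setdiff(ids, names(y))
    if (length(missing_ids))
      stop("ids missing from phenotype: ", paste(missing_ids, collapse = ", "))
    y <- y[ids]
  } else if (length(y) != nrow(genotypes)) {
    stop("phenotype length does not match genotype rows")
  }
  if (!is.null(ped)) {
    extra <- setdiff(ids, ped$id)
    if (length(extra))
      stop("ids missing from pedigree: ", paste(extra, collapse = ", "))
    K <- relatedness(kinship_from_pedigree(ped))[ids, ids]
  } else {
    warning("no pedigree supplied; using identity relatedness")
    K <- diag(length(ids))
    dimnames(K) <- list(ids, ids)
  }
  yt <- if (normalize) quantile_normalize(y) else as.numeric(y)
  W <- NULL
  screen <- NULL; retained <- character(0)
  if (!is.null(covariates)) {
    cv <- covariates[match(ids, covariates$id), setdiff(names(covariates), "id"),
                     drop = FALSE]
    sc <- screen_covariates(yt, as.matrix(cv), K = K, alpha = alpha)
    W <- sc$design
    screen <- sc$screen
    retained <- sc$retained
  }
  assoc <- association_scan(yt, genotypes, W = W, K = K)
  list(assoc = assoc, screen = screen, retained = retained, K = K)
}
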