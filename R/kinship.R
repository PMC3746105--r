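#' Construct and validate a pedigree
#'
#' A pedigree is a table of individuals with optional sire and dam, sex and
#' group labels. Unknown parents (`NA` or `"0"`) are treated as unique,
#' unrelated founders. The structure must be acyclic; records may be given in
#' any order and are topologically sorted internally.
#'
#' @param id,sire,dam Character vectors (recycled `NA` allowed for parents).
#' @param sex Optional sex codes (`"M"`/`"F"` or `1`/`2`); checked for
#'   consistency: an individual used as sire must never be used as dam.
#' @param group Optional group/species label per individual.
#' @return Object of class `pedigree`: a data frame with attributes.
#' @export
pedigree <- function(id, sire = NA, dam = NA, sex = NA, group = NA) {
  id <- as.character(id)
  clean <- function(p) {
    p <- as.character(p)
    p[p %in% c("0", "", "NA")] <- NA
    p
  }
  sire <- rep_len(clean(sire), length(id))
  dam <- rep_len(clean(dam), length(id))
  if (anyDuplicated(id)) stop("duplicate individual ids")
  if (any(!is.na(sire) & !(sire %in% id)) || any(!is.na(dam) & !(dam %in% id)))
    stop("parent ids must be present in the pedigree (or NA/0 for unknown)")
  as_sire <- stats::na.omit(sire)
  as_dam <- stats::na.omit(dam)
  if (length(intersect(as_sire, as_dam)))
    stop("inconsistent sexes: some individuals appear as both sire and dam")
  df <- data.frame(id = id, sire = sire, dam = dam,
                   sex = rep_len(as.character(sex), length(id)),
                   group = rep_len(as.character(group), length(id)),
                   stringsAsFactors = FALSE)
  ord <- .topo_order(df)
  structure(df[ord, , drop = FALSE], class = c("pedigree", "data.frame"))
}

# Kahn topological sort; errors on cycles.
.topo_order <- function(df) {
  n <- nrow(df)
  idx <- stats::setNames(seq_len(n), df$id)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed & vapply(seq_len(n), function(i) {
      p <- c(df$sire[i], df$dam[i])
      p <- p[!is.na(p)]
      all(placed[idx[p]])
    }, logical(1)))
    if (!length(ready)) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (length(ord) != n) stop("pedigree contains a cycle")
  ord
}

#' Read a pedigree TSV
#'
#' Expected columns `id  sire  dam  sex  group`, with `NA` or `0` for unknown
#' parents.
#'
#' @param path File path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "NA")
  pedigree(df$id, df$sire, df$dam,
           sex = if ("sex" %in% names(df)) df$sex else NA,
           group = if ("group" %in% names(df)) df$group else NA)
}

#' Write a pedigree TSV
#' @param ped A [pedigree()].
#' @param path File path.
#' @export
write_pedigree <- function(ped, path) {
  write_tsv_table(as.data.frame(ped), path)
}

#' Kinship coefficients from a pedigree
#'
#' Standard recursive computation of the kinship coefficient
#' \eqn{\phi_{ij}}, the probability that an allele sampled from `i` and one
#' sampled from `j` are identical by descent:
#' \eqn{\phi_{ii} = (1 + \phi_{f_i m_i})/2} and
#' \eqn{\phi_{ij} = (\phi_{f_i j} + \phi_{m_i j})/2} with individuals
#' processed parents-first. Founders are pairwise unrelated and non-inbred
#' (\eqn{\phi_{ii} = 0.5}); unknown parents contribute 0.
#'
#' @param ped A [pedigree()].
#' @return Object of class `kinship_matrix`: list with `ids`, `phi` (the
#'   symmetric kinship matrix) and `K` (the relatedness matrix `2 * phi`).
#' @export
kinship_from_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  ids <- ped$id
  idx <- stats::setNames(seq_len(n), ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {  # topological order: parents precede offspring
    f <- ped$sire[i]; m <- ped$dam[i]
    fi <- if (is.na(f)) NA_integer_ else idx[[f]]
    mi <- if (is.na(m)) NA_integer_ else idx[[m]]
    phi_fm <- if (!is.na(fi) && !is.na(mi)) phi[fi, mi] else 0
    phi[i, i] <- 0.5 * (1 + phi_fm)
    if (i > 1L) {
      js <- seq_len(i - 1L)
      contrib <- numeric(length(js))
      if (!is.na(fi)) contrib <- contrib + phi[fi, js]
      if (!is.na(mi)) contrib <- contrib + phi[mi, js]
      phi[i, js] <- 0.5 * contrib
      phi[js, i] <- phi[i, js]
    }
  }
  structure(list(ids = ids, phi = phi, K = 2 * phi),
            class = "kinship_matrix")
}

#' Relatedness matrix for the mixed-model random effect
#'
#' Returns the numerator relationship matrix `K = 2 * phi` (diagonal 1 for
#' non-inbred individuals), the covariance kernel expected by
#' [lmm_wald()]. Positive semi-definiteness is verified by
#' eigendecomposition.
#'
#' @param kin A `kinship_matrix` from [kinship_from_pedigree()].
#' @param scale `"2phi"` (default) or `"phi"` to pass raw kinship instead.
#' @param tol Smallest tolerated (relative) eigenvalue; more negative values
#'   raise an error.
#' @return Symmetric numeric matrix with id dimnames.
#' @export
relatedness <- function(kin, scale = c("2phi", "phi"), tol = 1e-8) {
  stopifnot(inherits(kin, "kinship_matrix"))
  scale <- match.arg(scale)
  K <- if (scale == "2phi") kin$K else kin$phi
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    stop("relatedness matrix is not positive semi-definite")
  K
}

#' Write/read a kinship matrix as a square TSV
#'
#' The file has an `id` header column and one column per individual.
#'
#' @param kin A `kinship_matrix`, or for reading, a file path.
#' @param path File path.
#' @param what Which matrix to write: `"phi"` or `"K"`.
#' @export
write_kinship <- function(kin, path, what = c("phi", "K")) {
  what <- match.arg(what)
  m <- if (what == "phi") kin$phi else kin$K
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write_tsv_table(df, path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path, what = c("phi", "K")) {
  what <- match.arg(what)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  phi <- if (what == "phi") m else m / 2
  structure(list(ids = rownames(m), phi = phi, K = 2 * phi),
            class = "kinship_matrix")
}
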