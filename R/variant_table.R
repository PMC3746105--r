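#' Construct an aligned-haplotype object
#'
#' Holds equal-length aligned haplotype sequences together with the sample
#' metadata the variant table needs: group labels, founder flags, the
#' designated outgroup used to polarize ancestral/derived states, and the
#' anchor column — the alignment column orthologous to the human iris-colour
#' SNP rs12913832, relative to which variant positions are reported.
#'
#' @param sequences Named character vector of aligned sequences over
#'   `A,C,G,T,N,-` (case-insensitive), all the same length.
#' @param outgroup_id Name of the outgroup sequence (present in
#'   `sequences`); it supplies ancestral states and, by default, the
#'   coordinate system.
#' @param anchor_column Alignment column (1-based) of the anchor site.
#' @param groups Named character vector: group label per ingroup sample
#'   (defaults to `"all"`).
#' @param founder Named logical vector: founder flag per ingroup sample
#'   (defaults to all `TRUE`).
#' @param ref_id Sequence providing ungapped reference coordinates; default
#'   the outgroup.
#' @return Object of class `aligned_haplotypes`.
#' @export
aligned_haplotypes <- function(sequences, outgroup_id, anchor_column,
                               groups = NULL, founder = NULL,
                               ref_id = outgroup_id) {
  sequences <- toupper(vapply(sequences, as.character, character(1)))
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  L <- lens[[1]]
  if (!outgroup_id %in% names(sequences)) stop("outgroup not present")
  if (!ref_id %in% names(sequences)) stop("reference sequence not present")
  if (anchor_column < 1L || anchor_column > L) stop("anchor column out of bounds")
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad)) stop("invalid characters in sequences: ",
                     paste(names(sequences)[bad], collapse = ", "))
  ingroup <- setdiff(names(sequences), outgroup_id)
  if (is.null(groups)) groups <- stats::setNames(rep("all", length(ingroup)), ingroup)
  if (is.null(founder)) founder <- stats::setNames(rep(TRUE, length(ingroup)), ingroup)
  if (!all(ingroup %in% names(groups))) stop("groups must cover all ingroup samples")
  if (!all(ingroup %in% names(founder))) stop("founder flags must cover all ingroup samples")
  mat <- do.call(rbind, strsplit(sequences, ""))
  rownames(mat) <- names(sequences)
  structure(list(seq_matrix = mat, ids = names(sequences),
                 ingroup = ingroup, outgroup_id = outgroup_id,
                 ref_id = ref_id, anchor_column = as.integer(anchor_column),
                 groups = groups[ingroup], founder = founder[ingroup]),
            class = "aligned_haplotypes")
}

#' Read aligned haplotypes from FASTA plus a metadata TSV
#'
#' The FASTA must contain the aligned sequences (gap character `-`); the
#' metadata TSV has columns `id  group  founder_flag` (and optionally
#' `diploid_pair`, pairing haplotypes into individuals).
#'
#' @param fasta_path Aligned FASTA file.
#' @param outgroup_id,anchor_column,ref_id As in [aligned_haplotypes()].
#' @param metadata_path Optional TSV path with per-sample metadata.
#' @return An `aligned_haplotypes` object; any `diploid_pair` column is
#'   stored in the `diploid_pair` element.
#' @export
read_haplotypes <- function(fasta_path, outgroup_id, anchor_column,
                            metadata_path = NULL, ref_id = outgroup_id) {
  ss <- Biostrings::readBStringSet(fasta_path)
  seqs <- stats::setNames(as.character(ss), names(ss))
  groups <- NULL; founder <- NULL; pair <- NULL
  if (!is.null(metadata_path)) {
    md <- read_tsv_table(metadata_path)
    groups <- stats::setNames(as.character(md$group), md$id)
    founder <- stats::setNames(as.logical(md$founder_flag), md$id)
    if ("diploid_pair" %in% names(md))
      pair <- stats::setNames(as.character(md$diploid_pair), md$id)
  }
  aln <- aligned_haplotypes(seqs, outgroup_id, anchor_column,
                            groups = groups, founder = founder, ref_id = ref_id)
  aln$diploid_pair <- pair
  aln
}

#' Write aligned haplotypes as FASTA
#' @param aln An `aligned_haplotypes` object.
#' @param path Output path.
#' @export
write_haplotypes <- function(aln, path) {
  seqs <- apply(aln$seq_matrix, 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(seqs, rownames(aln$seq_matrix))),
    path)
  invisible(path)
}

#' Signed offset of an alignment column relative to the anchor
#'
#' Positions are counted on the ungapped reference sequence: the offset is
#' the reference coordinate of the column minus that of the anchor column,
#' negative upstream and positive downstream (the anchor itself is 0).
#' Columns where the reference carries a gap have no reference coordinate.
#'
#' @param column Alignment column index (1-based).
#' @param aln An `aligned_haplotypes` object.
#' @return Integer offset.
#' @export
anchored_offset <- function(column, aln) {
  ref <- aln$seq_matrix[aln$ref_id, ]
  if (column < 1L || column > length(ref)) stop("column out of bounds")
  if (ref[column] == "-") stop("no reference coordinate")
  if (ref[aln$anchor_column] == "-") stop("anchor falls in a reference gap")
  pos <- cumsum(ref != "-")
  as.integer(pos[column] - pos[aln$anchor_column])
}

#' Extract biallelic segregating sites from an alignment
#'
#' Scans alignment columns for sites where the ingroup sequences carry
#' exactly two distinct bases (gaps and `N` treated as missing). Sites with
#' more than two alleles are excluded with a warning. The ancestral state is
#' the outgroup base when it matches one of the two alleles; otherwise the
#' site is flagged unpolarized and the major allele is (arbitrarily) listed
#' as ancestral. Sites falling in a reference gap carry `NA` offsets.
#'
#' @param aln An `aligned_haplotypes` object.
#' @return Data frame with one row per variant: `column`, `offset`,
#'   `ancestral`, `derived`, `polarized`, and one 0/1 haplotype dosage column
#'   per ingroup sample (attribute `"dosages"`), plus frequencies computed
#'   on demand by [founder_frequency()].
#' @export
segregating_sites <- function(aln) {
  mat <- aln$seq_matrix[aln$ingroup, , drop = FALSE]
  out_seq <- aln$seq_matrix[aln$outgroup_id, ]
  L <- ncol(mat)
  rows <- list()
  dosages <- list()
  multi <- 0L
  for (col in seq_len(L)) {
    bases <- mat[, col]
    obs <- bases[bases %in% c("A", "C", "G", "T")]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L) { multi <- multi + 1L; next }
    if (length(alleles) != 2L) next
    og <- out_seq[col]
    if (og %in% alleles) {
      anc <- og
      der <- setdiff(alleles, og)
      polarized <- TRUE
    } else {
      counts <- table(factor(obs, levels = alleles))
      anc <- names(counts)[which.max(counts)]
      der <- setdiff(alleles, anc)
      polarized <- FALSE
    }
    off <- tryCatch(anchored_offset(col, aln), error = function(e) NA_integer_)
    dos <- ifelse(bases == der, 1L, ifelse(bases == anc, 0L, NA_integer_))
    rows[[length(rows) + 1L]] <-
      data.frame(column = col, offset = off, ancestral = anc, derived = der,
                 polarized = polarized, stringsAsFactors = FALSE)
    dosages[[length(dosages) + 1L]] <- dos
  }
  if (multi > 0L)
    warning(multi, " multi-allelic site(s) excluded")
  if (!length(rows)) {
    res <- data.frame(column = integer(0), offset = integer(0),
                      ancestral = character(0), derived = character(0),
                      polarized = logical(0))
    attr(res, "dosages") <- matrix(integer(0), nrow = 0,
                                   ncol = length(aln$ingroup),
                                   dimnames = list(NULL, aln$ingroup))
    return(res)
  }
  res <- do.call(rbind, rows)
  dmat <- do.call(rbind, lapply(dosages, function(d)
    stats::setNames(d, aln$ingroup)))
  colnames(dmat) <- aln$ingroup
  attr(res, "dosages") <- dmat
  res
}

#' Derived-allele frequency among founders of a group
#'
#' Counts derived alleles over non-missing founder haplotypes of the group;
#' non-founders are excluded so transmitted alleles are not double-counted.
#'
#' @param variant One row of the [segregating_sites()] result (with its
#'   dosage attribute), or the full result plus `which` row index.
#' @param aln The `aligned_haplotypes` the sites came from.
#' @param group Group label.
#' @param sites Optionally, the full `segregating_sites()` result when
#'   `variant` is a row index.
#' @return Frequency in `[0, 1]`, or `NA` if the group has no genotyped
#'   founder haplotype at the site.
#' @export
founder_frequency <- function(variant, aln, group, sites = NULL) {
  if (is.numeric(variant) && !is.null(sites)) {
    dos <- attr(sites, "dosages")[variant, ]
  } else {
    dos <- attr(variant, "dosages")[1, ]
  }
  sel <- aln$founder & aln$groups == group
  if (!any(sel)) return(NA_real_)
  d <- dos[names(sel)[sel]]
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  sum(d) / length(d)
}

#' Variant report in the style of a candidate-region summary table
#'
#' One row per segregating site with its anchored offset, `ancestral >
#' derived` notation, and derived-allele frequency among founders of each
#' group (`NA` where the group has no genotyped founder haplotypes at the
#' site). Association p-value columns can be merged on afterwards.
#'
#' @param aln An `aligned_haplotypes` object.
#' @param groups Group labels to report; default all groups present.
#' @return Data frame: `offset`, `variant` (e.g. `"G > A"`), `polarized`, one
#'   `f_<group>` column per group; attribute `"dosages"` carries the
#'   haplotype dosage matrix (variants x samples).
#' @export
variant_report <- function(aln, groups = NULL) {
  sites <- segregating_sites(aln)
  if (is.null(groups)) groups <- unique(aln$groups)
  if (nrow(sites) == 0L) {
    out <- data.frame(offset = integer(0), variant = character(0),
                      polarized = logical(0))
    for (g in groups) out[[paste0("f_", g)]] <- numeric(0)
    return(out)
  }
  out <- data.frame(offset = sites$offset,
                    variant = paste(sites$ancestral, ">", sites$derived),
                    polarized = sites$polarized, stringsAsFactors = FALSE)
  for (g in groups)
    out[[paste0("f_", g)]] <- vapply(seq_len(nrow(sites)), function(i)
      founder_frequency(i, aln, g, sites = sites), numeric(1))
  attr(out, "dosages") <- attr(sites, "dosages")
  out[order(out$offset), , drop = FALSE]
}

#' Collapse haplotype dosages to diploid genotype dosages
#'
#' Sums the two haplotype dosages of each individual given the
#' `diploid_pair` mapping (haplotype id -> individual id); a missing
#' haplotype makes the genotype missing.
#'
#' @param sites Result of [segregating_sites()] (carries the dosage
#'   attribute).
#' @param pairing Named character vector: individual id per haplotype id.
#' @return Matrix individuals x variants with values 0/1/2/`NA`; variant
#'   columns named by offset when available, else by alignment column.
#' @export
diploid_dosages <- function(sites, pairing) {
  dmat <- attr(sites, "dosages")
  if (is.null(dmat)) stop("sites must carry a dosage attribute")
  haps <- colnames(dmat)
  if (!all(haps %in% names(pairing))) stop("pairing must cover all haplotypes")
  inds <- unique(unname(pairing[haps]))
  vn <- ifelse(is.na(sites$offset), paste0("col", sites$column),
               paste0("off", sites$offset))
  out <- matrix(NA_integer_, nrow = length(inds), ncol = nrow(sites),
                dimnames = list(inds, vn))
  for (ind in inds) {
    hs <- haps[pairing[haps] == ind]
    sub <- dmat[, hs, drop = FALSE]
    out[ind, ] <- as.integer(rowSums(sub))
  }
  out
}
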