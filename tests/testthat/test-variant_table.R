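make_toy_aln <- function() {
  # 10 columns; anchor at column 6. Two planted substitutions:
  #   column 2 (offset -4): A -> G in h1, h2
  #   column 9 (offset +3): C -> T in h3
  ref <- "TACGTAGGCA"
  seqs <- c(
    outgroup = ref,
    h1 = "TGCGTAGGCA",
    h2 = "TGCGTAGGCA",
    h3 = "TACGTAGGTA",
    h4 = ref, h5 = ref, h6 = ref)
  aligned_haplotypes(seqs, outgroup_id = "outgroup", anchor_column = 6,
                     groups = setNames(c("blue", "blue", "black", "black",
                                         "blue", "black"),
                                       paste0("h", 1:6)))
}

test_that("segregating sites are found with correct polarity", {
  aln <- make_toy_aln()
  sites <- segregating_sites(aln)
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$column, c(2L, 9L))
  expect_equal(sites$offset, c(-4L, 3L))
  expect_equal(sites$ancestral, c("A", "C"))
  expect_equal(sites$derived, c("G", "T"))
  expect_true(all(sites$polarized))
  dos <- attr(sites, "dosages")
  expect_equal(unname(dos[1, ]), c(1L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(unname(dos[2, ]), c(0L, 0L, 1L, 0L, 0L, 0L))
})

test_that("identical ingroup sequences yield no variants", {
  seqs <- c(outgroup = "ACGT", h1 = "ACGT", h2 = "ACGT", h3 = "ACGT")
  aln <- aligned_haplotypes(seqs, "outgroup", 2)
  expect_equal(nrow(segregating_sites(aln)), 0L)
})

test_that("outgroup carrying a third base flags the site unpolarized", {
  seqs <- c(outgroup = "TA", h1 = "CA", h2 = "GA", h3 = "CA")
  aln <- aligned_haplotypes(seqs, "outgroup", 2)
  sites <- segregating_sites(aln)
  expect_equal(nrow(sites), 1L)
  expect_false(sites$polarized)
  expect_equal(sites$ancestral, "C")  # major allele fallback
})

test_that("multi-allelic sites are excluded with a warning", {
  seqs <- c(outgroup = "AA", h1 = "CA", h2 = "GA", h3 = "TA", h4 = "AA")
  aln <- aligned_haplotypes(seqs, "outgroup", 2)
  expect_warning(sites <- segregating_sites(aln), "multi-allelic")
  expect_equal(nrow(sites), 0L)
})

test_that("anchored offsets count ungapped reference positions", {
  # reference gap of 3 columns between the site and the anchor
  seqs <- c(outgroup = "AC---GTAG",
            h1 = "ACTTTGTAG", h2 = "ACTTTGTAG")
  aln <- aligned_haplotypes(seqs, "outgroup", anchor_column = 6)
  expect_equal(anchored_offset(6, aln), 0L)
  expect_equal(anchored_offset(2, aln), -1L)  # gap columns not counted
  expect_equal(anchored_offset(1, aln), -2L)
  expect_equal(anchored_offset(9, aln), 3L)
  expect_error(anchored_offset(4, aln), "no reference coordinate")
  expect_error(anchored_offset(99, aln), "out of bounds")
  # strictly increasing along reference-coordinate columns
  cols <- c(1, 2, 6, 7, 8, 9)
  offs <- vapply(cols, anchored_offset, integer(1), aln = aln)
  expect_true(all(diff(offs) > 0))
})

test_that("founder frequencies use founder haplotypes of the group only", {
  aln <- make_toy_aln()
  sites <- segregating_sites(aln)
  # site 1: derived in h1, h2 (both blue founders); blue founders = h1,h2,h5
  expect_equal(founder_frequency(1, aln, "blue", sites = sites), 2 / 3)
  expect_equal(founder_frequency(1, aln, "black", sites = sites), 0)
  expect_true(is.na(founder_frequency(1, aln, "howler", sites = sites)))
  # excluding non-founders changes the denominator
  aln2 <- make_toy_aln()
  aln2$founder[c("h5")] <- FALSE
  expect_equal(founder_frequency(1, aln2, "blue", sites = sites), 2 / 2)
  # 9 derived among 14 founder haplotypes gives the ~64% scale
  g <- gen_alignment(offsets = -6, n_haplotypes = 14, seq_length = 40,
                     anchor_pos = 20, derived_freq = 9 / 14, seed = 12)
  rep14 <- variant_report(g$aln)
  expect_equal(rep14$f_all, 9 / 14, tolerance = 1e-9)
  expect_equal(round(100 * rep14$f_all), 64)
})

test_that("frequencies are invariant to order and haplotype duplication", {
  aln <- make_toy_aln()
  sites <- segregating_sites(aln)
  f_blue <- founder_frequency(1, aln, "blue", sites = sites)
  # duplicate every haplotype
  seqs <- apply(aln$seq_matrix, 1, paste, collapse = "")
  dup_ids <- paste0(aln$ingroup, "_b")
  seqs2 <- c(seqs, setNames(seqs[aln$ingroup], dup_ids))
  aln2 <- aligned_haplotypes(seqs2, "outgroup", 6,
                             groups = setNames(rep(aln$groups, 2),
                                               c(aln$ingroup, dup_ids)))
  sites2 <- segregating_sites(aln2)
  expect_equal(founder_frequency(1, aln2, "blue", sites = sites2), f_blue)
})

test_that("variant_report lays out offsets, alleles and group frequencies", {
  aln <- make_toy_aln()
  rep_tab <- variant_report(aln)
  expect_equal(rep_tab$offset, c(-4L, 3L))
  expect_equal(rep_tab$variant, c("A > G", "C > T"))
  expect_equal(rep_tab$f_blue, c(2 / 3, 0))
  expect_equal(rep_tab$f_black, c(0, 1 / 3))
  # private variant pattern: 0 in one group, f in the other
  expect_true(all(rep_tab$f_black[1] == 0 & rep_tab$f_blue[1] > 0))
  # empty alignment -> header-only table
  seqs <- c(outgroup = "ACGT", h1 = "ACGT", h2 = "ACGT")
  empty <- variant_report(aligned_haplotypes(seqs, "outgroup", 2))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("offset", "variant") %in% names(empty)))
  # TSV round trip
  td <- withr::local_tempdir()
  tp <- file.path(td, "variants.tsv")
  write_tsv_table(rep_tab, tp)
  back <- read_tsv_table(tp)
  expect_equal(back$offset, rep_tab$offset)
  expect_equal(back$variant, rep_tab$variant)
  expect_equal(back$f_blue, rep_tab$f_blue, tolerance = 1e-12)
})

test_that("haplotype FASTA and metadata round-trip through files", {
  aln <- make_toy_aln()
  td <- withr::local_tempdir()
  fp <- file.path(td, "aln.fasta")
  write_haplotypes(aln, fp)
  md <- data.frame(id = aln$ingroup, group = unname(aln$groups),
                   founder_flag = unname(aln$founder),
                   diploid_pair = rep(c("i1", "i2", "i3"), each = 2))
  mp <- file.path(td, "meta.tsv")
  write_tsv_table(md, mp)
  back <- read_haplotypes(fp, outgroup_id = "outgroup", anchor_column = 6,
                          metadata_path = mp)
  expect_equal(back$seq_matrix, aln$seq_matrix)
  expect_equal(back$groups, aln$groups)
  sites <- segregating_sites(back)
  dd <- diploid_dosages(sites, back$diploid_pair)
  expect_equal(dim(dd), c(3L, 2L))
  expect_equal(unname(dd[, 1]), c(2L, 0L, 0L))  # h1+h2 carry the -4 variant
})

test_that("a planted-variant simulator is recovered exactly", {
  g <- gen_alignment(offsets = c(-8, -2, 5), n_haplotypes = 10,
                     seq_length = 30, anchor_pos = 15,
                     derived_freq = c(0.3, 0.5, 0.2), seed = 77)
  sites <- segregating_sites(g$aln)
  expect_equal(sort(sites$offset), sort(g$planted$offset))
  m <- merge(sites, g$planted, by = "offset")
  expect_equal(m$ancestral.x, m$ancestral.y)
  expect_equal(m$derived.x, m$derived.y)
  expect_true(all(m$polarized))
})
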