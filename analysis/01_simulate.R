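#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study and write every input file the later
# stages consume — iris photographs with masks, a colony pedigree, genotypes
# at candidate-region variants, covariates and quantitative phenotypes, a
# continuous-variation phenotype pool, and an aligned haplotype FASTA.

suppressPackageStartupMessages(library(blueiris))

seed <- as.integer(Sys.getenv("BLUEIRIS_SEED", "1"))
out <- "results/sim"
dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)

message("Simulating study with seed ", seed)
study <- gen_study(seed = seed, delta_b = 15, n_per_species = 4,
                   n_macaque = 20, beta = 1.25)

# photographs + masks
manifest <- data.frame(id = character(0), image = character(0),
                       mask = character(0))
for (id in names(study$images)) {
  ip <- file.path(out, "images", paste0(id, ".png"))
  mp <- file.path(out, "images", paste0(id, "_mask.png"))
  write_iris_image(study$images[[id]], ip, mp)
  manifest <- rbind(manifest, data.frame(id = id, image = ip, mask = mp))
}
write_tsv_table(manifest, file.path(out, "image_manifest.tsv"))
write_tsv_table(study$image_truth, file.path(out, "image_truth.tsv"))
message("Wrote ", nrow(manifest), " photographs (two species, base b* ",
        "separated by 15)")

# continuous-variation pool for the size-matched subsampling comparison
write_tsv_table(data.frame(individual_id = sprintf("mac_%02d",
                                                   seq_along(study$macaque_b)),
                           median_b = study$macaque_b),
                file.path(out, "macaque_pool.tsv"))

# pedigree, genotypes, phenotype, covariates
write_pedigree(study$ped, file.path(out, "pedigree.tsv"))
gt <- data.frame(id = rownames(study$genotypes$dosages),
                 study$genotypes$dosages, check.names = FALSE)
write_tsv_table(gt, file.path(out, "genotypes.tsv"))
write_tsv_table(study$phenotypes$covariates, file.path(out, "covariates.tsv"))
write_tsv_table(data.frame(id = names(study$phenotypes$y),
                           y = study$phenotypes$y),
                file.path(out, "phenotype.tsv"))
writeLines(study$genotypes$causal, file.path(out, "causal_variant.txt"))
message("Pedigree: ", nrow(study$ped), " individuals; genotypes at ",
        ncol(study$genotypes$dosages), " variants (causal: ",
        study$genotypes$causal, ", beta = ", study$config$genetics$beta, ")")

# aligned haplotypes
write_haplotypes(study$alignment$aln, file.path(out, "haplotypes.fasta"))
md <- data.frame(id = study$alignment$aln$ingroup,
                 group = unname(study$alignment$aln$groups),
                 founder_flag = unname(study$alignment$aln$founder))
write_tsv_table(md, file.path(out, "haplotype_metadata.tsv"))
writeLines(as.character(study$alignment$aln$anchor_column),
           file.path(out, "anchor_column.txt"))
write_tsv_table(study$alignment$planted, file.path(out, "planted_variants.tsv"))
message("Alignment: ", length(study$alignment$aln$ingroup),
        " haplotypes + outgroup, planted offsets ",
        paste(study$alignment$planted$offset, collapse = ", "))
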