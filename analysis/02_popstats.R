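#!/usr/bin/env Rscript
# Stage 2: core population-genetic statistics on the simulated cohort.
#
# Applies the standard SNP quality filters (missing ratio < 10%, MAF > 1%),
# then computes 40-kb/20-kb sliding-window nucleotide diversity and
# Weir-Cockerham Fst, the pairwise-Fst matrix, per-population
# heterozygosity/inbreeding, the LD-decay curve and a genotype PCA.

suppressPackageStartupMessages(library(apiscan))

fx <- "results/fixture"
out <- "results/popstats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
params <- list(stage = "popstats", window_size = 40000, window_step = 20000,
               max_missing = 0.10, min_maf = 0.01,
               ld_max_dist = 200000, ld_bin_width = 10000, ld_threshold = 0.1,
               n_components = 5)

g <- read_vcf(file.path(fx, "cohort.vcf"))
pops <- read_population_map(file.path(fx, "popmap.tsv"))
gf <- filter_variants(g, params$max_missing, params$min_maf)
cat("Sites:", n_sites(g), "->", n_sites(gf), "after filtering\n")

win <- make_windows(c(chr1 = 2e6), params$window_size, params$window_step)
for (p in unique(pops$population)) {
  pw <- window_pi(gf, win, samples = pops$sample[pops$population == p])
  write_window_stats(pw, file.path(out, paste0("pi_", p, ".tsv")))
  cat(sprintf("Mean windowed pi (%s): %.3g per bp\n", p, mean(pw$pi)))
}

fw <- wc_fst_window(gf, pops, win)
write_window_stats(fw[, c("chrom", "start", "end", "n_sites", "fst")],
                   file.path(out, "fst_windows.tsv"))
cat(sprintf("Genome-wide W&C Fst: %.4f (window mean %.4f)\n",
            wc_fst_global(gf, pops), mean(fw$fst, na.rm = TRUE)))

m <- pairwise_fst_matrix(gf, pops)
write_fst_matrix(m, file.path(out, "fst_matrix.tsv"))

h <- het_and_inbreeding(gf, pops)
write.table(h$per_individual, file.path(out, "het_individuals.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(h$per_population, file.path(out, "het_populations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(h$per_population)

ld <- ld_r2_decay(gf, samples = pops$sample[pops$population == "pop1"],
                  max_dist = params$ld_max_dist,
                  bin_width = params$ld_bin_width,
                  threshold = params$ld_threshold)
write_ld_curve(ld, file.path(out, "ld_decay_pop1.tsv"))
cat("LD decay distance (pop1, r2 <", params$ld_threshold, "):",
    ld$decay_distance,
    "bp (sites are unlinked in the Balding-Nichols cohort)\n")

# a linked-site cohort shows the characteristic decay curve
gl <- simulate_linked_genotypes(n_samples = 50, n_snps = 800,
                                chrom_length = 1e6, decay_length = 20000,
                                seed = 2)
ldl <- ld_r2_decay(gl, max_dist = params$ld_max_dist,
                   bin_width = params$ld_bin_width,
                   threshold = params$ld_threshold)
write_ld_curve(ldl, file.path(out, "ld_decay_linked.tsv"))
cat("LD decay distance (linked simulation):", ldl$decay_distance, "bp\n")

pc <- genotype_pca(gf, params$n_components)
write.table(cbind(sample = rownames(pc$scores),
                  population = pops$population[match(rownames(pc$scores),
                                                     pops$sample)],
                  as.data.frame(pc$scores)),
            file.path(out, "pca_scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("PCA explained-variance fractions:",
    paste(sprintf("%.3f", pc$explained), collapse = " "), "\n")

jsonlite::write_json(params, file.path(out, "params.json"),
                     auto_unbox = TRUE, pretty = TRUE)
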