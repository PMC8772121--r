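#!/usr/bin/env Rscript
# Stage 3: selective-sweep scan.
#
# Scans 20-kb/10-kb windows for joint outliers of Z-transformed
# candidate-vs-reference Fst and the log2 theta-pi ratio (reference over
# candidate), selects the intersection of the top-5% tails, merges selected
# windows into regions and lists the genes they overlap.  On the fixture the
# injected sweep interval is chr1:1,000,001-1,100,000 (1-based).

suppressPackageStartupMessages(library(apiscan))

fx <- "results/fixture"
out <- "results/sweep"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
params <- list(stage = "sweep", window_size = 20000, window_step = 10000,
               q = 0.05, min_sites = 10, two_tailed_pi = FALSE,
               candidate = "pop1", reference = "pop2")

g <- filter_variants(read_vcf(file.path(fx, "cohort.vcf")))
pops <- read_population_map(file.path(fx, "popmap.tsv"))
cand <- pops$sample[pops$population == params$candidate]
refs <- pops$sample[pops$population == params$reference]

sw <- compute_sweep_stats(g, cand, refs, size = params$window_size,
                          step = params$window_step,
                          min_sites = params$min_sites,
                          chrom_lengths = c(chr1 = 2e6))
cat("Windows:", nrow(sw), "rankable:", sum(sw$rankable),
    "excluded:", attr(sw, "n_excluded"), "\n")
write_window_stats(sw, file.path(out, "sweep_windows.tsv"))

sel <- select_top_intersection(sw, q = params$q,
                               two_tailed_pi = params$two_tailed_pi)
cat(sprintf("Selected %d windows (Z-Fst >= %.3f and log2 ratio >= %.3f)\n",
            nrow(sel), attr(sel, "z_fst_threshold"),
            attr(sel, "log2_ratio_threshold")))

reg <- merge_regions(sel)
genes <- read_gff_genes(file.path(fx, "genes.gff3"))
ov <- overlap_genes(reg, genes)
write_regions_bed(ov$regions, file.path(out, "sweep_regions.bed"))
write.table(ov$regions, file.path(out, "sweep_regions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(ov$genes, file.path(out, "sweep_genes.txt"))
print(ov$regions[, c("chrom", "start", "end", "n_windows", "n_genes")])
cat("Candidate genes:", length(ov$genes), "\n")

# scatter summary for a Z-Fst vs log2-ratio outlier plot
scatter <- sw[sw$rankable, c("chrom", "start", "end", "z_fst", "log2_ratio")]
scatter$selected <- paste(scatter$chrom, scatter$start) %in%
  paste(sel$chrom, sel$start)
write.table(scatter, file.path(out, "fst_pi_scatter.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

jsonlite::write_json(params, file.path(out, "params.json"),
                     auto_unbox = TRUE, pretty = TRUE)
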