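test_that("z_transform standardizes to zero mean, unit sd", {
  expect_equal(z_transform(c(0.1, 0.2, 0.3)), c(-1, 0, 1))
  set.seed(7)
  x <- rnorm(50)
  z <- z_transform(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(z_transform(z), z)  # idempotent on standardized input
  expect_error(z_transform(0.5), ">= 2")
  expect_error(z_transform(c(1, 1, 1)), "zero spread")
})

test_that("sweep statistics orient the diversity ratio toward candidate depletion", {
  spec <- geno_sim_spec(
    n_pops = 2, n_per_pop = 20, n_snps = 4000, chrom_length = 2e6,
    fst = 0.05,
    sweeps = data.frame(start = 1e6, end = 1.1e6, factor = 10,
                        local_fst = 0.6, pop = 1),
    seed = 21)
  sim <- simulate_genotypes(spec)
  cand <- sim$pops$sample[sim$pops$population == "pop1"]
  refs <- sim$pops$sample[sim$pops$population == "pop2"]
  sw <- compute_sweep_stats(sim$genotypes, cand, refs,
                            chrom_lengths = c(chr1 = 2e6))
  expect_error(compute_sweep_stats(sim$genotypes, cand, c(cand[1], refs)),
               "disjoint")
  inside <- sw$start >= 1e6 & sw$end <= 1.1e6 & sw$rankable
  # diversity reduced 10x in the candidate: log2 ratio near log2(10) = 3.32
  expect_lt(abs(mean(sw$log2_ratio[inside]) - log2(10)), 0.8)
  # Z-scores are centred over rankable windows
  expect_lt(abs(mean(sw$z_fst[sw$rankable])), 1e-10)
  # equal diversities give log2 ratio 0
  i <- which(sw$rankable)[1]
  expect_equal(log2(sw$pi_reference[i] / sw$pi_candidate[i]),
               sw$log2_ratio[i])
})

test_that("top-quantile intersection selects exactly the joint upper tail", {
  mk <- function(z, lr) data.frame(
    chrom = "c", start = seq_along(z) * 10L, end = seq_along(z) * 10L + 20L,
    n_sites = 50L, fst = z, z_fst = z, pi_candidate = 1, pi_reference = 1,
    log2_ratio = lr, rankable = TRUE)
  # both statistics in the same rank order: exactly the top 5 of 100
  w <- mk(seq_len(100) / 100, seq_len(100) / 50)
  sel <- select_top_intersection(w, q = 0.05)
  expect_equal(sort(sel$z_fst), (96:100) / 100)
  # anti-correlated ranks: empty selection
  w2 <- mk(seq_len(100), rev(seq_len(100)))
  expect_equal(nrow(select_top_intersection(w2, q = 0.05)), 0)
  # all-tied statistics: every window ties the threshold, all selected
  w3 <- mk(rep(1, 30), rep(2, 30))
  expect_equal(nrow(select_top_intersection(w3, q = 0.05)), 30)
})

test_that("selection is monotone in q and marginal counts follow ceiling(q n)", {
  set.seed(33)
  w <- data.frame(chrom = "c", start = 1:97 * 10L, end = 1:97 * 10L + 20L,
                  n_sites = 50L, fst = rnorm(97), z_fst = rnorm(97),
                  pi_candidate = 1, pi_reference = 1,
                  log2_ratio = rnorm(97), rankable = TRUE)
  s1 <- select_top_intersection(w, q = 0.10)
  s2 <- select_top_intersection(w, q = 0.05)
  expect_true(all(paste(s2$start) %in% paste(s1$start)))
  for (q in c(0.05, 0.1, 0.2)) {
    sel <- select_top_intersection(w, q = q)
    n_fst <- sum(w$z_fst >= attr(sel, "z_fst_threshold"))
    expect_equal(n_fst, ceiling(q * nrow(w)))  # distinct values: no ties
  }
  expect_error(select_top_intersection(w[1:10, ]), ">= 20")
})

test_that("merge_regions merges overlapping same-chromosome windows only", {
  sel <- data.frame(chrom = c("c1", "c1", "c2"),
                    start = c(0L, 10000L, 0L), end = c(20000L, 30000L, 20000L),
                    z_fst = c(1, 2, 3), log2_ratio = c(4, 5, 6))
  reg <- merge_regions(sel)
  expect_equal(nrow(reg), 2)
  r1 <- reg[reg$chrom == "c1", ]
  expect_equal(c(r1$start, r1$end, r1$n_windows), c(0, 30000, 2))
  expect_equal(r1$peak_z_fst, 2)
  expect_equal(r1$peak_log2_ratio, 5)
  # three chained overlapping windows merge into one region of 3
  sel3 <- data.frame(chrom = "c", start = c(0L, 10000L, 20000L),
                     end = c(20000L, 30000L, 40000L),
                     z_fst = 1:3, log2_ratio = 1:3)
  expect_equal(merge_regions(sel3)$n_windows, 3L)
  # per-chromosome output intervals are pairwise disjoint
  set.seed(9)
  many <- data.frame(chrom = "c", start = sort(sample(0:50, 12)) * 1000L,
                     z_fst = rnorm(12), log2_ratio = rnorm(12))
  many$end <- many$start + 20000L
  m <- merge_regions(many)
  expect_true(all(m$start[-1] > m$end[-nrow(m)]))
})

test_that("gene overlap respects the half-open convention and deduplicates", {
  reg <- data.frame(chrom = "c", start = c(0L, 50000L),
                    end = c(30000L, 80000L),
                    n_windows = 1L, peak_z_fst = 1, peak_log2_ratio = 1)
  genes <- data.frame(
    chrom = "c",
    start = c(5000L, 29999L, 30000L, 60000L, 60000L),
    end = c(8000L, 30100L, 31000L, 61000L, 61000L) + c(0L, 0L, 0L, 0L, 0L),
    strand = "+",
    gene_id = c("gA", "gB", "gC", "gD", "gD"))
  # gC starts exactly at region 1's end: half-open, so not assigned there
  ov <- overlap_genes(reg[1, , drop = FALSE], genes[1:3, ])
  expect_equal(ov$genes, c("gA", "gB"))
  # a gene ending exactly at a region start is not assigned
  g2 <- data.frame(chrom = "c", start = 40000L, end = 50000L, strand = "+",
                   gene_id = "gE")
  expect_equal(overlap_genes(reg[2, , drop = FALSE], g2)$genes, character(0))
  # duplicate gene rows count once in the flat list
  ov2 <- overlap_genes(reg, genes)
  expect_equal(ov2$genes, c("gA", "gB", "gD"))
})

test_that("sweep scan recovers an injected sweep on the default fixture scenario", {
  spec <- geno_sim_spec(
    n_pops = 2, n_per_pop = 20, n_snps = 5000, chrom_length = 2e6,
    fst = 0.05,
    sweeps = data.frame(start = 1e6, end = 1.1e6, factor = 10,
                        local_fst = 0.6, pop = 1),
    seed = 55)
  sim <- simulate_genotypes(spec)
  cand <- sim$pops$sample[sim$pops$population == "pop1"]
  refs <- sim$pops$sample[sim$pops$population == "pop2"]
  sw <- compute_sweep_stats(sim$genotypes, cand, refs,
                            chrom_lengths = c(chr1 = 2e6))
  sel <- select_top_intersection(sw, q = 0.05)
  key <- function(d) paste(d$chrom, d$start)
  inside <- sw$start >= 1e6 & sw$end <= 1.1e6
  outside <- sw$end <= 1e6 | sw$start >= 1.1e6
  expect_gte(mean(key(sw)[inside] %in% key(sel)), 0.8)
  expect_lte(mean(key(sw)[outside & sw$rankable] %in% key(sel)), 0.02)
  reg <- merge_regions(sel)
  expect_true(any(reg$start <= 1.1e6 & reg$end >= 1e6))
})
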