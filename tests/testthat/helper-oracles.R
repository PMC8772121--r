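# Independent oracles used by the property and acceptance tests.  These are
# deliberately written along different computational routes than the package
# implementations they check.

# Weir-Cockerham Fst via the nested-ANOVA mean-squares route: allele
# indicators nested in individuals nested in populations, with
# sigma2_within = MSG, sigma2_ind = (MSI - MSG)/2, sigma2_pop =
# (MSP - MSI)/(2 nc).  Returns the ratio-of-sums estimate over all sites.
oracle_wc_fst <- function(dosage, popvec) {
  tot <- c(a = 0, b = 0, c = 0)
  for (s in seq_len(nrow(dosage))) {
    d <- dosage[s, ]
    ok <- !is.na(d)
    d <- d[ok]; pv <- as.character(popvec[ok])
    tab <- table(pv)
    if (length(tab) < 2) next
    n_i <- as.numeric(tab)
    r <- length(n_i)
    n <- sum(n_i)
    if (n / r <= 1) next
    p_i <- tapply(d, pv, function(x) sum(x) / (2 * length(x)))[names(tab)]
    pbar <- sum(d) / (2 * n)
    SSG <- sum(d == 1) * 0.5
    SSI <- sum(2 * (d / 2 - p_i[pv])^2)
    SSP <- sum(2 * n_i * (p_i - pbar)^2)
    MSG <- SSG / n
    MSI <- SSI / (n - r)
    MSP <- SSP / (r - 1)
    nc <- (n - sum(n_i^2) / n) / (r - 1)
    tot <- tot + c((MSP - MSI) / (2 * nc), (MSI - MSG) / 2, MSG)
  }
  tot[["a"]] / sum(tot)
}

# window nucleotide diversity by exhaustive enumeration of all unordered
# allele pairs at every site: mean pairwise Hamming difference per bp
oracle_window_pi <- function(dosage, pos, start, end) {
  in_win <- (pos - 1) >= start & (pos - 1) < end
  total <- 0
  for (s in which(in_win)) {
    d <- dosage[s, ]
    d <- d[!is.na(d)]
    alleles <- unlist(lapply(d, function(x) c(rep(1, x), rep(0, 2 - x))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      diffs <- diffs + (alleles[i] != alleles[j])
    total <- total + diffs / choose(n, 2)
  }
  total / (end - start)
}

# random small genotype matrix with missingness, for exhaustive-instance
# property loops
random_small_genotypes <- function(n_pops = 2, max_samples = 6,
                                   max_sites = 20, miss = 0.05) {
  ns <- sample(2:max_samples, n_pops, replace = TRUE)
  m <- sample(1:max_sites, 1)
  d <- matrix(sample(c(0L, 1L, 2L, NA),
                     m * sum(ns), replace = TRUE,
                     prob = c(0.35, 0.3, 0.3, miss)), m)
  samples <- paste0("s", seq_len(sum(ns)))
  g <- genotype_matrix(
    data.frame(chrom = "chr1", pos = seq_len(m) * 10L,
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    samples, d)
  list(g = g,
       pops = population_map(samples, rep(paste0("p", seq_len(n_pops)), ns)),
       dosage = d)
}

# toy VCF text written to a temp file; returns the path
write_toy_vcf <- function(records, samples = c("S1", "S2", "S3")) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), f)
  f
}
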