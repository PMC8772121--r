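test_that("window pi matches hand-computed and scaling examples", {
  # one SNP, 4 non-missing alleles split 2/2 (dosages 1,1 over 2 samples),
  # 10-bp window: pi = (2*2/C(4,2)) / 10 = 0.0666667
  g <- genotype_matrix(data.frame(chrom = "c", pos = 5L, ref = "A", alt = "G"),
                       c("s1", "s2"), matrix(c(1L, 1L), 1))
  w10 <- data.frame(chrom = "c", start = 0L, end = 10L)
  expect_equal(window_pi(g, w10)$pi, (4 / 6) / 10, tolerance = 1e-12)
  # doubling the window size halves pi
  w20 <- data.frame(chrom = "c", start = 0L, end = 20L)
  expect_equal(window_pi(g, w20)$pi, (4 / 6) / 20, tolerance = 1e-12)
  # monomorphic window
  g0 <- genotype_matrix(data.frame(chrom = "c", pos = 5L, ref = "A",
                                   alt = "G"),
                        c("s1", "s2"), matrix(c(0L, 0L), 1))
  expect_equal(window_pi(g0, w10)$pi, 0)
  # zero usable sites
  wempty <- data.frame(chrom = "c", start = 100L, end = 110L)
  out <- window_pi(g, wempty)
  expect_equal(out$pi, 0)
  expect_equal(out$n_sites, 0L)
})

test_that("window pi equals the exhaustive allele-pair oracle", {
  set.seed(101)
  for (i in 1:8) {
    r <- random_small_genotypes(n_pops = 1, max_samples = 6, max_sites = 20)
    end <- max(r$g$sites$pos)
    w <- data.frame(chrom = "chr1", start = 0L, end = end)
    expect_equal(window_pi(r$g, w)$pi,
                 oracle_window_pi(r$dosage, r$g$sites$pos, 0, end),
                 tolerance = 1e-12)
  }
})

test_that("pi is invariant under sample reordering", {
  r <- random_small_genotypes(n_pops = 1, max_samples = 6)
  w <- data.frame(chrom = "chr1", start = 0L, end = 250L)
  perm <- sample(seq_along(r$g$samples))
  expect_equal(window_pi(r$g, w)$pi,
               window_pi(subset_genotypes(r$g, samples = perm), w)$pi)
})

test_that("W&C Fst handles fixation and duplicated-population edge cases", {
  # pop1 fixed ref, pop2 fixed alt -> Fst = 1
  d <- matrix(c(rep(0L, 3), rep(2L, 3)), 1)
  g <- genotype_matrix(data.frame(chrom = "c", pos = 1L, ref = "A",
                                  alt = "G"), paste0("s", 1:6), d)
  pm <- population_map(paste0("s", 1:6), rep(c("p1", "p2"), each = 3))
  expect_equal(wc_fst_global(g, pm), 1)
  # two identical populations -> small negative (<= 0)
  d2 <- matrix(rep(c(0L, 1L, 2L, 1L), 2), nrow = 1)
  g2 <- genotype_matrix(data.frame(chrom = "c", pos = 1L, ref = "A",
                                   alt = "G"), paste0("s", 1:8), d2)
  pm2 <- population_map(paste0("s", 1:8), rep(c("p1", "p2"), each = 4))
  expect_lte(wc_fst_global(g2, pm2), 0)
})

test_that("W&C Fst matches the 1984 formulas on a specified configuration", {
  # 2 pops x 5 diploids, p1 = 0.9 (1 het + 4 hom alt), p2 = 0.1, h1 = h2 = 0.2
  d <- matrix(c(1L, 2L, 2L, 2L, 2L, 1L, 0L, 0L, 0L, 0L), 1)
  g <- genotype_matrix(data.frame(chrom = "c", pos = 1L, ref = "A",
                                  alt = "G"), paste0("s", 1:10), d)
  pm <- population_map(paste0("s", 1:10), rep(c("p1", "p2"), each = 5))
  expect_equal(wc_fst_global(g, pm),
               oracle_wc_fst(d, rep(c("p1", "p2"), each = 5)),
               tolerance = 1e-12)
})

test_that("W&C Fst equals the independent ANOVA oracle on small instances", {
  set.seed(42)
  for (i in 1:20) {
    r <- random_small_genotypes(n_pops = sample(2:3, 1), max_samples = 6,
                                max_sites = 10)
    est <- wc_fst_global(r$g, r$pops)
    ora <- oracle_wc_fst(r$dosage, r$pops$population)
    if (is.finite(ora)) expect_equal(est, ora, tolerance = 1e-12)
  }
})

test_that("Fst is invariant under population relabeling and killed by permutation", {
  sim <- simulate_genotypes(geno_sim_spec(n_pops = 2, n_per_pop = 15,
                                          n_snps = 5000,
                                          chrom_length = 1e6,
                                          fst = 0.15, seed = 77))
  est <- wc_fst_global(sim$genotypes, sim$pops)
  relab <- sim$pops
  relab$population <- c(pop1 = "east", pop2 = "west")[relab$population]
  expect_equal(wc_fst_global(sim$genotypes, relab), est)
  set.seed(5)
  perm <- sim$pops
  perm$population <- sample(perm$population)
  expect_lt(abs(wc_fst_global(sim$genotypes, perm)), 0.01)
})

test_that("windowed Fst flags empty windows and reports components", {
  sim <- simulate_genotypes(geno_sim_spec(n_pops = 2, n_per_pop = 5,
                                          n_snps = 50, chrom_length = 1e4,
                                          fst = 0.1, seed = 3))
  w <- rbind(make_windows(c(chr1 = 1e4), 5000, 5000),
             data.frame(chrom = "chr2", start = 0, end = 5000))
  out <- wc_fst_window(sim$genotypes, sim$pops, w)
  expect_true(is.nan(out$fst[3]))       # no sites on chr2
  expect_equal(out$fst[1],
               out$sum_a[1] / (out$sum_a[1] + out$sum_b[1] + out$sum_c[1]))
})

test_that("pairwise Fst matrices are symmetric and behave under panmixia/fixation", {
  sim <- simulate_genotypes(geno_sim_spec(n_pops = 3, n_per_pop = 10,
                                          n_snps = 2000,
                                          chrom_length = 1e6, fst = 0,
                                          seed = 19))
  m <- pairwise_fst_matrix(sim$genotypes, sim$pops)
  expect_identical(unclass(m), t(unclass(m)))
  expect_true(all(abs(m[upper.tri(m)]) < 0.02))
  # opposite fixation -> Fst = 1
  d <- matrix(c(rep(0L, 2), rep(2L, 2)), 2, 4, byrow = TRUE)
  g <- genotype_matrix(data.frame(chrom = "c", pos = c(1L, 2L), ref = "A",
                                  alt = "G"), paste0("s", 1:4), d)
  pm <- population_map(paste0("s", 1:4), rep(c("p1", "p2"), each = 2))
  expect_equal(unname(pairwise_fst_matrix(g, pm)["p1", "p2"]), 1)
  # undersized population excluded with warning; remaining pair still computed
  d5 <- matrix(c(rep(0L, 2), rep(2L, 2), 1L), 2, 5, byrow = TRUE)
  g5 <- genotype_matrix(data.frame(chrom = "c", pos = c(1L, 2L), ref = "A",
                                   alt = "G"), paste0("s", 1:5), d5)
  pm3 <- population_map(paste0("s", 1:5), c("p1", "p1", "p2", "p2", "p3"))
  expect_warning(m3 <- pairwise_fst_matrix(g5, pm3), "excluding")
  expect_equal(rownames(m3), c("p1", "p2"))
})

test_that("fst_matrix_summary selects pairs and validates labels", {
  v <- matrix(c(NA, 0.1, 0.3, 0.1, NA, 0.2, 0.3, 0.2, NA), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m <- fst_matrix(v)
  s <- fst_matrix_summary(m)
  expect_equal(s$mean, mean(c(0.1, 0.3, 0.2)))
  expect_equal(s$n_pairs, 3)
  sf <- fst_matrix_summary(m, focal = "A")
  expect_equal(sort(sf$values), c(0.1, 0.3))
  sp <- fst_matrix_summary(m, focal = "A", partners = "C")
  expect_equal(sp$values, 0.3)
  expect_error(fst_matrix_summary(m, focal = "Z"), "known")
})
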