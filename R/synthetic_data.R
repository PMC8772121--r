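#' Specification for a Balding-Nichols genotype simulation
#'
#' Describes a multi-population diploid SNP dataset with controllable
#' differentiation.  Ancestral allele frequencies are uniform on
#' `anc_range`; each population's frequency is Beta-distributed around the
#' ancestral value with divergence parameter `F` (the Balding-Nichols model,
#' whose expected Weir-Cockerham Fst equals `F`); genotypes are
#' `Binomial(2, p_pop)`; missing calls are i.i.d.  Optional sweep intervals
#' reduce the swept population's expected heterozygosity by exactly the
#' stated `factor` relative to its own background: the local frequency is
#' redrawn at elevated divergence `local_fst` and then pushed to the nearest
#' fixation with the compensating probability, so every injected signal has
#' a closed-form ground truth.
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploid individuals per population.
#' @param n_snps SNP count.
#' @param chrom_length chromosome length in bp.
#' @param fst per-population divergence F in [0, 1); scalar or vector.
#' @param anc_range range of ancestral allele frequencies.
#' @param missing_rate i.i.d. missing-genotype rate in [0, 1).
#' @param sweeps NULL or data.frame with columns `start`, `end` (0-based
#'   half-open bp), `factor` (diversity reduction, >= 1), `local_fst`, `pop`
#'   (1-based index of the swept population).
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return list of class `geno_sim_spec`.
#' @export
geno_sim_spec <- function(n_pops = 2, n_per_pop = 20, n_snps = 5000,
                          chrom_length = 2e6, fst = 0.05,
                          anc_range = c(0.05, 0.95), missing_rate = 0,
                          sweeps = NULL, chrom = "chr1", seed = 1) {
  fst <- rep_len(fst, n_pops)
  stopifnot(n_pops >= 1, n_per_pop >= 1, n_snps >= 1,
            chrom_length >= n_snps, all(fst >= 0), all(fst < 1),
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(sweeps)) {
    stopifnot(all(c("start", "end", "factor", "local_fst", "pop") %in%
                    names(sweeps)),
              all(sweeps$start >= 0), all(sweeps$end <= chrom_length),
              all(sweeps$end > sweeps$start), all(sweeps$factor >= 1),
              all(sweeps$pop >= 1), all(sweeps$pop <= n_pops))
  }
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_snps = n_snps,
                 chrom_length = chrom_length, fst = fst,
                 anc_range = anc_range, missing_rate = missing_rate,
                 sweeps = sweeps, chrom = chrom, seed = seed),
            class = "geno_sim_spec")
}

# Balding-Nichols draw: population frequency around ancestral p at divergence F
.bn_draw <- function(p, f) {
  if (f == 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Deterministic given the spec (which includes the seed): identical specs
#' give identical output.  The truth record stores the realised
#' per-population frequencies — including sweep modifications — so that
#' model-predicted statistics (e.g. the large-sample Weir-Cockerham Fst, via
#' [true_fst()]) can be computed without re-simulation.
#'
#' @param spec a [geno_sim_spec()].
#' @return list: `genotypes` (a `genotype_matrix`), `pops` (population map),
#'   `truth` (list: `positions` 1-based, `p_anc`, `pop_freq` sites x pops
#'   matrix, `pop_labels`, `sweeps`, `spec`).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "geno_sim_spec"))
  set.seed(spec$seed)
  m <- spec$n_snps
  pos <- sort(sample.int(spec$chrom_length, m))
  p_anc <- stats::runif(m, spec$anc_range[1], spec$anc_range[2])
  labs <- sprintf("pop%d", seq_len(spec$n_pops))
  P <- vapply(seq_len(spec$n_pops),
              function(i) .bn_draw(p_anc, spec$fst[i]), numeric(m))
  colnames(P) <- labs
  if (!is.null(spec$sweeps)) {
    for (s in seq_len(nrow(spec$sweeps))) {
      sw <- spec$sweeps[s, ]
      in_sw <- (pos - 1) >= sw$start & (pos - 1) < sw$end
      if (!any(in_sw)) next
      pl <- .bn_draw(p_anc[in_sw], sw$local_fst)
      # push to fixation with the probability that makes the expected
      # within-population heterozygosity, relative to the background of the
      # same population, exactly 1/factor: the local Balding-Nichols redraw
      # already shrinks E[2p(1-p)] by (1 - local_fst)/(1 - F_background)
      p_push <- max(0, 1 - (1 - spec$fst[sw$pop]) /
                      (sw$factor * (1 - sw$local_fst)))
      push <- stats::runif(sum(in_sw)) < p_push
      P[in_sw, sw$pop] <- ifelse(push, round(pl), pl)
    }
  }
  n_tot <- spec$n_pops * spec$n_per_pop
  dosage <- matrix(NA_integer_, m, n_tot)
  samples <- character(n_tot)
  for (i in seq_len(spec$n_pops)) {
    colidx <- (i - 1) * spec$n_per_pop + seq_len(spec$n_per_pop)
    samples[colidx] <- sprintf("%s_ind%02d", labs[i], seq_len(spec$n_per_pop))
    dosage[, colidx] <- stats::rbinom(m * spec$n_per_pop, 2,
                                      rep(P[, i], spec$n_per_pop))
  }
  if (spec$missing_rate > 0)
    dosage[stats::runif(length(dosage)) < spec$missing_rate] <- NA_integer_
  ref <- rep_len(c("A", "C", "G", "T"), m)
  alt <- rep_len(c("G", "T", "A", "C"), m)
  g <- genotype_matrix(
    data.frame(chrom = spec$chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    samples, dosage)
  pops <- population_map(samples, rep(labs, each = spec$n_per_pop))
  list(genotypes = g, pops = pops,
       truth = list(positions = pos, p_anc = p_anc, pop_freq = P,
                    pop_labels = labs, sweeps = spec$sweeps, spec = spec))
}

#' Model-predicted Fst from true population frequencies
#'
#' The large-sample limit of the ratio-of-sums Weir-Cockerham estimator,
#' evaluated on known per-population frequencies: per site,
#' `s2 = sum((p_i - pbar)^2) / (r - 1)` and the total-variance denominator is
#' `pbar (1 - pbar) + s2 / r`; the genome-wide value is the ratio of sums
#' over sites.  Used as the truth-record oracle in parameter-recovery tests.
#'
#' @param pop_freq sites x populations matrix of true frequencies (at least
#'   two columns; pass a column subset for a pairwise value).
#' @return a single numeric Fst.
#' @export
true_fst <- function(pop_freq) {
  r <- ncol(pop_freq)
  stopifnot(r >= 2)
  pbar <- rowMeans(pop_freq)
  s2 <- rowSums((pop_freq - pbar)^2) / (r - 1)
  sum(s2) / sum(pbar * (1 - pbar) + s2 / r)
}

#' Simulate linked genotypes for LD-decay analysis
#'
#' Haplotypes are generated from a per-haplotype latent Gaussian process
#' whose correlation between adjacent sites decays as `exp(-d / decay_length)`
#' with physical distance `d`, thresholded at each site's allele-frequency
#' quantile (a Gaussian-copula haplotype model).  Squared dosage correlation
#' therefore decays smoothly with distance at a configurable length scale.
#'
#' @param n_samples diploid individuals.
#' @param n_snps SNP count.
#' @param chrom_length chromosome length in bp.
#' @param decay_length correlation length scale in bp.
#' @param p_range allele-frequency range.
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return a `genotype_matrix`.
#' @export
simulate_linked_genotypes <- function(n_samples = 50, n_snps = 500,
                                      chrom_length = 1e6,
                                      decay_length = 20000,
                                      p_range = c(0.1, 0.9),
                                      chrom = "chr1", seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_length, n_snps))
  p <- stats::runif(n_snps, p_range[1], p_range[2])
  rho <- exp(-diff(pos) / decay_length)
  hap <- function() {
    z <- numeric(n_snps)
    z[1] <- stats::rnorm(1)
    e <- stats::rnorm(n_snps - 1)
    for (j in 2:n_snps) z[j] <- rho[j - 1] * z[j - 1] +
        sqrt(1 - rho[j - 1]^2) * e[j - 1]
    as.integer(z < stats::qnorm(p))
  }
  dosage <- matrix(0L, n_snps, n_samples)
  for (i in seq_len(n_samples)) dosage[, i] <- hap() + hap()
  genotype_matrix(
    data.frame(chrom = chrom, pos = pos,
               ref = rep_len(c("A", "C", "G", "T"), n_snps),
               alt = rep_len(c("G", "T", "A", "C"), n_snps),
               stringsAsFactors = FALSE),
    sprintf("ind%03d", seq_len(n_samples)), dosage)
}

# --- landmark simulation ----------------------------------------------------

#' Default wing-landmark template
#'
#' A deterministic non-degenerate k-landmark template (points on an
#' elongated ellipse, proportioned like a wing outline) used as the default
#' mean shape: 20 landmarks for a forewing-like scheme, 10 for a
#' hindwing-like scheme.
#'
#' @param k landmark count.
#' @return k x 2 coordinate matrix with centroid at origin.
#' @export
default_wing_template <- function(k = 20) {
  t <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  xy <- cbind(cos(t) * 2, sin(t) * 0.8)
  sweep(xy, 2, colMeans(xy))
}

#' Specification for a landmark simulation
#'
#' Each specimen is the mean shape plus its group's shape offset plus
#' isotropic Gaussian landmark noise, scaled to a true centroid size drawn
#' from a linear model on its site's latitude and altitude, then subjected to
#' nuisance rotation, translation and (recorded) image scale.
#'
#' @param mean_shape k x 2 template (default [default_wing_template()]).
#' @param sites data.frame with columns `site`, `group`, `latitude`,
#'   `longitude`, `altitude` (one row per sampling site).
#' @param n_per_site specimens per site.
#' @param group_offsets named list (by group) of k x 2 displacement matrices
#'   applied to the unit-size mean shape; groups absent from the list get no
#'   offset.
#' @param landmark_noise_sd isotropic landmark noise sd (shape units).
#' @param cs_base,cs_lat_slope,cs_alt_slope,cs_noise_sd centroid-size model:
#'   `CS = cs_base + cs_lat_slope * latitude + cs_alt_slope * altitude +
#'   N(0, cs_noise_sd)`.
#' @param rotation_range,translation_range,scale_range nuisance-transform
#'   ranges (radians, coordinate units, multiplicative).
#' @param seed RNG seed.
#' @return list of class `morpho_sim_spec`.
#' @export
morpho_sim_spec <- function(mean_shape = default_wing_template(20),
                            sites, n_per_site = 10,
                            group_offsets = list(),
                            landmark_noise_sd = 0.01,
                            cs_base = 6, cs_lat_slope = 0,
                            cs_alt_slope = 0, cs_noise_sd = 0,
                            rotation_range = c(-pi, pi),
                            translation_range = c(-5, 5),
                            scale_range = c(1, 1),
                            seed = 1) {
  stopifnot(is.matrix(mean_shape), ncol(mean_shape) == 2,
            nrow(mean_shape) >= 3,
            all(c("site", "group", "latitude", "longitude", "altitude") %in%
                  names(sites)),
            landmark_noise_sd >= 0, cs_noise_sd >= 0,
            all(scale_range > 0))
  if (stats::sd(mean_shape[, 1]) == 0 || stats::sd(mean_shape[, 2]) == 0 ||
      abs(stats::cor(mean_shape[, 1], mean_shape[, 2])) > 1 - 1e-12)
    stop("degenerate (collinear) mean shape")
  structure(list(mean_shape = mean_shape, sites = sites,
                 n_per_site = n_per_site, group_offsets = group_offsets,
                 landmark_noise_sd = landmark_noise_sd, cs_base = cs_base,
                 cs_lat_slope = cs_lat_slope, cs_alt_slope = cs_alt_slope,
                 cs_noise_sd = cs_noise_sd, rotation_range = rotation_range,
                 translation_range = translation_range,
                 scale_range = scale_range, seed = seed),
            class = "morpho_sim_spec")
}

#' Simulate landmark configurations with known ground truth
#'
#' @param spec a [morpho_sim_spec()].
#' @return list: `configs` (TPS-style configuration list; coordinates carry
#'   the nuisance image scale, with the corrective `SCALE=` factor recorded),
#'   `metadata` (specimen, site, group, latitude, longitude, altitude),
#'   `truth` (true CS, rotation, translation, image scale per specimen, plus
#'   the spec).
#' @export
simulate_landmarks <- function(spec) {
  stopifnot(inherits(spec, "morpho_sim_spec"))
  set.seed(spec$seed)
  base <- .center_scale(spec$mean_shape)  # unit CS
  k <- nrow(base)
  configs <- list(); meta <- list(); truth <- list()
  idx <- 0
  for (s in seq_len(nrow(spec$sites))) {
    row <- spec$sites[s, ]
    off <- spec$group_offsets[[as.character(row$group)]]
    if (is.null(off)) off <- matrix(0, k, 2)
    for (j in seq_len(spec$n_per_site)) {
      idx <- idx + 1
      id <- sprintf("%s_%02d", row$site, j)
      shape <- base + off +
        matrix(stats::rnorm(2 * k, 0, spec$landmark_noise_sd), k, 2)
      cs_true <- spec$cs_base + spec$cs_lat_slope * row$latitude +
        spec$cs_alt_slope * row$altitude +
        stats::rnorm(1, 0, spec$cs_noise_sd)
      theta <- stats::runif(1, spec$rotation_range[1], spec$rotation_range[2])
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      tr <- stats::runif(2, spec$translation_range[1],
                         spec$translation_range[2])
      img_scale <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
      xy <- shape / centroid_size(shape) * cs_true
      xy <- sweep(xy %*% R, 2, tr, `+`)
      # coords are held in calibrated units; `scale` records the image
      # calibration so written TPS carries pixel coordinates plus SCALE=
      configs[[idx]] <- list(id = id, coords = xy, scale = 1 / img_scale)
      meta[[idx]] <- data.frame(specimen = id, site = row$site,
                                group = row$group, latitude = row$latitude,
                                longitude = row$longitude,
                                altitude = row$altitude)
      truth[[idx]] <- data.frame(specimen = id, group = row$group,
                                 true_cs = cs_true, rotation = theta,
                                 tx = tr[1], ty = tr[2],
                                 image_scale = img_scale)
    }
  }
  list(configs = configs,
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       truth = list(specimens = do.call(rbind,
                                        c(truth, list(make.row.names = FALSE))),
                    spec = spec))
}

#' Write the default synthetic fixture suite
#'
#' Materialises a complete small analysis scenario with fixed seed: a
#' two-population Balding-Nichols cohort (20 diploids each, 5000 SNPs on a
#' 2-Mb chromosome) carrying one 100-kb sweep in population 1, a matching
#' population map, a fake gene annotation tiling the chromosome, a
#' five-region wing-landmark dataset (10 specimens per region) with a
#' latitude effect on centroid size, truth records as JSON, and a manifest
#' with md5 checksums.
#'
#' @param out_dir output directory; must be empty or absent unless
#'   `overwrite`.
#' @param seed base RNG seed.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
make_fixture_suite <- function(out_dir, seed = 1, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("refusing to write into non-empty directory ", out_dir,
         " (use overwrite = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  gspec <- geno_sim_spec(
    n_pops = 2, n_per_pop = 20, n_snps = 5000, chrom_length = 2e6,
    fst = 0.05, missing_rate = 0.02,
    sweeps = data.frame(start = 1000000, end = 1100000, factor = 10,
                        local_fst = 0.6, pop = 1),
    seed = seed)
  sim <- simulate_genotypes(gspec)
  write_vcf(sim$genotypes, file.path(out_dir, "cohort.vcf"))
  write_population_map(sim$pops, file.path(out_dir, "popmap.tsv"))

  # fake genes tiling the chromosome: 4-kb genes every 10 kb
  gstart <- seq(0, gspec$chrom_length - 4000, by = 10000)
  gff <- sprintf("%s\tapiscan\tgene\t%d\t%d\t.\t%s\t.\tID=gene%04d",
                 gspec$chrom, gstart + 1, gstart + 4000,
                 rep_len(c("+", "-"), length(gstart)), seq_along(gstart))
  writeLines(c("##gff-version 3", gff), file.path(out_dir, "genes.gff3"))

  # five regions sampled at two sites each (within-region spread in latitude
  # and altitude gives the size-on-geography regression usable support)
  regions <- data.frame(
    site = sprintf("site%02d", 1:10),
    group = rep(c("RegionA", "RegionB", "RegionC", "RegionD", "RegionE"),
                each = 2),
    latitude = c(42.1, 41.6, 40.5, 39.2, 36.2, 34.8, 30.0, 31.4, 23.5, 25.1),
    longitude = c(128.1, 127.5, 125.0, 124.1, 103.8, 105.2, 91.1, 92.6,
                  110.3, 109.8),
    altitude = c(1100, 850, 300, 420, 1500, 1250, 3600, 3350, 150, 600))
  mspec <- morpho_sim_spec(
    mean_shape = default_wing_template(20), sites = regions,
    n_per_site = 5,
    group_offsets = list(RegionA = 0.03 * default_wing_template(20)[, 2:1]),
    landmark_noise_sd = 0.01, cs_base = 5.2, cs_lat_slope = 0.02,
    cs_alt_slope = 2e-4, cs_noise_sd = 0.05,
    scale_range = c(0.8, 1.25), seed = seed + 1000L)
  msim <- simulate_landmarks(mspec)
  write_tps(msim$configs, file.path(out_dir, "forewing.tps"))
  utils::write.table(msim$metadata, file.path(out_dir, "wing_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(
    list(positions = sim$truth$positions, p_anc = sim$truth$p_anc,
         pop_freq = sim$truth$pop_freq, pop_labels = sim$truth$pop_labels,
         sweeps = sim$truth$sweeps, seed = seed),
    file.path(out_dir, "truth_genotypes.json"), digits = NA)
  jsonlite::write_json(
    msim$truth$specimens, file.path(out_dir, "truth_landmarks.json"),
    digits = NA)

  files <- c("cohort.vcf", "popmap.tsv", "genes.gff3", "forewing.tps",
             "wing_metadata.tsv", "truth_genotypes.json",
             "truth_landmarks.json")
  manifest <- data.frame(
    file = files,
    md5 = as.character(tools::md5sum(file.path(out_dir, files))))
  utils::write.table(manifest, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
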