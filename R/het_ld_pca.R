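#' Heterozygosity and inbreeding coefficients
#'
#' Per-individual observed/expected homozygosity and the method-of-moments
#' inbreeding coefficient, plus per-population summaries.  For each site the
#' expected heterozygosity is `He = 2 p (1 - p)` with `p` the alternate-allele
#' frequency in the individual's own population (no small-sample correction);
#' an individual's expected homozygote count sums `1 - He` over the sites at
#' which it is genotyped, and
#' `F = (observed_hom - expected_hom) / (n_sites_used - expected_hom)`.
#' Population `He`/`Ho`/`F` are unweighted means across sites / individuals.
#'
#' @param g a `genotype_matrix`.
#' @param pops a population map.
#' @return list with `per_individual` (sample, population, n_sites_used,
#'   observed_hom, expected_hom, F) and `per_population` (population, He, Ho,
#'   F, n_individuals) data.frames.  Individuals whose F denominator is zero
#'   get `F = NaN` and are excluded from the population mean.
#' @export
het_and_inbreeding <- function(g, pops) {
  cols <- .pop_columns(g, pops, min_n = 1, warn = FALSE)
  ind <- list(); popsum <- list()
  for (lab in names(cols)) {
    d <- g$dosage[, cols[[lab]], drop = FALSE]
    n <- rowSums(!is.na(d))
    p <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA_real_)
    he_site <- 2 * p * (1 - p)
    used <- !is.na(d) & !is.na(he_site)
    n_used <- colSums(used)
    exp_hom <- colSums((1 - he_site) * used, na.rm = TRUE)
    obs_hom <- colSums((d == 0L | d == 2L) & used, na.rm = TRUE)
    denom <- n_used - exp_hom
    f <- ifelse(denom != 0, (obs_hom - exp_hom) / denom, NaN)
    ho_ind <- ifelse(n_used > 0, colSums((d == 1L) & used) / n_used, NaN)
    ind[[lab]] <- data.frame(
      sample = g$samples[cols[[lab]]], population = lab,
      n_sites_used = n_used, observed_hom = obs_hom,
      expected_hom = exp_hom, F = f, row.names = NULL)
    popsum[[lab]] <- data.frame(
      population = lab,
      He = mean(he_site[n > 0], na.rm = TRUE),
      Ho = mean(ho_ind[is.finite(ho_ind)]),
      F = mean(f[is.finite(f)]),
      n_individuals = length(cols[[lab]]))
  }
  list(per_individual = do.call(rbind, c(ind, list(make.row.names = FALSE))),
       per_population = do.call(rbind, c(popsum, list(make.row.names = FALSE))))
}

#' Linkage-disequilibrium decay
#'
#' Composite genotype-dosage LD: for every same-chromosome SNP pair separated
#' by at most `max_dist` bp, `r^2` is the squared Pearson correlation of the
#' two dosage vectors over samples non-missing at both sites (no phasing).
#' Pairs are binned by physical distance and the decay distance is the
#' midpoint of the first bin whose mean `r^2` falls below `threshold`.
#'
#' @param g a `genotype_matrix`.
#' @param samples optional sample subset.
#' @param max_dist maximum pair separation in bp.
#' @param bin_width distance bin width in bp.
#' @param threshold r-squared level defining the decay distance (default 0.1,
#'   the conventional cutoff).
#' @return object of class `ld_decay`: list with `bins` (bin_start, bin_end,
#'   n_pairs, mean_r2), `decay_distance` (NaN when the curve never crosses the
#'   threshold) and `threshold`.  Monomorphic sites are skipped.
#' @export
ld_r2_decay <- function(g, samples = NULL, max_dist = 50000,
                        bin_width = 1000, threshold = 0.1) {
  if (!is.null(samples)) g <- subset_genotypes(g, samples = samples)
  stopifnot(max_dist >= bin_width, bin_width >= 1)
  nb <- ceiling(max_dist / bin_width)
  ssum <- double(nb); cnt <- integer(nb)
  X <- t(g$dosage)  # samples x sites
  for (ch in unique(g$sites$chrom)) {
    si <- which(g$sites$chrom == ch)
    if (length(si) < 2) next
    pos <- g$sites$pos[si]
    v <- apply(X[, si, drop = FALSE], 2, stats::var, na.rm = TRUE)
    ok <- !is.na(v) & v > 0
    si <- si[ok]; pos <- pos[ok]
    hi <- 1L
    for (k in seq_along(si)) {
      if (hi < k + 1L) hi <- k + 1L
      while (hi <= length(si) && pos[hi] - pos[k] <= max_dist) hi <- hi + 1L
      if (hi - 1L <= k) next
      j <- (k + 1L):(hi - 1L)
      r <- suppressWarnings(
        stats::cor(X[, si[k]], X[, si[j], drop = FALSE],
                   use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      b <- pmin(pmax(ceiling((pos[j] - pos[k]) / bin_width), 1L), nb)
      fin <- is.finite(r2)
      if (any(fin)) {
        t1 <- tapply(r2[fin], b[fin], sum)
        t2 <- tapply(rep(1L, sum(fin)), b[fin], sum)
        ii <- as.integer(names(t1))
        ssum[ii] <- ssum[ii] + t1
        cnt[ii] <- cnt[ii] + t2
      }
    }
  }
  bins <- data.frame(bin_start = (seq_len(nb) - 1) * bin_width,
                     bin_end = seq_len(nb) * bin_width,
                     n_pairs = cnt,
                     mean_r2 = ifelse(cnt > 0, ssum / cnt, NaN))
  below <- which(cnt > 0 & bins$mean_r2 < threshold)
  dd <- if (length(below)) (bins$bin_start[below[1]] + bins$bin_end[below[1]]) / 2 else NaN
  structure(list(bins = bins, decay_distance = dd, threshold = threshold),
            class = "ld_decay")
}

#' @rdname ld_r2_decay
#' @param x an `ld_decay` object.
#' @param path output path for the tab-separated curve.
#' @export
write_ld_curve <- function(x, path) {
  utils::write.table(x$bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype principal component analysis
#'
#' Standard normalised genotype PCA for population structure: missing dosages
#' are mean-imputed per site, each site is centred by `2 p` and scaled by
#' `sqrt(2 p (1 - p))` (`p` = alternate-allele frequency estimate), and the
#' sample-by-sample covariance of the standardised matrix is
#' eigendecomposed (via SVD).  Monomorphic sites carry no information and are
#' dropped.
#'
#' @param g a `genotype_matrix`.
#' @param n_components number of leading components to return (clipped with a
#'   warning to `n_samples - 1`).
#' @return list: `scores` (samples x components), `explained` (variance
#'   fractions, non-increasing), `p_hat` (per retained site).
#' @export
genotype_pca <- function(g, n_components = 10) {
  n <- n_samples(g)
  if (n_components > n - 1) {
    warning("n_components clipped to n_samples - 1 = ", n - 1)
    n_components <- n - 1
  }
  D <- g$dosage
  p <- rowMeans(D, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  D <- D[keep, , drop = FALSE]; p <- p[keep]
  imp <- is.na(D)
  if (any(imp)) D[imp] <- (2 * p)[row(D)[imp]]
  G <- t((D - 2 * p) / sqrt(2 * p * (1 - p)))  # samples x sites, cols centred
  sv <- svd(G)
  ev <- sv$d^2
  k <- seq_len(n_components)
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components)
  rownames(scores) <- g$samples
  colnames(scores) <- paste0("PC", k)
  list(scores = scores, explained = ev[k] / sum(ev), p_hat = p)
}

#' Write windowed statistics as tab-separated text
#'
#' Reports 1-based inclusive coordinates, the external convention for all
#' printed output.
#'
#' @param w data.frame with `chrom`, `start` (0-based), `end` and statistic
#'   columns.
#' @param path output path.
#' @export
write_window_stats <- function(w, path) {
  out <- w
  out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
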