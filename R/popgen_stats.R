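# --- per-site summaries -----------------------------------------------------

# per-site, per-population counts from a dosage matrix and a list of sample
# column indices: n (non-missing diploids), p (alt frequency), h (observed
# heterozygote proportion).  Matrices are sites x populations.
.site_pop_stats <- function(dosage, pop_cols) {
  r <- length(pop_cols)
  m <- nrow(dosage)
  N <- P <- H <- matrix(NA_real_, m, r, dimnames = list(NULL, names(pop_cols)))
  for (i in seq_len(r)) {
    d <- dosage[, pop_cols[[i]], drop = FALSE]
    n <- rowSums(!is.na(d))
    N[, i] <- n
    P[, i] <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA_real_)
    H[, i] <- ifelse(n > 0, rowSums(d == 1L, na.rm = TRUE) / n, NA_real_)
  }
  list(N = N, P = P, H = H)
}

#' Weir-Cockerham variance components per site
#'
#' Computes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) variance components of the Weir & Cockerham
#' (1984) Fst estimator for every biallelic site, from per-population sample
#' sizes, allele frequencies and observed heterozygote proportions.  Sites
#' where fewer than two populations carry data, or where the mean sample size
#' does not exceed one diploid, contribute zero components and are flagged.
#'
#' @param g a `genotype_matrix`.
#' @param pops a population map (see [population_map()]); populations with
#'   fewer than 2 genotyped samples overall are excluded.
#' @return data.frame with one row per site: `a`, `b`, `c`, `usable`.
#' @export
wc_site_components <- function(g, pops) {
  cols <- .pop_columns(g, pops, min_n = 2)
  if (length(cols) < 2) stop("need >= 2 populations with >= 2 samples")
  st <- .site_pop_stats(g$dosage, cols)
  .wc_components_from_stats(st$N, st$P, st$H)
}

# the 1984 component formulas, vectorised over sites; N/P/H are sites x pops
.wc_components_from_stats <- function(N, P, H) {
  N[N == 0] <- NA_real_
  r <- rowSums(!is.na(N))
  nsum <- rowSums(N, na.rm = TRUE)
  nbar <- nsum / r
  usable <- r >= 2 & nbar > 1
  n2 <- rowSums(N^2, na.rm = TRUE)
  nc <- (nsum - n2 / nsum) / (r - 1)
  pbar <- rowSums(N * P, na.rm = TRUE) / nsum
  s2 <- rowSums(N * (P - pbar)^2, na.rm = TRUE) / ((r - 1) * nbar)
  hbar <- rowSums(N * H, na.rm = TRUE) / nsum

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  a[!usable] <- 0; b[!usable] <- 0; c_[!usable] <- 0
  data.frame(a = a, b = b, c = c_, usable = usable)
}

# per-site pairwise nucleotide diversity over a sample subset:
# pi_site = n_ref * n_alt / C(n, 2), n = non-missing allele count
.site_pi <- function(dosage) {
  n <- 2 * rowSums(!is.na(dosage))
  nalt <- rowSums(dosage, na.rm = TRUE)
  pi <- rep(NA_real_, nrow(dosage))
  ok <- n >= 2
  pi[ok] <- (n[ok] - nalt[ok]) * nalt[ok] / (n[ok] * (n[ok] - 1) / 2)
  pi
}

# --- windowing --------------------------------------------------------------

# index sites into sliding windows; returns an integer list, one element per
# window, of row indices of g$sites falling inside (0-based half-open
# windows; site internal coordinate is pos - 1)
.window_site_index <- function(sites, windows) {
  pos0 <- sites$pos - 1L
  out <- vector("list", nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- which(sites$chrom == ch)
    if (length(si) == 0) { out[wi] <- list(integer()); next }
    p <- pos0[si]
    for (w in wi) {
      lo <- findInterval(windows$start[w] - 0.5, p) + 1L
      hi <- findInterval(windows$end[w] - 0.5, p)
      out[[w]] <- if (hi >= lo) si[lo:hi] else integer()
    }
  }
  out
}

#' Windowed nucleotide diversity
#'
#' Sliding-window nucleotide diversity (theta-pi).  Per site,
#' `pi = n_ref * n_alt / C(n, 2)` with `n` the number of non-missing alleles
#' in the chosen sample subset; the window value divides the per-site sum by
#' the window length in bp (the windowed-pi convention of VCFtools'
#' `--window-pi`).  A per-variant-site denominator is available via
#' `per_site = TRUE`.
#'
#' @param g a `genotype_matrix`.
#' @param windows data.frame from [make_windows()].
#' @param samples optional sample subset (names or indices); default all.
#' @param per_site divide by the number of usable sites instead of window bp.
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `pi`.  Sites with
#'   fewer than 2 non-missing alleles are skipped; their count is attached as
#'   attribute `n_skipped`.
#' @export
window_pi <- function(g, windows, samples = NULL, per_site = FALSE) {
  if (!is.null(samples)) g <- subset_genotypes(g, samples = samples)
  if (n_samples(g) == 0) stop("empty sample subset")
  pi_site <- .site_pi(g$dosage)
  skipped <- sum(is.na(pi_site))
  idx <- .window_site_index(g$sites, windows)
  ns <- vapply(idx, function(i) sum(!is.na(pi_site[i])), 0L)
  psum <- vapply(idx, function(i) sum(pi_site[i], na.rm = TRUE), 0)
  denom <- if (per_site) pmax(ns, 1L) else windows$end - windows$start
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, n_sites = ns,
                    pi = ifelse(ns > 0, psum / denom, 0))
  attr(out, "n_skipped") <- skipped
  out
}

#' Windowed Weir-Cockerham Fst
#'
#' Sliding-window Fst between two or more populations using the Weir &
#' Cockerham (1984) estimator: per window, `Fst = sum(a) / sum(a + b + c)`
#' over the window's sites (ratio of sums).  Values may be slightly negative;
#' they are reported as-is.  A window whose component sum is zero gets
#' `Fst = NaN`.
#'
#' @inheritParams window_pi
#' @param pops a population map restricted to >= 2 populations.
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `fst`, `sum_a`,
#'   `sum_b`, `sum_c`.
#' @export
wc_fst_window <- function(g, pops, windows) {
  comp <- wc_site_components(g, pops)
  idx <- .window_site_index(g$sites, windows)
  sa <- vapply(idx, function(i) sum(comp$a[i]), 0)
  sb <- vapply(idx, function(i) sum(comp$b[i]), 0)
  sc <- vapply(idx, function(i) sum(comp$c[i]), 0)
  ns <- vapply(idx, function(i) sum(comp$usable[i]), 0L)
  denom <- sa + sb + sc
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             n_sites = ns, fst = ifelse(denom != 0, sa / denom, NaN),
             sum_a = sa, sum_b = sb, sum_c = sc)
}

#' Genome-wide Weir-Cockerham Fst
#'
#' Ratio-of-sums Weir-Cockerham Fst over all usable sites.
#'
#' @inheritParams wc_fst_window
#' @return a single numeric value (NaN if no usable site).
#' @export
wc_fst_global <- function(g, pops) {
  comp <- wc_site_components(g, pops)
  denom <- sum(comp$a + comp$b + comp$c)
  if (denom == 0) NaN else sum(comp$a) / denom
}

# --- pairwise Fst matrices --------------------------------------------------

#' Pairwise Fst matrix over populations
#'
#' Genome-wide Weir-Cockerham Fst for every unordered pair of populations.
#' The default (`method = "genome"`) is the ratio-of-sums over all retained
#' sites; `method = "window_mean"` averages per-window ratio-of-sums values
#' over the supplied windows instead.
#'
#' @inheritParams wc_fst_window
#' @param method `"genome"` or `"window_mean"`.
#' @param windows required when `method = "window_mean"`.
#' @return an `fst_matrix`: a symmetric numeric matrix with population
#'   labels as dimnames and `NA` on the diagonal.
#' @export
pairwise_fst_matrix <- function(g, pops, method = c("genome", "window_mean"),
                                windows = NULL) {
  method <- match.arg(method)
  cols <- .pop_columns(g, pops, min_n = 2)
  labs <- names(cols)
  if (length(labs) < 2) stop("need >= 2 populations with >= 2 samples")
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  for (i in seq_along(labs)[-1]) for (j in seq_len(i - 1)) {
    sub <- pops[pops$population %in% labs[c(i, j)], ]
    v <- if (method == "genome") {
      wc_fst_global(g, sub)
    } else {
      if (is.null(windows)) stop("windows required for window_mean")
      w <- wc_fst_window(g, sub, windows)
      mean(w$fst[w$n_sites > 0], na.rm = TRUE)
    }
    m[i, j] <- m[j, i] <- v
  }
  fst_matrix(m)
}

#' Construct / read / write a pairwise-Fst matrix
#'
#' An `fst_matrix` is a symmetric numeric matrix of pairwise Fst values over
#' named populations, with an ignored diagonal.  On disk it is a labelled
#' square tab-separated table.
#'
#' @param values square numeric matrix with matching dimnames.
#' @return an object of class `fst_matrix`.
#' @export
fst_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("fst matrix must be square")
  if (is.null(rownames(values)) || !identical(rownames(values), colnames(values)))
    stop("fst matrix needs matching row/column labels")
  diag(values) <- NA_real_
  if (!isTRUE(all.equal(values, t(values)))) stop("fst matrix must be symmetric")
  off <- values[upper.tri(values)]
  if (any(off > 1, na.rm = TRUE)) stop("Fst values must be <= 1")
  structure(values, class = c("fst_matrix", "matrix"))
}

#' @rdname fst_matrix
#' @param path file path.
#' @export
read_fst_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  fst_matrix(m)
}

#' @rdname fst_matrix
#' @param m an `fst_matrix`.
#' @export
write_fst_matrix <- function(m, path) {
  utils::write.table(cbind(population = rownames(m), as.data.frame(unclass(m))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise pairs of a pairwise-Fst matrix
#'
#' Mean, minimum and maximum over a chosen set of unordered population pairs:
#' all `C(k, 2)` pairs by default, or — with `focal` — only pairs containing a
#' focal population (optionally restricted to a set of partner populations).
#' Means are exact unweighted arithmetic means.
#'
#' @param m an `fst_matrix`.
#' @param focal optional label (or labels) all selected pairs must touch.
#' @param partners optional labels the other end of each pair must lie in.
#' @return list: `mean`, `min`, `max`, `n_pairs`, `values`.
#' @export
fst_matrix_summary <- function(m, focal = NULL, partners = NULL) {
  labs <- rownames(m)
  chk <- function(x) {
    bad <- setdiff(x, labs)
    if (length(bad))
      stop("unknown population(s) ", paste(bad, collapse = ", "),
           "; known: ", paste(labs, collapse = ", "))
  }
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  if (!is.null(focal)) {
    chk(focal)
    touch <- labs[pairs[, 1]] %in% focal | labs[pairs[, 2]] %in% focal
    pairs <- pairs[touch, , drop = FALSE]
    if (!is.null(partners)) {
      chk(partners)
      other <- ifelse(labs[pairs[, 1]] %in% focal,
                      labs[pairs[, 2]], labs[pairs[, 1]])
      pairs <- pairs[other %in% partners, , drop = FALSE]
    }
  }
  if (nrow(pairs) == 0) stop("no pairs selected")
  v <- m[pairs]
  list(mean = mean(v), min = min(v), max = max(v),
       n_pairs = length(v), values = v)
}
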