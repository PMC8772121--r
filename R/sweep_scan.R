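#' Joint Fst / diversity-ratio sweep statistics
#'
#' Computes, in sliding windows (default 20 kb with 10 kb step), the
#' Weir-Cockerham Fst between a candidate and a reference cohort together
#' with the nucleotide diversity of each cohort, then derives the two
#' selection statistics: the Z-transformed Fst and the log2 theta-pi ratio
#' `log2(pi_reference / pi_candidate)`, oriented so that diversity depletion
#' in the candidate cohort gives a large positive value.
#'
#' Windows are rankable (enter the Z-transform and the selection quantiles)
#' only if they hold at least `min_sites` usable SNPs and both cohort
#' diversities are positive; the number excluded is attached as attribute
#' `n_excluded`.
#'
#' @param g a `genotype_matrix`.
#' @param candidate,reference disjoint sample-identifier sets, each >= 2.
#' @param size,step window size and step in bp.
#' @param min_sites minimum usable SNPs for a window to be ranked.
#' @param chrom_lengths optional named lengths; defaults to the maximum
#'   observed position per chromosome.
#' @param invert_ratio use `log2(pi_candidate / pi_reference)` instead.
#' @return data.frame of `sweep_window` rows: chrom, start, end, n_sites,
#'   fst, z_fst, pi_candidate, pi_reference, log2_ratio, rankable.
#' @export
compute_sweep_stats <- function(g, candidate, reference,
                                size = 20000, step = 10000,
                                min_sites = 10, chrom_lengths = NULL,
                                invert_ratio = FALSE) {
  if (length(intersect(candidate, reference)) > 0)
    stop("candidate and reference cohorts must be disjoint")
  if (length(candidate) < 2 || length(reference) < 2)
    stop("each cohort needs >= 2 samples")
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(g$sites$pos, g$sites$chrom, max)[
      unique(g$sites$chrom)]
  windows <- make_windows(chrom_lengths, size, step)
  pops <- population_map(c(candidate, reference),
                         rep(c("candidate", "reference"),
                             c(length(candidate), length(reference))))
  fst <- wc_fst_window(g, pops, windows)
  pic <- window_pi(g, windows, samples = candidate)
  pir <- window_pi(g, windows, samples = reference)
  lr <- ifelse(pic$pi > 0 & pir$pi > 0,
               log2(pir$pi / pic$pi), NaN)
  if (invert_ratio) lr <- -lr
  rankable <- fst$n_sites >= min_sites & pic$pi > 0 & pir$pi > 0 &
    is.finite(fst$fst)
  z <- rep(NaN, nrow(windows))
  if (sum(rankable) >= 2 && stats::sd(fst$fst[rankable]) > 0)
    z[rankable] <- z_transform(fst$fst[rankable])
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, n_sites = fst$n_sites,
                    fst = fst$fst, z_fst = z,
                    pi_candidate = pic$pi, pi_reference = pir$pi,
                    log2_ratio = lr, rankable = rankable)
  attr(out, "n_excluded") <- sum(!rankable)
  out
}

#' Z-transform a numeric vector
#'
#' Standardisation to zero mean and unit sample standard deviation
#' (denominator `n - 1`).
#'
#' @param values numeric vector of finite values, length >= 2, nonzero spread.
#' @return numeric vector of Z-scores.
#' @export
z_transform <- function(values) {
  if (length(values) < 2 || any(!is.finite(values)))
    stop("need >= 2 finite values")
  s <- stats::sd(values)
  if (s == 0) stop("zero spread: Z-transform undefined")
  (values - mean(values)) / s
}

# empirical quantile, "higher" convention: an observed order statistic at or
# above the nominal position, so selecting x >= q keeps ceiling(q * n) values
# up to ties
.quantile_higher <- function(x, prob) {
  xs <- sort(x)
  n <- length(xs)
  xs[min(n, ceiling((n - 1) * prob + 1))]
}

#' Select top-quantile outlier windows on both statistics
#'
#' The sweep selection rule: a window is selected when its Z(Fst) and its
#' log2 theta-pi ratio both lie in the top `q` empirical tail (default top
#' 5%).  Thresholds are marginal empirical quantiles over rankable windows
#' computed with the "higher" convention (the threshold is an observed value;
#' ties at the threshold are included).  With `two_tailed_pi = TRUE` the
#' diversity-ratio criterion keeps each tail at level `q`.
#'
#' @param wins data.frame from [compute_sweep_stats()].
#' @param q upper-tail mass per statistic (default 0.05).
#' @param two_tailed_pi select either theta-pi-ratio tail.
#' @return the selected subset of `wins`, with logical columns
#'   `selected_fst` and `selected_pi`, plus attributes `z_fst_threshold` and
#'   `log2_ratio_threshold`.
#' @export
select_top_intersection <- function(wins, q = 0.05, two_tailed_pi = FALSE) {
  r <- wins[wins$rankable, , drop = FALSE]
  if (nrow(r) < 20) stop("need >= 20 rankable windows")
  if (nrow(r) < 1 / q)
    warning("fewer than 1/q rankable windows; thresholds are coarse")
  tf <- .quantile_higher(r$z_fst, 1 - q)
  tp <- .quantile_higher(r$log2_ratio, 1 - q)
  sel_f <- r$z_fst >= tf
  sel_p <- r$log2_ratio >= tp
  if (two_tailed_pi) {
    lo <- -.quantile_higher(-r$log2_ratio, 1 - q)
    sel_p <- sel_p | r$log2_ratio <= lo
  }
  out <- r[sel_f & sel_p, , drop = FALSE]
  out$selected_fst <- sel_f[sel_f & sel_p]
  out$selected_pi <- sel_p[sel_f & sel_p]
  attr(out, "z_fst_threshold") <- tf
  attr(out, "log2_ratio_threshold") <- tp
  out
}

#' Merge selected windows into sweep regions
#'
#' Same-chromosome selected windows that overlap or lie within `gap` bp of
#' each other are merged into disjoint regions; peak scores are maxima over
#' the merged member windows.
#'
#' @param selected data.frame of selected sweep windows (0-based half-open).
#' @param gap maximum bp between windows still merged (default 0 = abutting).
#' @return data.frame of regions: chrom, start, end, n_windows, peak_z_fst,
#'   peak_log2_ratio.
#' @export
merge_regions <- function(selected, gap = 0) {
  if (nrow(selected) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      peak_z_fst = numeric(), peak_log2_ratio = numeric()))
  gr <- GenomicRanges::GRanges(
    selected$chrom,
    IRanges::IRanges(selected$start + 1L, selected$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_windows = as.integer(table(factor(grp, seq_along(red)))),
    peak_z_fst = as.numeric(tapply(selected$z_fst,
                                   factor(grp, seq_along(red)), max)),
    peak_log2_ratio = as.numeric(tapply(selected$log2_ratio,
                                        factor(grp, seq_along(red)), max)),
    stringsAsFactors = FALSE)
}

#' Annotate sweep regions with overlapping genes
#'
#' A gene is assigned to a region iff their half-open intervals share at
#' least one bp (strand ignored).
#'
#' @param regions data.frame from [merge_regions()].
#' @param genes data.frame from [read_gff_genes()].
#' @return list: `regions` (with a comma-separated `genes` column and
#'   `n_genes`) and `genes` (flat deduplicated sorted gene-id vector).
#' @export
overlap_genes <- function(regions, genes) {
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    regions$genes <- character(nrow(regions))
    regions$n_genes <- integer(nrow(regions))
    return(list(regions = regions, genes = character()))
  }
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  hit <- GenomicRanges::findOverlaps(rg, gg, ignore.strand = TRUE)
  per <- split(genes$gene_id[S4Vectors::subjectHits(hit)],
               factor(S4Vectors::queryHits(hit), seq_len(nrow(regions))))
  regions$genes <- vapply(per, function(x) paste(sort(unique(x)), collapse = ","), "")
  regions$n_genes <- vapply(per, function(x) length(unique(x)), 0L)
  list(regions = regions,
       genes = sort(unique(genes$gene_id[S4Vectors::subjectHits(hit)])))
}

#' Write sweep regions as BED
#'
#' BED is 0-based half-open, matching the internal convention directly.
#'
#' @param regions data.frame from [merge_regions()] / [overlap_genes()].
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, regions$start, regions$end,
                    paste0("sweep_", seq_len(nrow(regions))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
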