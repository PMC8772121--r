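#' Construct a genotype matrix
#'
#' The central container for all population-genetic computations: a set of
#' biallelic SNP sites with per-sample alternate-allele dosages.  Sites are
#' anchored to genomic coordinates; positions are stored 1-based (as in VCF)
#' while all windowing arithmetic in the package is done 0-based half-open.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt` (single-character nucleotide codes).
#' @param samples character vector of sample identifiers.
#' @param dosage integer matrix, `nrow(sites)` x `length(samples)`, each cell
#'   the count of alternate alleles in {0, 1, 2} or `NA` for missing.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sites`, `samples`, `dosage`.
#' @export
genotype_matrix <- function(sites, samples, dosage) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(sites) || ncol(dosage) != length(samples))
    stop("dosage dimensions must be n_sites x n_samples")
  if (nrow(sites) > 0) {
    if (any(sites$pos < 1)) stop("positions must be >= 1")
    bad <- which(as.character(sites$ref) == as.character(sites$alt))
    if (length(bad))
      stop("ref and alt alleles identical at site ", bad[1])
    ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
    if (!all(ok)) stop("dosage values must be 0, 1, 2 or NA")
    key <- paste(sites$chrom, sites$pos)
    if (anyDuplicated(key))
      stop("duplicate (chrom, pos): ", key[duplicated(key)][1])
    .check_sorted(sites$chrom, sites$pos)
  }
  rownames(dosage) <- NULL
  colnames(dosage) <- samples
  structure(list(sites = sites, samples = as.character(samples),
                 dosage = dosage),
            class = "genotype_matrix")
}

# sites must form contiguous chromosome blocks with strictly increasing pos
.check_sorted <- function(chrom, pos) {
  chrom <- as.character(chrom)
  r <- rle(chrom)
  if (anyDuplicated(r$values)) {
    d <- r$values[duplicated(r$values)][1]
    stop("records for chromosome ", d, " are not contiguous (file unsorted)")
  }
  same <- chrom[-1] == chrom[-length(chrom)]
  bad <- which(same & diff(pos) <= 0)
  if (length(bad))
    stop("unsorted positions: ", chrom[bad[1] + 1], ":", pos[bad[1] + 1],
         " follows position ", pos[bad[1]])
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x", length(x$samples),
      "samples;", sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_sites <- function(g) nrow(g$sites)

#' @rdname n_sites
#' @export
n_samples <- function(g) length(g$samples)

#' Subset a genotype matrix by site and/or sample
#'
#' @param g a `genotype_matrix`.
#' @param sites integer or logical index over sites.
#' @param samples integer, logical or character index over samples.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(g, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(g))
  if (is.null(samples)) samples <- seq_along(g$samples)
  if (is.character(samples)) {
    idx <- match(samples, g$samples)
    if (anyNA(idx)) stop("unknown sample(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    samples <- idx
  }
  genotype_matrix(g$sites[sites, , drop = FALSE],
                  g$samples[samples],
                  g$dosage[sites, samples, drop = FALSE])
}

#' Read a population map
#'
#' A population map assigns each sample to a population label.  On disk it is
#' two-column tab-separated text (sample, population) without a header.
#'
#' @param path path to the tab-separated file.
#' @return data.frame with columns `sample`, `population`.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("cannot read population map: ", path)
  m <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("sample", "population"),
                         colClasses = "character")
  population_map(m$sample, m$population)
}

#' @rdname read_population_map
#' @param sample,population character vectors of equal length.
#' @export
population_map <- function(sample, population) {
  if (length(sample) != length(population))
    stop("sample and population must have equal length")
  if (any(!nzchar(population))) stop("population labels must be non-empty")
  if (anyDuplicated(sample))
    stop("duplicate sample in population map: ",
         sample[duplicated(sample)][1])
  data.frame(sample = as.character(sample),
             population = as.character(population),
             stringsAsFactors = FALSE)
}

#' @rdname read_population_map
#' @param map a population map data.frame.
#' @param path output path.
#' @export
write_population_map <- function(map, path) {
  utils::write.table(map[, c("sample", "population")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# named list of sample-column indices per population, restricted to samples
# present in g; populations with fewer than min_n samples are dropped with a
# warning when warn = TRUE
.pop_columns <- function(g, pops, min_n = 2, warn = TRUE) {
  idx <- match(pops$sample, g$samples)
  keep <- !is.na(idx)
  sp <- split(idx[keep], pops$population[keep])
  small <- vapply(sp, length, 0L) < min_n
  if (any(small)) {
    if (warn)
      warning("excluding population(s) with < ", min_n, " samples: ",
              paste(names(sp)[small], collapse = ", "))
    sp <- sp[!small]
  }
  sp
}
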