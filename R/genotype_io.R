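#' Read diploid genotypes from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a [genotype_matrix()].  Diploid
#' GT fields are converted to alternate-allele dosage; half-called genotypes
#' (one allele missing, e.g. `./1`) are treated as fully missing so that every
#' cell is a whole-individual dosage.
#'
#' @param path path to an (optionally gzipped) VCF file.
#' @param biallelic_only drop multi-allelic and non-SNP records (default TRUE).
#' @return a `genotype_matrix`.  The number of records dropped by the
#'   biallelic/SNP filter is attached as attribute `n_dropped`.
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0)
    return(genotype_matrix(
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      colnames(vcf@gt)[-1], matrix(integer(), 0, ncol(vcf@gt) - 1)))
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, TRUE)))
    stop("VCF format error: records without a GT field")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  .check_sorted(chrom, pos)

  keep <- rep(TRUE, length(pos))
  if (biallelic_only)
    keep <- nchar(ref) == 1L & grepl("^[ACGTacgt]$", ref) &
      nchar(alt) == 1L & grepl("^[ACGTacgt]$", alt)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(pos))
  dosage <- .gt_to_dosage(gt[keep, , drop = FALSE])
  g <- genotype_matrix(
    data.frame(chrom = chrom[keep], pos = pos[keep],
               ref = ref[keep], alt = alt[keep],
               stringsAsFactors = FALSE),
    colnames(vcf@gt)[-1], dosage)
  attr(g, "n_dropped") <- sum(!keep)
  g
}

# "0/0"->0, "0/1"/"1|0"->1, "1/1"->2; anything containing "." -> NA
.gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt))
  a <- sub("[/|].*", "", gt)
  b <- sub(".*[/|]", "", gt)
  ok <- !is.na(gt) & a %in% c("0", "1") & b %in% c("0", "1")
  d[ok] <- as.integer(a[ok]) + as.integer(b[ok])
  d
}

#' Write a genotype matrix as minimal VCF
#'
#' Emits an uncompressed sites-by-samples VCF with GT as the only FORMAT
#' field.  `read_vcf(write_vcf(g, f))` reproduces dosages and coordinates
#' exactly.
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=apiscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  if (n_sites(g) > 0) {
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", n_sites(g), n_samples(g))
    ok <- !is.na(g$dosage)
    gt[ok] <- code[g$dosage[ok] + 1L]
    lines <- paste(g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt,
                   ".", "PASS", ".", "GT", sep = "\t")
    lines <- paste(lines, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Filter sites on missingness and minor allele frequency
#'
#' Retains sites whose missing-call fraction is strictly below `max_missing`
#' and whose minor allele frequency, computed over non-missing alleles across
#' all samples, is strictly above `min_maf`.  These are the standard
#' post-calling SNP quality filters (defaults: missing ratio < 10%,
#' MAF > 1%).  Idempotent; site order preserved.
#'
#' @param g a `genotype_matrix`.
#' @param max_missing maximum tolerated missing fraction (exclusive).
#' @param min_maf minimum minor allele frequency (exclusive).
#' @return the filtered `genotype_matrix` (empty, with a warning, if no site
#'   survives).
#' @export
filter_variants <- function(g, max_missing = 0.10, min_maf = 0.01) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  if (n_sites(g) == 0) return(g)
  nmiss <- rowSums(is.na(g$dosage))
  nonmiss <- n_samples(g) - nmiss
  alt <- rowSums(g$dosage, na.rm = TRUE)
  p <- ifelse(nonmiss > 0, alt / (2 * nonmiss), NA_real_)
  maf <- pmin(p, 1 - p)
  keep <- (nmiss / n_samples(g)) < max_missing & !is.na(maf) & maf > min_maf
  if (!any(keep)) warning("all sites removed by filter_variants")
  subset_genotypes(g, sites = which(keep))
}

#' Sliding genomic windows
#'
#' Builds the sliding-window grid shared by all windowed statistics:
#' per chromosome, windows start at 0 and advance by `step`; the final window
#' is truncated at the chromosome end, and a window is emitted only if its
#' start lies within the chromosome.  Coordinates are 0-based half-open.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp.
#' @param step step between window starts in bp; must satisfy
#'   `size >= step >= 1`.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, size, step = size) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (step < 1 || step > size)
    stop("window configuration error: need size >= step >= 1")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read gene records from a GFF3 file
#'
#' Imports a GFF3 annotation (via \pkg{rtracklayer}) and returns its `gene`
#' features converted to the package's 0-based half-open convention.  Lines
#' are pre-validated so malformed input is reported with its line number.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `strand`, `gene_id`.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("cannot read GFF3: ", path)
  lines <- readLines(path)
  fasta <- grep("^##FASTA", lines)
  if (length(fasta)) lines <- lines[seq_len(fasta[1] - 1)]
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8))
    stop("malformed GFF3 line ", which(body)[nf < 8][1],
         ": fewer than 8 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  if (length(gr) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character()))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
  ids[is.na(ids)] <- paste0("gene_", which(is.na(ids)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = ids,
             stringsAsFactors = FALSE)
}
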