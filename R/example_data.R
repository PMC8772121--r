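#' Reference pairwise-Fst tables for A. cerana cohorts
#'
#' Two published genome-wide pairwise Weir-Cockerham Fst tables for Chinese
#' *Apis cerana* cohorts, shipped as plain-text fixtures and used in examples
#' and regression tests of [fst_matrix_summary()]:
#'
#' * `"five_regions"` — five geographic regions (Changbai Mountain, North,
#'   Northwest, Qinghai-Tibet, South; 10 pairs).
#' * `"changbai_sites"` — six sampling areas around Changbai Mountain
#'   (four Jilin sites, Heilongjiang, Liaoning; 15 pairs, including small
#'   negative ratio-of-sums values).
#'
#' @param which `"five_regions"` or `"changbai_sites"`.
#' @return an `fst_matrix`.
#' @examples
#' m <- reference_fst_matrix("five_regions")
#' fst_matrix_summary(m)$mean
#' @export
reference_fst_matrix <- function(which = c("five_regions", "changbai_sites")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("fst_", if (which == "five_regions")
                     "five_regions" else "changbai_sites", ".tsv"),
                   package = "apiscan", mustWork = TRUE)
  read_fst_matrix(f)
}
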