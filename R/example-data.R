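#' Worked-example data files
#'
#' Paths to small plain-text tables shipped with the package, taken from a
#' published CMAP screen of a diabetic-nephropathy glomerular signature
#' (late-stage vs early-stage disease). They serve as worked examples and
#' fixtures for the scoring arithmetic:
#'
#' * `dn_ks_top20.tsv` — the top 20 instances of the KS connectivity
#'   screen, with the printed connectivity (`score`), `up` and `down` tag
#'   scores per instance.
#' * `dn_matching_top20.tsv` — the top 20 instances of the reversing-score
#'   screen, with reversed/aggravated gene counts.
#' * `dn_reversed_genes.tsv` — long table (`drug`, `direction`, `gene`) of
#'   the disease DEGs reversed by the four consensus drugs; `decrease`
#'   rows are disease-up genes the drug pushes down, `increase` rows
#'   disease-down genes it pushes up.
#'
#' @param file File name (default: list the available files).
#' @return Full path to the file, or a vector of available file names.
#' @examples
#' sigreverse_example()
#' readr::read_tsv(sigreverse_example("dn_ks_top20.tsv"), show_col_types = FALSE)
#' @export
sigreverse_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "sigreverse")))
  }
  path <- system.file("extdata", file, package = "sigreverse")
  if (!nzchar(path)) abort(paste0("no example file '", file, "'."))
  path
}
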