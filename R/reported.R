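#' Published per-timepoint spot counts (EAM Visium study)
#'
#' The per-condition spot counts printed in the source study for
#' fibroblast-dominant and immune-rich spot sets at day 0 (healthy) and
#' day 19 (acute inflammation), shipped as a small CSV. Summing each
#' category across conditions with [condition_totals()] reproduces the
#' published totals (657 fibroblast-dominant, 1032 immune-rich spots) —
#' an arithmetic-consistency check, since the underlying dataset is not
#' bundled.
#'
#' @return data.frame with columns category, condition, n_spots
#' @export
reported_spot_counts <- function() {
  path <- system.file("extdata", "reported_spot_counts.csv",
                      package = "spotcoloc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Per-category totals across conditions
#'
#' @param counts data.frame with columns category, condition, n_spots
#'   (default: [reported_spot_counts()])
#' @return named integer vector of totals per category
#' @export
condition_totals <- function(counts = reported_spot_counts()) {
  tapply(counts$n_spots, counts$category, sum)
}
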