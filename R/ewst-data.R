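#' Published per-marker genotype-class counts (European Wadden Sea survey)
#'
#' The per-locus allele-set classes of the 79-sample SSR survey (7 hybrid,
#' 72 allopolyploid) with their carrier counts per cytotype, as printed in
#' the population-survey frequency table. These counts are the input for
#' reproducing the published per-marker frequencies.
#'
#' @return data.frame with columns \code{locus}, \code{genotype}
#'   (slash-separated binned allele sizes), \code{n_hybrid},
#'   \code{n_allopolyploid}.
#' @export
ewst_locus_classes <- function() {
  utils::read.csv(system.file("extdata", "ewst_locus_classes.csv",
                              package = "traitscape", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Synthetic SSR population carrying the published per-marker counts
#'
#' Reconstructs a 79-sample SSR table whose per-locus class counts match
#' [ewst_locus_classes()] exactly: within each cytotype stratum the
#' classes of each locus are assigned to samples in fixed order. Because
#' the published table reports loci marginally, the multilocus
#' combinations of this reconstruction are synthetic -- per-locus
#' frequencies are exact, multilocus genotype combinations are not.
#'
#' @return SSR table (data.frame) with 7 hybrid and 72 allopolyploid
#'   samples.
#' @export
ewst_population <- function() {
  cls <- ewst_locus_classes()
  n_h <- 7L; n_a <- 72L
  out <- data.frame(
    sample_id = sprintf("EWST%02d", seq_len(n_h + n_a)),
    cytotype = c(rep("hybrid", n_h), rep("allopolyploid", n_a)),
    origin = NA_character_, stringsAsFactors = FALSE)
  for (lc in unique(cls$locus)) {
    rows <- cls[cls$locus == lc, , drop = FALSE]
    if (sum(rows$n_hybrid) != n_h || sum(rows$n_allopolyploid) != n_a)
      stop("class counts at ", lc, " do not sum to the stratum sizes")
    out[[lc]] <- c(rep(rows$genotype, rows$n_hybrid),
                   rep(rows$genotype, rows$n_allopolyploid))
  }
  out
}
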