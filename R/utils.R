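#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for reported percentages, where
#' \code{base::round()}'s round-half-to-even rule would disagree at exact
#' .5 boundaries (e.g. 12.45 -> 12.5, not 12.4).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Truncated-normal draws for non-negative traits
#'
#' Samples N(mean, sd) conditioned on being >= 0 by rejection; with the
#' trait means used here the truncation mass is negligible but guarantees
#' biologically valid values. sd = 0 returns the mean exactly.
#'
#' @param n number of draws.
#' @param mean,sd distribution parameters, sd >= 0.
#' @return numeric vector of length n, all >= 0.
#' @keywords internal
rtrunc0 <- function(n, mean, sd) {
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

# Serialize an integer allele set as Table-1 style "223/250/258/261"
format_alleles <- function(sizes) {
  if (!length(sizes)) return("")
  paste(sort(unique(sizes)), collapse = "/")
}

# Parse "223/250/258/261" (empty string = failed amplification)
parse_alleles <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  sort(unique(as.numeric(strsplit(s, "/", fixed = TRUE)[[1]])))
}

# Locus columns of an SSR table = everything that is not metadata
ssr_locus_columns <- function(samples) {
  setdiff(names(samples), c("sample_id", "cytotype", "origin"))
}

# All allele sets of one locus column as a list of numeric vectors
ssr_allele_sets <- function(samples, locus) {
  lapply(samples[[locus]], parse_alleles)
}
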