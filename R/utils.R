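#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the DNA alphabet. RNA input (U) is
#' converted to DNA first; all package-internal sequence comparisons are done
#' in DNA space.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' dna_revcomp("ACGT")
dna_revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", dna_upper(x)))
}

#' @keywords internal
dna_upper <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' @keywords internal
check_dna <- function(x, what = "sequence") {
  x <- dna_upper(x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,U/T}: e.g. '%s'",
      what, x[which(bad)[1]]
    ))
  }
  x
}

#' @keywords internal
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Run code under a fixed seed without touching the global RNG state,
# unless seed is NULL in which case the current stream is used.
#' @keywords internal
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
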