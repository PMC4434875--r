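#' Construct a canonical miRNA hairpin around a mature sequence
#'
#' Builds a precursor that folds into a perfect stem-loop placing the given
#' mature sequence opposite a miRNA-star with the 2-nt 3' overhangs typical
#' of RNase III (Dicer-like) products on both duplex strands. The 5p arm is
#' `arm_padding` random bases, the mature, then `arm_padding` random bases;
#' the 3p arm is its exact reverse complement; the loop is drawn from {A, C}
#' only so it cannot pair internally. All coordinates are 1-based inclusive
#' precursor positions.
#'
#' On the perfect stem of length `n`, position `i` pairs with `n + 1 - i`.
#' The star span is derived from the duplex geometry: its 5' end faces
#' `mature_end - 2` and its 3' end extends two bases past the partner of
#' `mature_start`, which yields 2-nt 3' overhangs on both strands.
#'
#' @param mature mature miRNA sequence, 20-22 nt, DNA or RNA alphabet.
#' @param loop_length hairpin loop length (>= 3).
#' @param arm_padding random bases added on each side of the mature within
#'   its arm (>= 2, so the star's 2-nt overhang stays inside the precursor).
#' @param arm which arm carries the mature sequence, "5p" or "3p".
#' @param seed optional integer seed; identical inputs and seed give a
#'   byte-identical precursor.
#' @return a list of class `planted_hairpin` with elements `precursor`,
#'   `mature`, `mature_span`, `star`, `star_span`, `arm`, `loop_span`,
#'   `partner` (pairing-partner lookup, 0 = unpaired).
#' @export
#' @examples
#' hp <- build_hairpin("ACGTGACGTGACGTGACGTGA", loop_length = 10, seed = 1)
#' hp$mature_span
#' hp$star_span
build_hairpin <- function(mature, loop_length = 10, arm_padding = 2,
                          arm = c("5p", "3p"), seed = NULL) {
  arm <- match.arg(arm)
  mature <- check_dna(mature, "mature")
  L <- nchar(mature)
  if (L < 20 || L > 22) {
    abort(sprintf("mature must be 20-22 nt (got %d)", L))
  }
  if (loop_length < 3) abort("loop_length must be >= 3")
  if (arm_padding < 2) abort("arm_padding must be >= 2")

  with_seed_if(seed, {
    pad5 <- rand_dna(arm_padding)
    pad3 <- rand_dna(arm_padding)
    loop <- rand_dna(loop_length, alphabet = c("A", "C"))
    if (arm == "5p") {
      arm5 <- paste0(pad5, mature, pad3)
      arm3 <- dna_revcomp(arm5)
    } else {
      arm3 <- paste0(pad5, mature, pad3)
      arm5 <- dna_revcomp(arm3)
    }
    precursor <- paste0(arm5, loop, arm3)
  })

  A <- as.integer(arm_padding * 2 + L)
  n <- as.integer(2 * A + loop_length)
  partner <- integer(n)
  partner[seq_len(A)] <- n + 1L - seq_len(A)
  partner[(n - A + 1L):n] <- n + 1L - ((n - A + 1L):n)

  if (arm == "5p") {
    ms <- as.integer(arm_padding + 1)
  } else {
    ms <- as.integer(A + loop_length + arm_padding + 1)
  }
  me <- ms + L - 1L
  star_span <- sort(c(partner[me - 2L], partner[ms] + 2L))
  star <- substr(precursor, star_span[1], star_span[2])

  structure(
    list(
      precursor = precursor,
      mature = mature,
      mature_span = c(ms, me),
      star = star,
      star_span = star_span,
      arm = arm,
      loop_span = c(A + 1, A + loop_length),
      partner = partner
    ),
    class = "planted_hairpin"
  )
}

#' @export
print.planted_hairpin <- function(x, ...) {
  cat(sprintf("<planted_hairpin> %d nt, mature (%s) %d-%d, star %d-%d\n",
              nchar(x$precursor), x$arm, x$mature_span[1], x$mature_span[2],
              x$star_span[1], x$star_span[2]))
  invisible(x)
}
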