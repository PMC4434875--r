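#' Fold a precursor by weighted base-pair maximization
#'
#' Computes the nested (pseudoknot-free) base-pair set maximizing total pair
#' weight with G:C = 3, A:U = 2 and G:U = 1, subject to a minimum hairpin
#' loop of `min_loop` unpaired bases. The dynamic program is exact and the
#' traceback is deterministic (among co-optimal structures, the pair with the
#' smallest 5' index is taken first), so identical input always yields the
#' identical structure.
#'
#' The hairpin anatomy is derived from the main stem: starting at the
#' outermost pair (of the exterior helix whose nested chain carries the most
#' pairs), pairs are followed inward - at a branch the better-populated
#' branch is taken (ties to the smaller 5' index) - down to the innermost
#' pair. The 5p arm runs from the outermost to the innermost 5' index, the
#' loop is the span they enclose and the 3p arm mirrors it. A structure
#' whose main stem has fewer than `min_stem` pairs is not hairpin-like.
#'
#' @param precursor sequence (DNA or RNA alphabet, length >= 1; locus
#'   analysis uses >= 40 nt windows).
#' @param min_loop minimum hairpin loop length (default 3).
#' @param min_stem minimum pairs in the main stem for the structure to count
#'   as hairpin-like (default 15).
#' @return an object of class `hairpin_model`: list with `sequence`,
#'   `partner` (1-based pairing partner, 0 = unpaired), `score`,
#'   `dot_bracket`, `stem_pairs`, `hairpin` (logical), `arm5`, `arm3`,
#'   `loop` (1-based inclusive spans, NULL when no pair exists).
#' @export
#' @examples
#' fold_hairpin("GGGAAACCC")$dot_bracket
fold_hairpin <- function(precursor, min_loop = 3, min_stem = 15) {
  seq <- check_dna(precursor, "precursor")
  n <- nchar(seq)
  res <- .fold_bpmax(seq, as.integer(min_loop))
  partner <- res$partner
  db <- rep(".", n)
  db[partner > seq_len(n)] <- "("
  db[partner > 0 & partner < seq_len(n)] <- ")"

  anatomy <- stem_anatomy(partner)
  structure(
    list(
      sequence = seq,
      partner = partner,
      score = res$score,
      dot_bracket = paste(db, collapse = ""),
      stem_pairs = anatomy$stem_pairs,
      hairpin = anatomy$stem_pairs >= min_stem,
      arm5 = anatomy$arm5,
      arm3 = anatomy$arm3,
      loop = anatomy$loop
    ),
    class = "hairpin_model"
  )
}

#' @export
print.hairpin_model <- function(x, ...) {
  cat(sprintf("<hairpin_model> %d nt, score %d, %d stem pairs (%s)\n",
              nchar(x$sequence), x$score, x$stem_pairs,
              if (x$hairpin) "hairpin-like" else "not hairpin-like"))
  cat(" ", x$sequence, "\n ", x$dot_bracket, "\n")
  invisible(x)
}

# walk the main stem of a partner vector; returns arms, loop, pair count
#' @keywords internal
stem_anatomy <- function(partner) {
  n <- length(partner)
  none <- list(stem_pairs = 0L, arm5 = NULL, arm3 = NULL, loop = NULL)
  opens <- which(partner > seq_len(n))
  if (length(opens) == 0) return(none)

  # children pairs directly inside (i, j)
  children <- function(i, j) {
    out <- list()
    k <- i + 1L
    while (k < j) {
      if (partner[k] > k) {
        out[[length(out) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else k <- k + 1L
    }
    out
  }
  count_pairs <- function(i, j) {
    ch <- children(i, j)
    1L + sum(vapply(ch, function(p) count_pairs(p[1], p[2]), integer(1)))
  }
  # exterior helices
  ext <- children(0L, n + 1L)
  sizes <- vapply(ext, function(p) count_pairs(p[1], p[2]), integer(1))
  top <- ext[[which.max(sizes)]]

  i0 <- top[1]; j0 <- top[2]
  i <- i0; j <- j0; stem <- 1L
  repeat {
    ch <- children(i, j)
    if (length(ch) == 0) break
    sz <- vapply(ch, function(p) count_pairs(p[1], p[2]), integer(1))
    best <- ch[[which.max(sz)]]
    i <- best[1]; j <- best[2]
    stem <- stem + 1L
  }
  list(
    stem_pairs = stem,
    arm5 = c(i0, i),
    arm3 = c(j, j0),
    loop = c(i + 1L, j - 1L)
  )
}
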