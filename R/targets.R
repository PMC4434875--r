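#' Score a miRNA against a target site
#'
#' Classic plant miRNA target penalty scheme, applied position by position
#' from the miRNA 5' end against the site read 5' to 3' on the transcript
#' (antiparallel pairing: miRNA position i faces site position L - i + 1).
#' A Watson-Crick pair costs 0, a G:U wobble 0.5, a mismatch 1; penalties
#' are doubled at miRNA positions 2-13 (the seed and central region). A
#' score of 0 means perfect complementarity. Ungapped mode only: the site
#' must have the miRNA's length.
#'
#' @param mirna miRNA sequence (DNA or RNA alphabet).
#' @param site target site sequence, same length, transcript orientation.
#' @return list: `score`, `alignment` (one symbol per miRNA position:
#'   `|` pair, `o` wobble, `.` mismatch).
#' @export
#' @examples
#' score_duplex("ACGTACGTACGTACGTACGTA", dna_revcomp("ACGTACGTACGTACGTACGTA"))
score_duplex <- function(mirna, site) {
  mirna <- check_dna(mirna, "mirna")
  site <- check_dna(site, "site")
  L <- nchar(mirna)
  if (nchar(site) != L) abort("site length must equal miRNA length (ungapped mode)")
  mb <- strsplit(mirna, "")[[1]]
  sb <- rev(strsplit(site, "")[[1]])  # antiparallel
  pm <- .target_penalty_matrix()
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  pen <- pm[cbind(code[mb], code[sb])]
  mult <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  score <- sum(pen * mult)
  sym <- ifelse(pen == 0, "|", ifelse(pen == 0.5, "o", "."))
  list(score = score, alignment = paste(sym, collapse = ""))
}

#' Scan transcripts for miRNA target sites
#'
#' Scores every window of miRNA length in every transcript with the
#' [score_duplex()] scheme; windows scoring at most `compute_cutoff` are
#' kept internally and those at most `report_cutoff` are reported
#' (mirroring the practice of computing with a permissive cutoff and
#' reporting the confident set). Hits are sorted per miRNA by score, then
#' transcript id, then position.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param compute_cutoff internal score cutoff (default 4).
#' @param report_cutoff reported score cutoff (default 3).
#' @return tibble of class `target_hits`: `mirna_id`, `transcript_id`,
#'   `site_start` (1-based), `site`, `score`, `alignment`.
#' @export
scan_targets <- function(mirnas, transcripts, compute_cutoff = 4,
                         report_cutoff = 3) {
  if (length(transcripts) == 0) abort("transcripts must be non-empty")
  if (is.null(names(mirnas))) names(mirnas) <- paste0("mir", seq_along(mirnas))
  if (is.null(names(transcripts))) {
    names(transcripts) <- paste0("tx", seq_along(transcripts))
  }
  mirnas <- vapply(mirnas, check_dna, character(1))
  transcripts <- vapply(transcripts, check_dna, character(1))
  pm <- .target_penalty_matrix()
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)

  out <- list()
  for (tx in names(transcripts)) {
    tb <- code[strsplit(transcripts[[tx]], "")[[1]]]
    nT <- length(tb)
    for (mi in names(mirnas)) {
      mseq <- mirnas[[mi]]
      L <- nchar(mseq)
      if (nT < L) next
      mb <- code[strsplit(mseq, "")[[1]]]
      mult <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
      n_win <- nT - L + 1L
      sc <- numeric(n_win)
      # miRNA position i faces site position L - i + 1 within each window
      for (i in seq_len(L)) {
        sc <- sc + pm[mb[i], tb[(L - i + 1):(nT - i + 1)]] * mult[i]
      }
      keep <- which(sc <= compute_cutoff)
      if (length(keep) == 0) next
      out[[length(out) + 1]] <- tibble(
        mirna_id = mi, transcript_id = tx,
        site_start = as.integer(keep),
        site = substr(rep(transcripts[[tx]], length(keep)),
                      keep, keep + L - 1L),
        score = sc[keep]
      )
    }
  }
  hits <- if (length(out)) bind_rows(out) else {
    tibble(mirna_id = character(), transcript_id = character(),
           site_start = integer(), site = character(), score = numeric())
  }
  hits <- hits |>
    filter(.data$score <= report_cutoff) |>
    mutate(alignment = purrr::map2_chr(
      .data$mirna_id, .data$site,
      function(m, s) score_duplex(mirnas[[m]], s)$alignment)) |>
    arrange(.data$mirna_id, .data$score, .data$transcript_id,
            .data$site_start)
  structure(hits, class = c("target_hits", class(tibble())))
}

#' Filter predicted targets by expression anti-correlation
#'
#' For each miRNA:transcript hit, Pearson correlation is computed over the
#' samples shared between the two expression matrices, with both profiles
#' log10(1 + x)-transformed. The two-sided p-value comes from the t
#' transform t = r*sqrt(n - 2)/sqrt(1 - r^2) with n - 2 degrees of
#' freedom. A pair is retained iff r is negative and p below the cutoff;
#' pairs with
#' fewer than 4 shared samples are marked untestable.
#'
#' @param hits tibble from [scan_targets()] (columns `mirna_id`,
#'   `transcript_id`).
#' @param mirna_mat wide tibble `mirna_id` + sample columns (TP5M).
#' @param transcript_mat wide tibble `transcript_id` + sample columns.
#' @param p_cutoff raw p-value cutoff (default 0.05; no multiple-testing
#'   correction, matching the declared selection rule).
#' @return the hits tibble with `r`, `p_value`, `n_shared`, `testable`,
#'   `retained` columns added.
#' @export
correlate_and_filter <- function(hits, mirna_mat, transcript_mat,
                                 p_cutoff = 0.05) {
  shared <- intersect(setdiff(names(mirna_mat), "mirna_id"),
                      setdiff(names(transcript_mat), "transcript_id"))
  n <- length(shared)
  res <- hits |>
    mutate(r = NA_real_, p_value = NA_real_, n_shared = n,
           testable = n >= 4, retained = FALSE)
  if (n < 4) return(res)
  mm <- log10(1 + as.matrix(mirna_mat[, shared, drop = FALSE]))
  rownames(mm) <- mirna_mat$mirna_id
  tm <- log10(1 + as.matrix(transcript_mat[, shared, drop = FALSE]))
  rownames(tm) <- transcript_mat$transcript_id
  for (i in seq_len(nrow(res))) {
    x <- mm[res$mirna_id[i], ]
    y <- tm[res$transcript_id[i], ]
    if (sd(x) == 0 || sd(y) == 0) next
    r <- cor(x, y)
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(tt), df = n - 2)
    res$r[i] <- r
    res$p_value[i] <- p
    res$retained[i] <- r < 0 && p < p_cutoff
  }
  res
}
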