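#' Trim 3' adapters and size-select reads
#'
#' The insert is the read prefix before the leftmost occurrence of the full
#' adapter; when the full adapter is absent, a terminal adapter prefix of at
#' least 7 nt also counts as adapter evidence (the longest matching terminal
#' prefix is removed). Reads without any adapter evidence are discarded, as
#' are inserts shorter than `min_len` or longer than `max_len`.
#'
#' @param reads character vector of raw reads, or a tibble with columns
#'   `read` and `count` (collapsed representation).
#' @param adapter 3' adapter sequence (non-empty).
#' @param min_len,max_len retained insert length range (default 18-34 nt).
#' @return list with `reads` (tibble `read`, `count` of kept inserts) and
#'   `stats` (tibble of input/kept/discard tallies; read counts are conserved:
#'   kept + discarded = input).
#' @export
trim_and_filter <- function(reads, adapter, min_len = 18, max_len = 34) {
  if (!nzchar(adapter)) abort("adapter must be non-empty")
  adapter <- check_dna(adapter, "adapter")
  if (is.character(reads)) {
    reads <- tibble(read = reads) |>
      group_by(.data$read) |> summarise(count = dplyr::n())
  }
  if (nrow(reads) == 0) {
    return(list(
      reads = tibble(read = character(), count = integer()),
      stats = tibble(input = 0L, no_adapter = 0L, too_short = 0L,
                     too_long = 0L, kept = 0L)
    ))
  }
  rd <- dna_upper(reads$read)
  cnt <- as.integer(reads$count)

  pos <- stringr::str_locate(rd, stringr::fixed(adapter))[, "start"]
  # fall back to the longest terminal adapter prefix of >= 7 nt
  kmax <- nchar(adapter) - 1L
  if (kmax >= 7L) {
    for (k in kmax:7L) {
      idx <- is.na(pos) & endsWith(rd, substr(adapter, 1L, k))
      pos[idx] <- nchar(rd[idx]) - k + 1L
    }
  }
  insert_len <- pos - 1L

  no_adapter <- is.na(pos)
  too_short <- !no_adapter & insert_len < min_len
  too_long <- !no_adapter & insert_len > max_len
  keep <- !no_adapter & !too_short & !too_long

  kept <- tibble(read = substr(rd[keep], 1L, insert_len[keep]),
                 count = cnt[keep]) |>
    filter(nchar(.data$read) > 0)
  stats <- tibble(
    input = sum(cnt),
    no_adapter = sum(cnt[no_adapter]),
    too_short = sum(cnt[too_short]),
    too_long = sum(cnt[too_long]),
    kept = sum(cnt[keep])
  )
  list(reads = kept, stats = stats)
}

#' Collapse trimmed reads into a unique-tag table
#'
#' @param reads character vector of trimmed inserts, or a tibble with
#'   columns `read`/`sequence` and `count`.
#' @param library_id optional library label stored on the table.
#' @return a `tag_table`: tibble with columns `sequence`, `count`
#'   (one row per distinct sequence; the counts sum to the number of input
#'   reads), carrying totals as attributes.
#' @export
collapse_tags <- function(reads, library_id = NA_character_) {
  if (is.character(reads)) reads <- tibble(read = reads, count = 1L)
  nm <- if ("sequence" %in% names(reads)) "sequence" else "read"
  tab <- reads |>
    group_by(sequence = dna_upper(.data[[nm]])) |>
    summarise(count = as.integer(sum(.data$count))) |>
    arrange(dplyr::desc(.data$count), .data$sequence)
  new_tag_table(tab, library_id = library_id,
                totals = list(trimmed = sum(tab$count)))
}

#' @keywords internal
new_tag_table <- function(tab, library_id = NA_character_, totals = list()) {
  structure(tab, class = c("tag_table", class(tibble())),
            library_id = library_id, totals = totals)
}

#' @export
glance.tag_table <- function(x, ...) {
  tot <- attr(x, "totals")
  tibble(
    library = attr(x, "library_id") %||% NA_character_,
    distinct_tags = nrow(x),
    reads = sum(x$count),
    genome_matched = tot$genome_matched %||% NA_integer_,
    structural_matched = tot$structural_matched %||% NA_integer_,
    denominator = tot$denominator %||% NA_integer_
  )
}

#' @importFrom rlang %||%
NULL

#' Map tags exactly to a genome and flag structural RNAs
#'
#' Counts, for every tag, the exact full-length matches in the genome on
#' either strand, and flags tags whose sequence occurs as an exact substring
#' (either strand) of any structural reference sequence (rRNA, tRNA, snRNA,
#' snoRNA and similar). Only perfect matches count; unmatched tags stay in
#' the table but are excluded from downstream totals, and structural tags
#' are excluded from the normalization denominator.
#'
#' @param tags a `tag_table` from [collapse_tags()].
#' @param genome named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param structural_set character vector (or `DNAStringSet`) of structural
#'   RNA sequences; may be empty.
#' @return the `tag_table` with columns `hits` (genome match count) and
#'   `structural` (logical) added, and totals updated.
#' @export
map_exact <- function(tags, genome, structural_set = character()) {
  stopifnot(inherits(tags, "tag_table"))
  subject <- as_dss(genome)
  if (length(subject) == 0 || sum(Biostrings::width(subject)) == 0) {
    abort("genome must be non-empty")
  }
  struct <- as_dss(structural_set)

  hits <- integer(nrow(tags))
  structural <- logical(nrow(tags))
  if (nrow(tags) > 0) {
    chrom_seqs <- as.character(subject)
    seqs <- tags$sequence
    seqs_rc <- dna_revcomp(seqs)
    for (chrom in chrom_seqs) {
      hits <- hits +
        stringi::stri_count_fixed(chrom, seqs, overlap = TRUE) +
        stringi::stri_count_fixed(chrom, seqs_rc, overlap = TRUE)
    }
    for (s in as.character(struct)) {
      structural <- structural |
        stringi::stri_detect_fixed(s, seqs) |
        stringi::stri_detect_fixed(s, seqs_rc)
    }
  }
  out <- tags
  out$hits <- hits
  out$structural <- structural
  tot <- attr(tags, "totals")
  tot$genome_matched <- sum(out$count[out$hits > 0])
  tot$structural_matched <- sum(out$count[out$structural])
  tot$denominator <- sum(out$count[out$hits > 0 & !out$structural])
  new_tag_table(out, library_id = attr(tags, "library_id"), totals = tot)
}

#' @keywords internal
as_dss <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  x <- dna_upper(as.character(x))
  x <- x[nzchar(x)]
  Biostrings::DNAStringSet(x)
}

#' Size-class profile and library quality flags
#'
#' Sums normalized abundance (TP5M) per insert length 18-34 nt over
#' genome-matched, non-structural tags, flags whether 21 and 24 nt are local
#' maxima (the bimodal profile expected of angiosperm small-RNA libraries),
#' and applies two quality checks: presence of a 21 or 24 nt local maximum,
#' and a minimum number of distinct genome-matched tags.
#'
#' @param table a mapped `tag_table` (after [map_exact()]); TP5M values are
#'   computed on the fly via [tp5m_normalize()] when absent.
#' @param min_distinct minimum distinct genome-matched tags for a usable
#'   library. The default (1000) is a package choice scaled to the synthetic
#'   libraries; the original criterion is qualitative.
#' @param min_len,max_len profiled length range.
#' @return list with `profile` (tibble: length, abundance, distinct_tags,
#'   peak flag) and `qc` (tibble: library, pass, reasons).
#' @export
size_profile_and_qc <- function(table, min_distinct = 1000,
                                min_len = 18, max_len = 34) {
  stopifnot(inherits(table, "tag_table"))
  if (!all(c("hits", "structural") %in% names(table))) {
    abort("table must be mapped with map_exact() first")
  }
  if (!"tp5m" %in% names(table)) table <- tp5m_normalize(table)
  counted <- dplyr::as_tibble(table) |>
    filter(.data$hits > 0, !.data$structural)
  prof <- tibble(length = min_len:max_len) |>
    left_join(
      counted |>
        group_by(length = nchar(.data$sequence)) |>
        summarise(abundance = sum(.data$tp5m), distinct_tags = dplyr::n()),
      by = "length") |>
    mutate(abundance = dplyr::coalesce(.data$abundance, 0),
           distinct_tags = dplyr::coalesce(.data$distinct_tags, 0L))

  is_peak <- function(len) {
    a <- prof$abundance
    i <- match(len, prof$length)
    lo <- if (i > 1) a[i - 1] else 0
    hi <- if (i < nrow(prof)) a[i + 1] else 0
    a[i] > lo && a[i] > hi
  }
  prof$peak <- prof$length %in% c(21, 24) &
    vapply(prof$length, function(l) l %in% c(21, 24) && is_peak(l), logical(1))

  reasons <- character()
  if (!is_peak(21) && !is_peak(24)) reasons <- c(reasons, "no 21/24 nt peak")
  n_distinct_gm <- nrow(dplyr::as_tibble(table) |> filter(.data$hits > 0))
  if (n_distinct_gm < min_distinct) {
    reasons <- c(reasons, sprintf("low distinct genome-matched tags (%d < %d)",
                                  n_distinct_gm, min_distinct))
  }
  qc <- tibble(
    library = attr(table, "library_id") %||% NA_character_,
    pass = length(reasons) == 0,
    reasons = paste(reasons, collapse = "; ")
  )
  list(profile = prof, qc = qc)
}
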