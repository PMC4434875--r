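#' TP5M normalization of a tag table
#'
#' Transcripts-per-five-million: each tag's raw count is scaled by
#' `5e6 / denominator`, where the denominator is the total count of
#' genome-matched tags minus those matching structural RNAs (and organellar
#' sequences when these are included in the structural set). Tags outside the
#' denominator (unmatched or structural) get `NA` TP5M. Over all counted
#' tags the TP5M values sum to exactly 5,000,000 (up to floating point), and
#' the normalization is scale-equivariant: doubling every raw count leaves
#' TP5M unchanged.
#'
#' @param table a mapped `tag_table` from [map_exact()].
#' @return the `tag_table` with a `tp5m` column; attribute `usable` is FALSE
#'   (with a warning) when the denominator is zero.
#' @export
tp5m_normalize <- function(table) {
  stopifnot(inherits(table, "tag_table"))
  if (!all(c("hits", "structural") %in% names(table))) {
    abort("table must be mapped with map_exact() before normalization")
  }
  counted <- table$hits > 0 & !table$structural
  denom <- sum(table$count[counted])
  out <- table
  if (denom == 0) {
    warn(sprintf("library %s has a zero normalization denominator; marked unusable",
                 attr(table, "library_id")))
    out$tp5m <- NA_real_
    usable <- FALSE
  } else {
    out$tp5m <- ifelse(counted, table$count * 5e6 / denom, NA_real_)
    usable <- TRUE
  }
  tot <- attr(table, "totals")
  tot$denominator <- denom
  out <- new_tag_table(out, library_id = attr(table, "library_id"), totals = tot)
  attr(out, "usable") <- usable
  out
}

#' Assemble a miRNA x library abundance matrix
#'
#' Sums TP5M over the tags assigned to each miRNA identifier (typically the
#' dominant isoform plus end variants within a +/-2 nt window, see
#' [variant_sequences()]). Tags mapped to no identifier are excluded and
#' tallied; a sequence assigned to two identifiers is rejected. Absent
#' identifiers get 0 in a library.
#'
#' @param tables named list of normalized `tag_table`s (one per library).
#' @param id_map tibble with columns `sequence`, `mirna_id`.
#' @return a wide tibble (`mirna_id` + one numeric column per library) of
#'   class `abundance_tbl`; attribute `unmapped` holds the per-library count
#'   of tags that matched no identifier.
#' @export
build_matrix <- function(tables, id_map) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- vapply(tables, function(t) {
      as.character(attr(t, "library_id") %||% NA_character_)
    }, character(1))
  }
  if (anyNA(names(tables)) || anyDuplicated(names(tables))) {
    abort("tables must have unique library identifiers")
  }
  id_map <- id_map |> mutate(sequence = dna_upper(.data$sequence)) |> distinct()
  if (anyDuplicated(id_map$sequence)) {
    abort("id_map assigns some sequence to more than one identifier")
  }
  ids <- unique(id_map$mirna_id)
  long <- purrr::imap(tables, function(tab, lib) {
    dplyr::as_tibble(tab) |>
      filter(!is.na(.data$tp5m)) |>
      inner_join(id_map, by = "sequence") |>
      group_by(.data$mirna_id) |>
      summarise(tp5m = sum(.data$tp5m)) |>
      mutate(library = lib)
  }) |> bind_rows()
  unmapped <- vapply(tables, function(tab) {
    t <- dplyr::as_tibble(tab) |> filter(!is.na(.data$tp5m))
    sum(!t$sequence %in% id_map$sequence)
  }, numeric(1))
  wide <- tidyr::expand_grid(mirna_id = ids, library = names(tables)) |>
    left_join(long, by = c("mirna_id", "library")) |>
    mutate(tp5m = dplyr::coalesce(.data$tp5m, 0)) |>
    tidyr::pivot_wider(names_from = "library", values_from = "tp5m")
  structure(wide, class = c("abundance_tbl", class(tibble())),
            unmapped = unmapped)
}

#' Average replicate libraries into sample-level abundances
#'
#' Per-sample abundance is the arithmetic mean of the TP5M values of its
#' replicate libraries (the mean is invariant to replicate order; a single
#' replicate passes through unchanged).
#'
#' @param mat wide abundance tibble (`mirna_id` + library columns), e.g. from
#'   [build_matrix()].
#' @param design tibble with columns `library`, `sample` (plus any metadata);
#'   every library column of `mat` must appear in `design`.
#' @return wide tibble `mirna_id` + one column per sample.
#' @export
average_replicates <- function(mat, design) {
  libs <- setdiff(names(mat), "mirna_id")
  missing <- setdiff(libs, design$library)
  if (length(missing) > 0) {
    abort(paste0("libraries absent from design: ",
                 paste(missing, collapse = ", ")))
  }
  long <- mat |>
    tidyr::pivot_longer(all_of(libs), names_to = "library",
                        values_to = "tp5m") |>
    left_join(design |> select("library", "sample"), by = "library") |>
    group_by(.data$mirna_id, .data$sample) |>
    summarise(tp5m = mean(.data$tp5m), .groups = "drop")
  samples <- unique(design$sample[design$library %in% libs])
  long |>
    tidyr::pivot_wider(names_from = "sample", values_from = "tp5m") |>
    select("mirna_id", all_of(samples)) |>
    arrange(.data$mirna_id)
}

#' Enumerate isomiR end-variant sequences of a mature span
#'
#' All substrings of the precursor whose start and end are within
#' `shift` nt of the dominant isoform's ends; used to aggregate a locus'
#' abundance at the miRNA level.
#'
#' @param precursor precursor sequence (mature-strand orientation).
#' @param mature_span integer length-2 vector, 1-based inclusive.
#' @param shift maximum end shift (default 2).
#' @return character vector of variant sequences (including the mature).
#' @export
variant_sequences <- function(precursor, mature_span, shift = 2) {
  n <- nchar(precursor)
  starts <- max(1, mature_span[1] - shift):min(n, mature_span[1] + shift)
  ends <- max(1, mature_span[2] - shift):min(n, mature_span[2] + shift)
  grid <- expand.grid(s = starts, e = ends)
  grid <- grid[grid$e > grid$s, ]
  unique(substr(rep(precursor, nrow(grid)), grid$s, grid$e))
}
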