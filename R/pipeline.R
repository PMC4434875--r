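#' Preprocess one library from raw reads to a normalized tag table
#'
#' Convenience chain: [trim_and_filter()] -> [collapse_tags()] ->
#' [map_exact()] -> [tp5m_normalize()].
#'
#' @param reads character vector or tibble (`read`, `count`) of raw reads.
#' @param adapter 3' adapter sequence.
#' @param genome named character vector or `DNAStringSet`.
#' @param structural_set structural RNA sequences (may be empty).
#' @param library_id label stored on the table.
#' @return a normalized `tag_table`; the trimming stats are attached as the
#'   `trim_stats` attribute.
#' @export
preprocess_library <- function(reads, adapter, genome,
                               structural_set = character(),
                               library_id = NA_character_) {
  tr <- trim_and_filter(reads, adapter)
  tab <- collapse_tags(tr$reads, library_id = library_id)
  tab <- map_exact(tab, genome, structural_set)
  tab <- tp5m_normalize(tab)
  attr(tab, "trim_stats") <- tr$stats
  tab
}

#' Preprocess every simulated library
#'
#' @param libs `sim_libraries` from [simulate_libraries()].
#' @param truth `sim_truth` from [plant_genome()].
#' @return named list of normalized `tag_table`s, one per library.
#' @export
preprocess_libraries <- function(libs, truth) {
  purrr::imap(libs$reads, function(tab, lib) {
    preprocess_library(tab, truth$config$adapter_sequence, truth$genome,
                       truth$structural$sequence, library_id = lib)
  })
}

#' Aggregate planted-locus abundances into a miRNA x library matrix
#'
#' Builds the identifier map from each planted locus' mature span (dominant
#' isoform plus end variants within `shift` nt) and assembles the
#' replicate-level abundance matrix.
#'
#' @param tables named list of normalized `tag_table`s.
#' @param loci tibble with `locus_id`, `precursor`, `mature_s_prec`,
#'   `mature_e_prec` (as in `sim_truth$mirna`, or candidate equivalents).
#' @param shift isomiR aggregation window (default 2).
#' @return wide abundance tibble from [build_matrix()].
#' @export
quantify_loci <- function(tables, loci, shift = 2) {
  id_map <- purrr::pmap(
    list(loci$locus_id, loci$precursor, loci$mature_s_prec,
         loci$mature_e_prec),
    function(id, pre, ms, me) {
      tibble(sequence = variant_sequences(pre, c(ms, me), shift),
             mirna_id = id)
    }) |>
    bind_rows() |>
    distinct(.data$sequence, .keep_all = TRUE)
  build_matrix(tables, id_map)
}
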