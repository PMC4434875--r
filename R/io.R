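#' Read small-RNA reads from FASTA or FASTQ
#'
#' FASTQ reads get count 1 each; collapsed FASTA headers of the form
#' `id_count` (count as the last underscore-separated field) carry their
#' count, otherwise count 1.
#'
#' @param path file path; format from extension (`.fq`/`.fastq` vs
#'   `.fa`/`.fasta`).
#' @return tibble with columns `read`, `count`.
#' @export
read_reads <- function(path) {
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  ss <- Biostrings::readDNAStringSet(path, format = if (fastq) "fastq" else "fasta")
  reads <- as.character(ss)
  if (fastq) {
    return(tibble(read = unname(reads), count = 1L) |>
             group_by(.data$read) |>
             summarise(count = as.integer(sum(.data$count))))
  }
  hdr <- names(ss)
  last <- sub(".*_", "", hdr)
  cnt <- suppressWarnings(as.integer(last))
  cnt[is.na(cnt)] <- 1L
  tibble(read = unname(reads), count = cnt) |>
    group_by(.data$read) |>
    summarise(count = as.integer(sum(.data$count)))
}

#' Write a simulated dataset to disk
#'
#' Writes the genome FASTA, per-library reads (collapsed FASTA with
#' `tag_count` headers, or FASTQ with constant quality "I"), the ground
#' truth as GFF3 (`miRNA_primary_transcript` and `miRNA` features, 1-based
#' inclusive), the structural set FASTA, the design and expected-count TSVs,
#' and - when provided - the mRNA compendium FASTA and expression TSV.
#'
#' @param truth `sim_truth` from [plant_genome()].
#' @param libs `sim_libraries` from [simulate_libraries()].
#' @param dir output directory (created if needed).
#' @param format "fasta" (collapsed) or "fastq".
#' @param mrna optional `sim_mrna` from [generate_mrna_atlas()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, libs, dir, format = c("fasta", "fastq"),
                             mrna = NULL) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- Biostrings::DNAStringSet(truth$genome)
  Biostrings::writeXStringSet(gen, file.path(dir, "genome.fa"))
  if (nrow(truth$structural) > 0) {
    st <- Biostrings::DNAStringSet(setNames(truth$structural$sequence,
                                            truth$structural$id))
    Biostrings::writeXStringSet(st, file.path(dir, "structural.fa"))
  }
  write_truth_gff3(truth, file.path(dir, "truth.gff3"))
  utils::write.table(truth$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(libs$expected, file.path(dir, "expected_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (lib in names(libs$reads)) {
    tab <- libs$reads[[lib]]
    if (format == "fasta") {
      hdr <- sprintf("%s_tag%06d_%d", lib, seq_len(nrow(tab)), tab$count)
      writeLines(paste0(">", hdr, "\n", tab$read),
                 file.path(dir, paste0(lib, ".fa")))
    } else {
      expanded <- rep(tab$read, tab$count)
      ids <- sprintf("@%s_read%07d", lib, seq_along(expanded))
      writeLines(paste(ids, expanded, "+",
                       strrep("I", nchar(expanded)), sep = "\n"),
                 file.path(dir, paste0(lib, ".fastq")))
    }
  }
  if (!is.null(mrna)) {
    tx <- Biostrings::DNAStringSet(setNames(mrna$transcripts$sequence,
                                            mrna$transcripts$transcript_id))
    Biostrings::writeXStringSet(tx, file.path(dir, "mrna.fa"))
    utils::write.table(mrna$expression, file.path(dir, "mrna_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @keywords internal
write_truth_gff3 <- function(truth, path) {
  lines <- "##gff-version 3"
  m <- truth$mirna
  if (nrow(m) > 0) {
    pre <- sprintf(
      "%s\tsrnatlas_sim\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;role=%s",
      m$chrom, m$start, m$end, m$strand, m$locus_id, m$role)
    mat <- sprintf(
      "%s\tsrnatlas_sim\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s_mature;Derives_from=%s",
      m$chrom, m$mature_start, m$mature_end, m$strand, m$locus_id, m$locus_id)
    star <- sprintf(
      "%s\tsrnatlas_sim\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s_star;Derives_from=%s",
      m$chrom, m$star_start, m$star_end, m$strand, m$locus_id, m$locus_id)
    lines <- c(lines, pre, mat, star)
  }
  if (nrow(truth$sirna) > 0) {
    lines <- c(lines, sprintf(
      "%s\tsrnatlas_sim\tsiRNA_cluster\t%d\t%d\t.\t%s\t.\tID=%s",
      truth$sirna$chrom, truth$sirna$start, truth$sirna$end,
      truth$sirna$strand, truth$sirna$cluster_id))
  }
  writeLines(lines, path)
}
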