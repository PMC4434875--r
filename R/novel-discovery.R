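#' Validation criteria for novel miRNA candidates
#'
#' The identification rules are encoded as explicit, configurable
#' thresholds: allowed mature lengths 20-22 nt; at most `max_mismatch`
#' unpaired mature bases in the miR/miR* duplex; at most `max_bulge`
#' consecutive unpaired bases; duplex-associated reads (mature and star,
#' ends within 2 nt) covering at least `min_duplex_fraction` of the locus
#' reads; a main stem of at least `min_stem` pairs; and an optional
#' dual-replicate abundance gate of `min_abundance` TP5M. Family assignment
#' uses the `similarity` identity threshold.
#'
#' @param allowed_lengths allowed dominant-tag lengths.
#' @param max_mismatch maximum unpaired mature positions (default 4).
#' @param max_bulge maximum consecutive unpaired bases in mature or star
#'   (default 2).
#' @param min_duplex_fraction minimum fraction of locus reads from the
#'   miR/miR* duplex (default 0.75).
#' @param min_stem minimum main-stem pairs (default 15).
#' @param min_abundance TP5M threshold for the optional expression gate.
#' @param similarity identity threshold for family assignment (default 0.90,
#'   exceeded strictly).
#' @param apply_abundance_gate apply the dual-replicate abundance gate at
#'   discovery time (default FALSE: the gate belongs to the atlas stage).
#' @return list of class `candidate_criteria`.
#' @export
candidate_criteria <- function(allowed_lengths = 20:22, max_mismatch = 4,
                               max_bulge = 2, min_duplex_fraction = 0.75,
                               min_stem = 15, min_abundance = 10,
                               similarity = 0.90,
                               apply_abundance_gate = FALSE) {
  stopifnot(all(allowed_lengths %in% 20:22),
            max_mismatch >= 0, max_bulge >= 0,
            min_duplex_fraction >= 0, min_duplex_fraction <= 1)
  structure(list(allowed_lengths = as.integer(allowed_lengths),
                 max_mismatch = max_mismatch, max_bulge = max_bulge,
                 min_duplex_fraction = min_duplex_fraction,
                 min_stem = min_stem, min_abundance = min_abundance,
                 similarity = similarity,
                 apply_abundance_gate = apply_abundance_gate),
            class = "candidate_criteria")
}

#' Genomic alignments of genome-matched tags
#'
#' Exact full-length match positions of every genome-matched, non-structural
#' tag on both strands, 1-based inclusive.
#'
#' @param tags mapped `tag_table`.
#' @param genome named character vector or `DNAStringSet`.
#' @return tibble: `sequence`, `chrom`, `start`, `end`, `strand`.
#' @export
tag_alignments <- function(tags, genome) {
  subject <- as_dss(genome)
  if (is.null(names(subject))) names(subject) <- paste0("chr", seq_along(subject))
  t <- dplyr::as_tibble(tags)
  if ("hits" %in% names(t)) t <- t |> filter(.data$hits > 0)
  if ("structural" %in% names(t)) t <- t |> filter(!.data$structural)
  if (nrow(t) == 0) {
    return(tibble(sequence = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  seqs <- t$sequence
  w <- nchar(seqs)
  seqs_rc <- dna_revcomp(seqs)
  out <- list()
  for (ci in seq_along(subject)) {
    chrom <- names(subject)[ci]
    cs <- as.character(subject[[ci]])
    fw <- stringi::stri_locate_all_fixed(cs, seqs, overlap = TRUE)
    rv <- stringi::stri_locate_all_fixed(cs, seqs_rc, overlap = TRUE)
    for (k in seq_along(seqs)) {
      sf <- fw[[k]][, 1]
      if (!anyNA(sf)) {
        out[[length(out) + 1]] <- tibble(
          sequence = seqs[k], chrom = chrom,
          start = as.integer(sf), end = as.integer(sf + w[k] - 1L),
          strand = "+")
      }
      sr <- rv[[k]][, 1]
      if (!anyNA(sr)) {
        out[[length(out) + 1]] <- tibble(
          sequence = seqs[k], chrom = chrom,
          start = as.integer(sr), end = as.integer(sr + w[k] - 1L),
          strand = "-")
      }
    }
  }
  bind_rows(out)
}

#' Nominate candidate miRNA loci from unannotated tag clusters
#'
#' Clusters overlapping tag alignments outside annotated loci (alignments
#' closer than `cluster_gap` are merged, strands pooled), extracts a folding
#' window around each cluster's most abundant tag, and discards clusters
#' whose dominant tag is not 20-22 nt long (the siRNA guard).
#'
#' @param tables named list of normalized, mapped `tag_table`s.
#' @param genome named character vector or `DNAStringSet`.
#' @param annotated_loci tibble with `chrom`, `start`, `end` of annotated
#'   precursors (may have zero rows).
#' @param window folding window size centred on the dominant tag
#'   (default 250 nt).
#' @param cluster_gap maximum gap between alignments merged into one
#'   cluster (default 30 nt).
#' @param min_cluster_tp5m skip clusters whose summed TP5M is below this
#'   floor (default 1).
#' @return tibble of clusters: `cluster_id`, `chrom`, `start`, `end`,
#'   `dominant_sequence`, `dominant_start`, `dominant_end`,
#'   `dominant_strand`, `dominant_tp5m`, `total_tp5m`, `window_start`,
#'   `window_end`, `status` ("nominated" or "discarded_length").
#' @export
nominate_loci <- function(tables, genome, annotated_loci = NULL,
                          window = 250, cluster_gap = 30,
                          min_cluster_tp5m = 1) {
  merged <- purrr::map(tables, function(tab) {
    dplyr::as_tibble(tab) |>
      filter(!is.na(.data$tp5m)) |>
      select("sequence", "tp5m")
  }) |>
    bind_rows() |>
    group_by(.data$sequence) |>
    summarise(tp5m = sum(.data$tp5m))

  # pool sequences from all libraries with their flags from any library
  flags <- purrr::map(tables, function(tab) {
    dplyr::as_tibble(tab) |>
      select(dplyr::any_of(c("sequence", "hits", "structural")))
  }) |> bind_rows() |> distinct(.data$sequence, .keep_all = TRUE)
  tags <- merged |> inner_join(flags, by = "sequence") |>
    filter(.data$hits > 0, !.data$structural)

  aln <- tag_alignments(new_tag_table(tags), genome) |>
    inner_join(merged, by = "sequence")
  if (!is.null(annotated_loci) && nrow(annotated_loci) > 0) {
    inside <- purrr::pmap_lgl(
      list(aln$chrom, aln$start, aln$end),
      function(c, s, e) any(annotated_loci$chrom == c &
                              s <= annotated_loci$end &
                              e >= annotated_loci$start))
    aln <- aln[!inside, ]
  }
  if (nrow(aln) == 0) return(empty_cluster_tbl())

  gdss <- as_dss(genome)
  if (is.null(names(gdss))) names(gdss) <- paste0("chr", seq_along(gdss))
  glen <- setNames(Biostrings::width(gdss), names(gdss))

  clusters <- list()
  for (chrom in unique(aln$chrom)) {
    a <- aln |> filter(.data$chrom == !!chrom) |> arrange(.data$start)
    brk <- cumsum(c(0L, as.integer(
      a$start[-1] > cummax(a$end[-nrow(a)]) + cluster_gap)))
    a$cluster <- brk
    for (cl in unique(brk)) {
      b <- a |> filter(.data$cluster == cl)
      tot <- sum(b$tp5m[!duplicated(b$sequence)])
      if (tot < min_cluster_tp5m) next
      dom <- b |> arrange(dplyr::desc(.data$tp5m), .data$sequence) |>
        dplyr::slice(1)
      status <- if (nchar(dom$sequence) %in% 20:22) "nominated"
                else "discarded_length"
      centre <- (dom$start + dom$end) %/% 2
      ws <- max(1L, centre - as.integer(window) %/% 2L)
      we <- min(glen[[chrom]], ws + as.integer(window) - 1L)
      clusters[[length(clusters) + 1]] <- tibble(
        chrom = chrom, start = min(b$start), end = max(b$end),
        dominant_sequence = dom$sequence, dominant_start = dom$start,
        dominant_end = dom$end, dominant_strand = dom$strand,
        dominant_tp5m = dom$tp5m, total_tp5m = tot,
        window_start = ws, window_end = we, status = status
      )
    }
  }
  if (length(clusters) == 0) return(empty_cluster_tbl())
  bind_rows(clusters) |>
    arrange(.data$chrom, .data$start) |>
    mutate(cluster_id = sprintf("CL%04d", dplyr::row_number()),
           .before = 1)
}

#' @keywords internal
empty_cluster_tbl <- function() {
  tibble(cluster_id = character(), chrom = character(), start = integer(),
         end = integer(), dominant_sequence = character(),
         dominant_start = integer(), dominant_end = integer(),
         dominant_strand = character(), dominant_tp5m = numeric(),
         total_tp5m = numeric(), window_start = integer(),
         window_end = integer(), status = character())
}

#' Validate a nominated candidate locus against miRNA annotation criteria
#'
#' Folds the candidate window on the dominant tag's strand, requires a
#' hairpin-like main stem, a mature lying within one arm, a miR/miR* duplex
#' with limited mismatches and bulges, and locus reads concentrated in the
#' duplex; optionally applies the dual-replicate abundance gate. Rejections
#' carry explicit reasons ("not hairpin-like", "in loop", "sub-optimal
#' pairing", "bulge too large", "read dispersion", "low abundance",
#' "length gate").
#'
#' @param candidate one-row tibble from [nominate_loci()].
#' @param genome named character vector or `DNAStringSet`.
#' @param tables named list of normalized `tag_table`s.
#' @param criteria a [candidate_criteria()] list.
#' @param design library design (`library`, `sample`, `replicate`); needed
#'   only when `criteria$apply_abundance_gate` is TRUE.
#' @return one-row tibble: `cluster_id`, `accepted`, `reasons`, `mature`,
#'   `mature_start`, `mature_end` (window coordinates on the folded strand),
#'   `star`, `star_start`, `star_end`, `mismatches`, `max_bulge_run`,
#'   `duplex_fraction`.
#' @export
validate_candidate <- function(candidate, genome, tables,
                               criteria = candidate_criteria(),
                               design = NULL) {
  reject <- function(reasons) tibble(
    cluster_id = candidate$cluster_id, accepted = FALSE,
    reasons = paste(reasons, collapse = "; "),
    mature = candidate$dominant_sequence,
    mature_start = NA_integer_, mature_end = NA_integer_,
    star = NA_character_, star_start = NA_integer_, star_end = NA_integer_,
    mismatches = NA_integer_, max_bulge_run = NA_integer_,
    duplex_fraction = NA_real_
  )
  if (!nchar(candidate$dominant_sequence) %in% criteria$allowed_lengths) {
    return(reject("length gate"))
  }
  gseq <- as_dss(genome)
  if (is.null(names(gseq))) names(gseq) <- paste0("chr", seq_along(gseq))
  wseq <- as.character(Biostrings::subseq(
    gseq[[candidate$chrom]], candidate$window_start, candidate$window_end))
  if (candidate$dominant_strand == "-") wseq <- dna_revcomp(wseq)

  ms0 <- as.integer(regexpr(candidate$dominant_sequence, wseq, fixed = TRUE))
  if (ms0 < 0) return(reject("dominant tag absent from window"))
  me0 <- ms0 + nchar(candidate$dominant_sequence) - 1L

  # fold progressively tighter windows around the dominant tag: base-pair
  # maximization over a wide window can recruit flanking sequence into the
  # stem, so a locus is kept if any window scale yields a clean duplex
  n_w <- nchar(wseq)
  scales <- unique(pmin(n_w, c(n_w, 150L, 100L)))
  attempt <- NULL
  for (width in scales) {
    centre <- (ms0 + me0) %/% 2L
    ws <- max(1L, min(centre - width %/% 2L, n_w - width + 1L))
    we <- min(n_w, ws + width - 1L)
    if (ms0 < ws || me0 > we) next
    sub <- substr(wseq, ws, we)
    ms <- ms0 - ws + 1L
    me <- me0 - ws + 1L
    hp <- fold_hairpin(sub, min_stem = criteria$min_stem)
    if (!hp$hairpin) {
      if (is.null(attempt)) attempt <- list(reasons = "not hairpin-like")
      next
    }
    st <- tryCatch(infer_star(hp, c(ms, me)), error = function(e) e)
    if (inherits(st, "error")) {
      msg <- conditionMessage(st)
      r <- if (grepl("loop", msg)) "in loop" else "sub-optimal pairing"
      if (is.null(attempt) || identical(attempt$reasons, "not hairpin-like")) {
        attempt <- list(reasons = r)
      }
      next
    }
    unpaired <- hp$partner[ms:me] == 0
    mism <- sum(unpaired)
    runs <- rle(unpaired)
    bulge_m <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    sp <- st$star_span
    unp_s <- hp$partner[sp[1]:sp[2]] == 0
    runs_s <- rle(unp_s)
    bulge_s <- if (any(runs_s$values)) max(runs_s$lengths[runs_s$values]) else 0L
    bulge <- max(bulge_m, bulge_s)
    reasons <- character()
    if (mism > criteria$max_mismatch) reasons <- c(reasons, "sub-optimal pairing")
    if (bulge > criteria$max_bulge) reasons <- c(reasons, "bulge too large")
    cur <- list(reasons = reasons, ws = ws, sub = sub, ms = ms, me = me,
                st = st, sp = sp, mism = mism, bulge = bulge)
    if (is.null(attempt) || length(attempt$reasons) > 0) attempt <- cur
    if (length(reasons) == 0) break
  }
  if (is.null(attempt)) return(reject("not hairpin-like"))
  if (is.null(attempt$sub)) return(reject(attempt$reasons))
  ws <- attempt$ws; sub <- attempt$sub
  ms <- attempt$ms; me <- attempt$me
  st <- attempt$st; sp <- attempt$sp
  mism <- attempt$mism; bulge <- attempt$bulge
  reasons <- attempt$reasons

  # read-dispersion check over the full window on the mature strand
  locus_tags <- precursor_tag_abundance(wseq, tables)
  duplex_seqs <- unique(c(variant_sequences(sub, c(ms, me), 2),
                          variant_sequences(sub, sp, 2)))
  total <- sum(locus_tags$tp5m)
  duplex <- sum(locus_tags$tp5m[locus_tags$sequence %in% duplex_seqs])
  frac <- if (total > 0) duplex / total else 0
  if (frac < criteria$min_duplex_fraction) {
    reasons <- c(reasons, "read dispersion")
  }

  if (isTRUE(criteria$apply_abundance_gate)) {
    if (is.null(design)) abort("design is required for the abundance gate")
    gate <- mature_abundance_gate(candidate$dominant_sequence, tables, design,
                                  criteria$min_abundance)
    if (!gate) reasons <- c(reasons, "low abundance")
  }

  tibble(
    cluster_id = candidate$cluster_id,
    accepted = length(reasons) == 0,
    reasons = paste(reasons, collapse = "; "),
    mature = candidate$dominant_sequence,
    mature_start = ms + ws - 1L, mature_end = me + ws - 1L,
    star = st$star, star_start = sp[1] + ws - 1L, star_end = sp[2] + ws - 1L,
    mismatches = as.integer(mism), max_bulge_run = as.integer(bulge),
    duplex_fraction = frac
  )
}

# TRUE iff the mature tag reaches min_abundance TP5M in both replicates of
# at least one sample
#' @keywords internal
mature_abundance_gate <- function(mature, tables, design, min_abundance) {
  ab <- vapply(names(tables), function(lib) {
    t <- dplyr::as_tibble(tables[[lib]])
    v <- t$tp5m[match(mature, t$sequence)]
    if (is.na(v)) 0 else v
  }, numeric(1))
  d <- design |> filter(.data$library %in% names(ab)) |>
    mutate(tp5m = ab[.data$library]) |>
    group_by(.data$sample) |>
    summarise(ok = all(.data$tp5m >= min_abundance) & dplyr::n() >= 1)
  any(d$ok)
}

#' Assign candidate matures to known miRNA families by similarity
#'
#' Identity is `(L - d) / L` with `d` the unit-cost global edit distance
#' (insertions, deletions, substitutions) and `L` the candidate length. The
#' best reference with identity strictly above the threshold assigns its
#' family; ties are broken by smaller distance, then lexicographic family
#' name. Candidates with no such reference are `novel`.
#'
#' @param matures character vector of candidate mature sequences.
#' @param reference tibble with columns `family`, `sequence` (known plant
#'   mature miRNAs), non-empty.
#' @param threshold identity threshold, exceeded strictly (default 0.90).
#' @return tibble: `sequence`, `family` ("novel" when unassigned),
#'   `identity`, `distance`.
#' @export
assign_family_by_similarity <- function(matures, reference, threshold = 0.90) {
  if (nrow(reference) == 0) abort("reference set must be non-empty")
  matures <- dna_upper(matures)
  ref_seq <- dna_upper(reference$sequence)
  d <- utils::adist(matures, ref_seq)
  purrr::map(seq_along(matures), function(i) {
    L <- nchar(matures[i])
    identity <- (L - d[i, ]) / L
    ok <- which(identity > threshold)
    if (length(ok) == 0) {
      return(tibble(sequence = matures[i], family = "novel",
                    identity = max(identity), distance = min(d[i, ])))
    }
    ord <- ok[order(d[i, ok], reference$family[ok])]
    best <- ord[1]
    tibble(sequence = matures[i], family = reference$family[best],
           identity = identity[best], distance = d[i, best])
  }) |> bind_rows()
}

#' Summary statistics of accepted candidates
#'
#' @param candidates tibble with a `mature` column (and optionally `family`).
#' @return list: `n`, `five_prime_u_fraction` (fraction of matures starting
#'   with uridine, i.e. T in DNA space; NA when empty), `length_counts`
#'   tibble, `family_counts` tibble (when families present).
#' @export
candidate_stats <- function(candidates) {
  n <- nrow(candidates)
  if (n == 0) {
    return(list(n = 0L, five_prime_u_fraction = NA_real_,
                length_counts = tibble(length = integer(), n = integer()),
                family_counts = tibble(family = character(), n = integer())))
  }
  m <- dna_upper(candidates$mature)
  list(
    n = n,
    five_prime_u_fraction = mean(startsWith(m, "T")),
    length_counts = tibble(length = nchar(m)) |>
      dplyr::count(.data$length),
    family_counts = if ("family" %in% names(candidates)) {
      candidates |> dplyr::count(.data$family)
    } else tibble(family = character(), n = integer())
  )
}
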