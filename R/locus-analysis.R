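#' Dominant isoform of an annotated miRNA locus
#'
#' Among the tags mapping within the precursor on the annotated strand, the
#' dominant isoform is the tag with the highest TP5M summed across usable
#' libraries. An exact tie with the annotated mature sequence is resolved in
#' favour of the annotation. The dominant is classified against the
#' annotation as `none` (identical), `length_variant` (same 5' start,
#' different length) or `shift_variant` (start offset, reported signed as
#' dominant start minus annotated start in precursor coordinates).
#'
#' @param precursor precursor sequence, mature-strand orientation.
#' @param annotated_mature annotated mature sequence (must occur in the
#'   precursor).
#' @param tables named list of normalized `tag_table`s (usable libraries).
#' @return one-row tibble: `dominant_sequence`, `start`, `end`, `abundance`,
#'   `annotated_abundance`, `isomir_class`, `offset`; errors with
#'   "silent locus" when no tag maps within the precursor.
#' @export
dominant_isoform <- function(precursor, annotated_mature, tables) {
  precursor <- check_dna(precursor, "precursor")
  annotated_mature <- check_dna(annotated_mature, "annotated_mature")
  ann_start <- as.integer(regexpr(annotated_mature, precursor, fixed = TRUE))
  if (ann_start < 0) abort("annotated mature does not occur in the precursor")

  tags <- precursor_tag_abundance(precursor, tables)
  if (nrow(tags) == 0) abort("silent locus: no tag maps within the precursor")

  ann_ab <- tags$tp5m[match(annotated_mature, tags$sequence)]
  if (is.na(ann_ab)) ann_ab <- 0
  best <- max(tags$tp5m)
  top <- tags |> filter(.data$tp5m == best)
  dom <- if (ann_ab == best) {
    tibble(sequence = annotated_mature, tp5m = ann_ab)
  } else {
    top |> arrange(.data$sequence) |> dplyr::slice(1)
  }
  dstart <- as.integer(regexpr(dom$sequence, precursor, fixed = TRUE))
  offset <- dstart - ann_start
  cls <- if (dom$sequence == annotated_mature) {
    "none"
  } else if (offset == 0L) {
    "length_variant"
  } else {
    "shift_variant"
  }
  tibble(
    dominant_sequence = dom$sequence,
    start = dstart,
    end = dstart + nchar(dom$sequence) - 1L,
    abundance = dom$tp5m,
    annotated_abundance = ann_ab,
    isomir_class = cls,
    offset = if (cls == "none") 0L else offset
  )
}

# summed TP5M across libraries of every tag that is a substring of the
# precursor (annotated strand)
#' @keywords internal
precursor_tag_abundance <- function(precursor, tables) {
  purrr::map(tables, function(tab) {
    t <- dplyr::as_tibble(tab) |> filter(!is.na(.data$tp5m))
    t[stringi::stri_detect_fixed(precursor, t$sequence),
      c("sequence", "tp5m")]
  }) |>
    bind_rows() |>
    group_by(.data$sequence) |>
    summarise(tp5m = sum(.data$tp5m))
}

#' Infer the miRNA-star span from duplex geometry
#'
#' Given a folded hairpin and the mature span, the star span follows the
#' RNase III product geometry: the star's 5' end faces the partner of
#' `mature_end - 2` and its 3' end extends two bases (toward the precursor
#' 3' direction) past the partner of `mature_start`, producing 2-nt 3'
#' overhangs on both duplex strands. When an anchor position is unpaired,
#' the nearest paired position within the mature (preferring the smaller
#' distance, ties toward the mature interior) is used instead and the result
#' is flagged non-canonical. On a perfect stem the operation is an
#' involution: the star of the star is the mature.
#'
#' @param hairpin a `hairpin_model` from [fold_hairpin()], or any list with
#'   `partner` and `loop` elements.
#' @param mature_span integer length-2 vector, 1-based inclusive; must lie
#'   within one arm (not across the loop) with >= 60% of its bases paired.
#' @return list: `star_span` (sorted), `star` (sequence if available),
#'   `canonical` (TRUE iff both anchors were paired and the span lies inside
#'   the precursor), `adjusted` (anchors moved).
#' @export
infer_star <- function(hairpin, mature_span) {
  partner <- hairpin$partner
  n <- length(partner)
  ms <- mature_span[1]; me <- mature_span[2]
  if (ms < 1 || me > n || me <= ms) abort("invalid mature span")
  if (!is.null(hairpin$loop)) {
    lo <- hairpin$loop
    if (lo[2] >= lo[1] && ms <= lo[2] && me >= lo[1]) {
      abort("mature spans the loop (in loop)")
    }
  }
  mature_pos <- ms:me
  paired_frac <- mean(partner[mature_pos] > 0)
  if (paired_frac < 0.6) {
    abort(sprintf("mature has only %.0f%% paired bases (< 60%%)",
                  100 * paired_frac))
  }
  anchor <- function(p) {
    if (partner[p] > 0) return(list(pos = p, adjusted = FALSE))
    paired <- mature_pos[partner[mature_pos] > 0]
    d <- abs(paired - p)
    center <- (ms + me) / 2
    ord <- order(d, abs(paired - center))
    list(pos = paired[ord[1]], adjusted = TRUE)
  }
  a1 <- anchor(me - 2L)
  a2 <- anchor(ms)
  p1 <- partner[a1$pos]
  p2 <- partner[a2$pos] + 2L
  span <- sort(c(p1, p2))
  adjusted <- a1$adjusted || a2$adjusted
  inside <- span[1] >= 1 && span[2] <= n
  span[1] <- max(1L, span[1]); span[2] <- min(n, span[2])
  star <- if (!is.null(hairpin$sequence)) {
    substr(hairpin$sequence, span[1], span[2])
  } else NA_character_
  list(star_span = span, star = star,
       canonical = !adjusted && inside, adjusted = adjusted)
}

#' Detect additional duplexes on a precursor and their phasing
#'
#' Secondary abundant tags (summed TP5M >= `abundance_min`) within the
#' precursor that do not overlap the primary mature/star (within 2 nt) and
#' sit on one arm with enough pairing are reported as additional duplexes,
#' with their inferred star. The gap to the primary segment on the same arm,
#' `g = second_start - first_end - 1` (segments ordered by start), is
#' classified: `tandem` (g = 0), `phased` (g > 0 and g mod `phase` = 0),
#' `overlapping` (g < 0, magnitude reported), otherwise `unphased`.
#'
#' @param precursor precursor sequence.
#' @param hairpin folded `hairpin_model` of the precursor.
#' @param tables named list of normalized `tag_table`s.
#' @param primary_span mature span of the primary duplex (1-based).
#' @param primary_star_span star span of the primary duplex; inferred via
#'   [infer_star()] when NULL.
#' @param abundance_min minimum summed TP5M for a secondary tag (default 10).
#' @param phase phasing register in nt (default 21).
#' @return tibble: `sequence`, `start`, `end`, `abundance`, `star_start`,
#'   `star_end`, `gap`, `phase_class`; zero rows when none found.
#' @export
detect_additional_duplexes <- function(precursor, hairpin, tables,
                                       primary_span, primary_star_span = NULL,
                                       abundance_min = 10, phase = 21) {
  precursor <- check_dna(precursor, "precursor")
  if (is.null(primary_star_span)) {
    primary_star_span <- infer_star(hairpin, primary_span)$star_span
  }
  tags <- precursor_tag_abundance(precursor, tables) |>
    filter(.data$tp5m >= abundance_min)
  if (nrow(tags) == 0) return(empty_duplex_tbl())
  tags <- tags |>
    mutate(start = vapply(.data$sequence, function(s) {
      as.integer(regexpr(s, precursor, fixed = TRUE))
    }, integer(1)),
    end = .data$start + nchar(.data$sequence) - 1L)

  overlaps <- function(s, e, span, slack = 0L) {
    s <= span[2] + slack && e >= span[1] - slack
  }
  # drop isomiR-like near-duplicates of the primary mature/star (both ends
  # within 2 nt); genuinely shifted tags - including partially overlapping
  # second duplexes - stay in
  near_dup <- function(s, e, span) {
    abs(s - span[1]) <= 2L && abs(e - span[2]) <= 2L
  }
  sec <- tags |>
    filter(!purrr::map2_lgl(.data$start, .data$end, near_dup, primary_span),
           !purrr::map2_lgl(.data$start, .data$end, near_dup,
                            primary_star_span))
  if (nrow(sec) == 0) return(empty_duplex_tbl())

  # greedy: repeatedly take the most abundant remaining non-overlapping tag
  sec <- sec |> arrange(dplyr::desc(.data$tp5m), .data$sequence)
  picked <- list()
  taken <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(sec))) {
    s <- sec$start[i]; e <- sec$end[i]
    if (nrow(taken) > 0 &&
        any(apply(taken, 1, function(sp) overlaps(s, e, sp, 0L)))) next
    st <- tryCatch(infer_star(hairpin, c(s, e)), error = function(e) NULL)
    if (is.null(st)) next
    # same-arm primary segment for phasing
    same_arm <- if (spans_overlap_arm(hairpin, c(s, e), primary_span)) {
      primary_span
    } else {
      primary_star_span
    }
    first <- if (same_arm[1] <= s) same_arm else c(s, e)
    second <- if (same_arm[1] <= s) c(s, e) else same_arm
    g <- second[1] - first[2] - 1L
    cls <- if (g == 0L) "tandem"
      else if (g > 0L && g %% phase == 0L) sprintf("phased(%d)", g)
      else if (g < 0L) sprintf("overlapping(%d)", abs(g))
      else sprintf("unphased(%d)", g)
    picked[[length(picked) + 1]] <- tibble(
      sequence = sec$sequence[i], start = s, end = e,
      abundance = sec$tp5m[i],
      star_start = st$star_span[1], star_end = st$star_span[2],
      gap = g, phase_class = cls
    )
    taken <- rbind(taken, c(s, e), st$star_span)
  }
  if (length(picked) == 0) return(empty_duplex_tbl())
  bind_rows(picked)
}

#' @keywords internal
empty_duplex_tbl <- function() {
  tibble(sequence = character(), start = integer(), end = integer(),
         abundance = numeric(), star_start = integer(), star_end = integer(),
         gap = integer(), phase_class = character())
}

# are two spans on the same arm of the hairpin?
#' @keywords internal
spans_overlap_arm <- function(hairpin, a, b) {
  arm_of <- function(sp) {
    if (!is.null(hairpin$arm5) &&
        sp[1] >= hairpin$arm5[1] && sp[2] <= hairpin$arm5[2]) return("5p")
    if (!is.null(hairpin$arm3) &&
        sp[1] >= hairpin$arm3[1] && sp[2] <= hairpin$arm3[2]) return("3p")
    "none"
  }
  arm_of(a) != "none" && arm_of(a) == arm_of(b)
}

#' Detect antisense (sense/antisense) locus pairs
#'
#' Links pairs of loci whose precursor spans overlap reciprocally by at
#' least `min_overlap` on opposite strands of the same chromosome -
#' candidates for miRNAs transcribed from the antisense strand of another
#' miRNA locus (RC-miRNAs).
#'
#' @param loci tibble with columns `locus_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param min_overlap minimum reciprocal overlap fraction (default 0.5).
#' @return tibble: `locus_1`, `locus_2`, `overlap_bp`, `overlap_frac_1`,
#'   `overlap_frac_2`.
#' @export
detect_antisense <- function(loci, min_overlap = 0.5) {
  out <- list()
  n <- nrow(loci)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (loci$chrom[i] != loci$chrom[j]) next
      if (loci$strand[i] == loci$strand[j]) next
      ov <- min(loci$end[i], loci$end[j]) - max(loci$start[i], loci$start[j]) + 1L
      if (ov <= 0) next
      f1 <- ov / (loci$end[i] - loci$start[i] + 1L)
      f2 <- ov / (loci$end[j] - loci$start[j] + 1L)
      if (f1 >= min_overlap && f2 >= min_overlap) {
        out[[length(out) + 1]] <- tibble(
          locus_1 = loci$locus_id[i], locus_2 = loci$locus_id[j],
          overlap_bp = ov, overlap_frac_1 = f1, overlap_frac_2 = f2
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(locus_1 = character(), locus_2 = character(),
                  overlap_bp = integer(), overlap_frac_1 = numeric(),
                  overlap_frac_2 = numeric()))
  }
  bind_rows(out)
}
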