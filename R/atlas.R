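#' Dual-replicate expression calls
#'
#' A miRNA is called expressed in a sample only when every biological
#' replicate of that sample reaches the TP5M threshold (default 10). A
#' sample with a missing replicate value is marked unusable for that miRNA.
#' Raising the threshold can only shrink the expressed set (monotonicity).
#'
#' @param mat replicate-level wide abundance tibble (`mirna_id` + library
#'   columns).
#' @param design tibble with `library`, `sample`, `organ`, `stage`.
#' @param threshold TP5M expression threshold (default 10).
#' @return tidy calls tibble: `mirna_id`, `sample`, `organ`, `stage`,
#'   `expressed`, `usable`, `n_replicates`.
#' @export
call_expressed <- function(mat, design, threshold = 10) {
  libs <- setdiff(names(mat), "mirna_id")
  if (!all(libs %in% design$library)) {
    abort("every library column must appear in design")
  }
  mat |>
    tidyr::pivot_longer(all_of(libs), names_to = "library",
                        values_to = "tp5m") |>
    left_join(design |> select("library", "sample", "organ", "stage"),
              by = "library") |>
    group_by(.data$mirna_id, .data$sample, .data$organ, .data$stage) |>
    summarise(
      expressed = all(!is.na(.data$tp5m)) && all(.data$tp5m >= threshold),
      usable = all(!is.na(.data$tp5m)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

#' Classify organ specificity of each miRNA
#'
#' `common`: expressed in every usable sample. `organ_specific(o)`:
#' expressed in at least one stage of organ `o` and in no sample of any
#' other organ. Everything else (including miRNAs expressed nowhere) is
#' `neither`. With a single organ the common class takes precedence. The
#' classes are mutually exclusive per miRNA.
#'
#' @param calls tidy calls from [call_expressed()].
#' @return tibble: `mirna_id`, `class` ("common" / "organ_specific" /
#'   "neither"), `organ` (home organ for organ-specific calls, else NA),
#'   `n_samples_expressed`.
#' @export
classify_specificity <- function(calls) {
  calls |>
    group_by(.data$mirna_id) |>
    summarise(
      n_samples_expressed = sum(.data$expressed),
      all_usable_expressed = sum(.data$usable) > 0 &&
        all(.data$expressed[.data$usable]),
      organs_expressed = list(unique(.data$organ[.data$expressed])),
      .groups = "drop"
    ) |>
    mutate(
      class = dplyr::case_when(
        .data$n_samples_expressed > 0 & .data$all_usable_expressed ~ "common",
        lengths(.data$organs_expressed) == 1 ~ "organ_specific",
        TRUE ~ "neither"
      ),
      organ = ifelse(.data$class == "organ_specific",
                     vapply(.data$organs_expressed, `[`, character(1), 1),
                     NA_character_)
    ) |>
    select("mirna_id", "class", "organ", "n_samples_expressed")
}

#' Stage sharing of expressed miRNAs within an organ
#'
#' For one organ, counts miRNAs expressed in exactly k of its stages, the
#' set expressed in all stages, and that set's fraction of the organ's
#' expressed union.
#'
#' @param calls tidy calls from [call_expressed()].
#' @param organ organ label.
#' @return list: `counts` (tibble k, n), `all_stages` (miRNA ids expressed
#'   in every stage), `union_n`, `fraction` (all-stages / union), `n_stages`,
#'   `single_stage_note` (TRUE when the organ has only one stage, making the
#'   sharing trivial).
#' @export
stage_sharing <- function(calls, organ) {
  oc <- calls |> filter(.data$organ == !!organ)
  if (nrow(oc) == 0) abort(sprintf("organ '%s' not present in calls", organ))
  n_stages <- dplyr::n_distinct(oc$stage)
  per <- oc |>
    group_by(.data$mirna_id) |>
    summarise(k = sum(.data$expressed), .groups = "drop") |>
    filter(.data$k > 0)
  counts <- tibble(k = seq_len(n_stages)) |>
    left_join(per |> dplyr::count(.data$k), by = "k") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  all_stages <- per$mirna_id[per$k == n_stages]
  union_n <- nrow(per)
  list(
    counts = counts,
    all_stages = all_stages,
    union_n = union_n,
    fraction = if (union_n > 0) length(all_stages) / union_n else NA_real_,
    n_stages = n_stages,
    single_stage_note = n_stages == 1
  )
}

#' Select stage-variable miRNAs and per-sample top-expressed lists
#'
#' Within an organ's developmental track, the fold change between two stage
#' averages is `max(a, b) / max(min(a, b), 1)` - the denominator is floored
#' at 1 TP5M so absent stages yield finite fold changes. A miRNA is selected
#' when it is called expressed in at least one compared stage and its
#' maximum pairwise fold change reaches `min_fold`. The per-sample top lists
#' rank the replicate-averaged abundances.
#'
#' @param avg_mat sample-averaged wide abundance tibble (`mirna_id` +
#'   sample columns).
#' @param design sample design with `sample`, `organ`, `stage` (one row per
#'   sample).
#' @param calls tidy calls from [call_expressed()].
#' @param organ the organ track to analyse (>= 2 stages).
#' @param min_fold fold-change threshold (default 5).
#' @param top_n size of the per-sample top-expressed list (default 20).
#' @return list: `selected` (tibble mirna_id, max_fold_change, stage_high,
#'   stage_low), `top_expressed` (tibble sample, rank, mirna_id, tp5m).
#' @export
select_variable <- function(avg_mat, design, calls, organ,
                            min_fold = 5, top_n = 20) {
  sd <- design |> distinct(.data$sample, .data$organ, .data$stage) |>
    filter(.data$organ == !!organ)
  if (nrow(sd) < 2) abort("organ track needs >= 2 stages")
  samples <- sd$sample
  m <- as.matrix(avg_mat[, samples, drop = FALSE])
  rownames(m) <- avg_mat$mirna_id

  pairs <- utils::combn(seq_along(samples), 2)
  fc <- matrix(NA_real_, nrow(m), ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- m[, pairs[1, p]]; b <- m[, pairs[2, p]]
    fc[, p] <- pmax(a, b) / pmax(pmin(a, b), 1)
  }
  best <- apply(fc, 1, which.max)
  max_fc <- fc[cbind(seq_len(nrow(m)), best)]

  expressed_any <- calls |>
    filter(.data$organ == !!organ, .data$expressed) |>
    distinct(.data$mirna_id) |> pull()
  selected <- tibble(
    mirna_id = rownames(m),
    max_fold_change = max_fc,
    stage_high = samples[ifelse(m[cbind(seq_len(nrow(m)), pairs[1, best])] >=
                                  m[cbind(seq_len(nrow(m)), pairs[2, best])],
                                pairs[1, best], pairs[2, best])],
    stage_low = samples[ifelse(m[cbind(seq_len(nrow(m)), pairs[1, best])] >=
                                 m[cbind(seq_len(nrow(m)), pairs[2, best])],
                               pairs[2, best], pairs[1, best])]
  ) |>
    filter(.data$max_fold_change >= min_fold,
           .data$mirna_id %in% expressed_any) |>
    arrange(dplyr::desc(.data$max_fold_change))

  all_samples <- setdiff(names(avg_mat), "mirna_id")
  top <- avg_mat |>
    tidyr::pivot_longer(all_of(all_samples), names_to = "sample",
                        values_to = "tp5m") |>
    group_by(.data$sample) |>
    arrange(dplyr::desc(.data$tp5m), .data$mirna_id, .by_group = TRUE) |>
    dplyr::slice_head(n = top_n) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup() |>
    select("sample", "rank", "mirna_id", "tp5m")

  list(selected = selected, top_expressed = top)
}
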