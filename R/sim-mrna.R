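#' Generate a transcript compendium coupled to planted miRNAs
#'
#' Builds transcript sequences for a set of planted miRNA:target pairs plus
#' an equal number of uncoupled decoy transcripts. Each target embeds a site
#' perfectly complementary to its miRNA (penalty score 0 under
#' [score_duplex()], hence <= 3 by construction). Target expression is
#' generated on the log10(1 + x) scale as an affine image of
#' r*z + sqrt(1 - r^2)*noise, where z is the z-scored transformed
#' miRNA profile, so the Pearson correlation between the transformed target
#' and miRNA profiles has expectation `coupling_r`; with `coupling_r = -1`
#' the construction is noiseless and the sample correlation is exactly -1.
#'
#' Target miRNAs are taken from the planted loci with the most variable
#' designed profiles (trajectory and organ-specific roles first), since a
#' flat profile carries no correlation signal.
#'
#' @param truth a `sim_truth` from [plant_genome()].
#' @param n_samples number of expression samples (>= 4, at most the number of
#'   organ x stage samples in the truth design).
#' @param coupling_r expected Pearson correlation in \[-1, 1\] between target
#'   and miRNA transformed profiles.
#' @param seed integer seed.
#' @param transcript_length length of each generated transcript.
#' @return list of class `sim_mrna`: `transcripts` (tibble: transcript_id,
#'   sequence, mirna_id, site_start) and `expression` (wide tibble,
#'   transcripts x samples) plus `mirna_expression` (designed miRNA TP5M over
#'   the same samples, for correlation tests).
#' @export
generate_mrna_atlas <- function(truth, n_samples = NULL,
                                coupling_r = truth$config$target_coupling_r,
                                seed = truth$config$seed + 77L,
                                transcript_length = 500L) {
  if (!inherits(truth, "sim_truth")) abort("truth must come from plant_genome()")
  if (abs(coupling_r) > 1) abort("coupling_r must lie in [-1, 1]")
  samples <- unique(truth$design$sample)
  if (is.null(n_samples)) n_samples <- length(samples)
  if (n_samples < 4) abort("n_samples must be >= 4")
  if (n_samples > length(samples)) {
    abort(sprintf(
      "n_samples (%d) exceeds the %d organ x stage samples in the design; use a larger sim_config",
      n_samples, length(samples)))
  }
  samples <- samples[seq_len(n_samples)]
  n_pairs <- truth$config$n_target_pairs

  # designed miRNA TP5M profiles over the selected samples
  prof <- truth$abundance_design |>
    filter(.data$type == "mirna_arm", .data$sample %in% samples) |>
    tidyr::pivot_wider(id_cols = "feature_id", names_from = "sample",
                       values_from = "tp5m_design")
  pm <- as.matrix(prof[, samples, drop = FALSE])
  rownames(pm) <- prof$feature_id
  tm <- log10(1 + pm)
  vv <- apply(tm, 1, sd)
  role <- truth$mirna$role[match(rownames(pm), truth$mirna$locus_id)]
  pref <- order(role %in% c("trajectory", "organ_specific"), vv,
                decreasing = TRUE)
  usable <- pref[vv[pref] > 0]
  if (length(usable) < n_pairs) {
    abort("not enough variable planted miRNA profiles for n_target_pairs")
  }
  target_loci <- rownames(pm)[usable[seq_len(n_pairs)]]

  withr::with_seed(as.integer(seed), {
    tx <- vector("list", 2L * n_pairs)
    expr <- matrix(0, nrow = 2L * n_pairs, ncol = length(samples),
                   dimnames = list(NULL, samples))
    for (i in seq_len(n_pairs)) {
      locus <- target_loci[i]
      mature <- truth$mirna$mature[truth$mirna$locus_id == locus]
      site <- dna_revcomp(mature)
      pos <- sample.int(transcript_length - nchar(site) + 1L, 1)
      seq <- rand_dna(transcript_length)
      substr(seq, pos, pos + nchar(site) - 1L) <- site
      tx[[i]] <- tibble(transcript_id = sprintf("TX%04d", i), sequence = seq,
                        mirna_id = locus, site_start = pos)
      z <- as.vector(scale(tm[locus, ]))
      eps <- rnorm(length(samples))
      tl <- 3 + 0.6 * (coupling_r * z + sqrt(1 - coupling_r^2) * eps)
      expr[i, ] <- pmax(10^tl - 1, 0)
    }
    for (i in seq_len(n_pairs)) {
      j <- n_pairs + i
      tx[[j]] <- tibble(transcript_id = sprintf("TX%04d", j),
                        sequence = rand_dna(transcript_length),
                        mirna_id = NA_character_, site_start = NA_integer_)
      expr[j, ] <- pmax(10^(2 + 0.5 * rnorm(length(samples))) - 1, 0)
    }
  })

  transcripts <- bind_rows(tx)
  expression <- bind_cols(tibble(transcript_id = transcripts$transcript_id),
                          as_tibble(expr))
  mirna_expression <- bind_cols(tibble(mirna_id = rownames(pm)),
                                as_tibble(pm))
  structure(list(transcripts = transcripts, expression = expression,
                 mirna_expression = mirna_expression),
            class = "sim_mrna")
}
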