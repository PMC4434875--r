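#' Plant a synthetic genome with miRNA loci, siRNA clusters and decoys
#'
#' Generates a random-background genome and plants, at non-overlapping
#' positions: miRNA hairpin precursors (each built with [build_hairpin()]),
#' siRNA cluster spans that will emit heterogeneous 24-nt tags, and
#' structural-RNA decoy spans whose sequences also populate the structural
#' reference set. Every planted feature occurs in the genome exactly once
#' (verified by exact string search; colliding draws are resampled).
#'
#' miRNA loci are assigned expression roles: `organ_specific` (expressed in a
#' single home organ), `common` (expressed everywhere), `trajectory` (planted
#' stage-wise fold change) and `background` (low abundance, below the usual
#' 10 TP5M call threshold). Designed abundances are expressed in TP5M and
#' converted to expected per-library read counts against the designed
#' genome-matched, non-structural denominator.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sim_truth` with elements `genome` (named
#'   character, one chromosome), `mirna`, `sirna`, `structural` (tibbles of
#'   planted features, 1-based inclusive coordinates), `design` (library
#'   metadata), `abundance_design` (per-feature, per-sample designed TP5M and
#'   expected per-library read counts) and `config`.
#' @export
plant_genome <- function(config) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) abort("config must be a sim_config object")

  withr::with_seed(cfg$seed, {
    design <- config_design(cfg)
    samples <- unique(design$sample)

    # ---- feature sequences -------------------------------------------------
    mirna <- build_planted_mirnas(cfg)
    sirna_len <- 200L
    decoy_len <- 120L
    sirna_seqs <- vapply(seq_len(cfg$n_sirna_clusters),
                         function(i) rand_dna(sirna_len), character(1))
    decoy_seqs <- vapply(seq_len(cfg$n_structural_decoys),
                         function(i) rand_dna(decoy_len), character(1))

    feat_seq <- c(mirna$genome_seq, sirna_seqs, decoy_seqs)
    feat_type <- c(rep("mirna", nrow(mirna)),
                   rep("sirna", length(sirna_seqs)),
                   rep("decoy", length(decoy_seqs)))
    lens <- nchar(feat_seq)
    k <- length(feat_seq)
    min_gap <- 50L
    need <- sum(lens) + (k + 1L) * min_gap
    if (cfg$genome_length < need) {
      abort(sprintf(
        "genome_length %d too small to host %d features without overlap (need >= %d bp)",
        cfg$genome_length, k, need))
    }

    # ---- placement: random order, random extra gap between features --------
    ord <- sample.int(k)
    slack <- cfg$genome_length - sum(lens) - (k + 1L) * min_gap
    extra <- as.vector(rmultinom(1, slack, rep(1, k + 1L)))
    starts <- integer(k)
    pos <- 1L
    for (i in seq_len(k)) {
      pos <- pos + min_gap + extra[i]
      starts[ord[i]] <- pos
      pos <- pos + lens[ord[i]]
    }
    genome <- rand_dna(cfg$genome_length)
    for (i in seq_len(k)) {
      substr(genome, starts[i], starts[i] + lens[i] - 1L) <- feat_seq[i]
    }

    # uniqueness of planted precursors and matures (resample genome background
    # is never needed in practice; verify and fail loudly if violated)
    n_mi <- nrow(mirna)
    occ <- vapply(feat_seq, function(s) {
      count_occurrences(genome, s) + count_occurrences(genome, dna_revcomp(s))
    }, numeric(1))
    if (any(occ != 1)) {
      abort("a planted feature maps more than once; use a different seed")
    }

    # ---- genomic coordinates ----------------------------------------------
    mirna$start <- starts[seq_len(n_mi)]
    mirna$end <- mirna$start + nchar(mirna$precursor) - 1L
    loc <- function(p, strand, s, e) ifelse(strand == "+", s + p - 1L, e - p + 1L)
    m1 <- loc(mirna$mature_s_prec, mirna$strand, mirna$start, mirna$end)
    m2 <- loc(mirna$mature_e_prec, mirna$strand, mirna$start, mirna$end)
    mirna$mature_start <- pmin(m1, m2)
    mirna$mature_end <- pmax(m1, m2)
    s1 <- loc(mirna$star_s_prec, mirna$strand, mirna$start, mirna$end)
    s2 <- loc(mirna$star_e_prec, mirna$strand, mirna$start, mirna$end)
    mirna$star_start <- pmin(s1, s2)
    mirna$star_end <- pmax(s1, s2)
    mirna$chrom <- "chr1"

    sirna <- tibble(
      cluster_id = sprintf("SIR%02d", seq_len(cfg$n_sirna_clusters)),
      chrom = "chr1",
      start = starts[feat_type == "sirna"],
      end = starts[feat_type == "sirna"] + sirna_len - 1L,
      strand = "+"
    )
    structural <- tibble(
      id = sprintf("STRUCT%02d", seq_len(cfg$n_structural_decoys)),
      sequence = decoy_seqs,
      chrom = "chr1",
      start = starts[feat_type == "decoy"],
      end = starts[feat_type == "decoy"] + decoy_len - 1L,
      strand = "+"
    )

    abundance_design <- design_abundances(cfg, mirna, sirna, structural, samples)
  })

  structure(
    list(
      genome = c(chr1 = genome),
      mirna = mirna,
      sirna = sirna,
      structural = structural,
      design = design,
      abundance_design = abundance_design,
      config = cfg
    ),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d bp genome | %d miRNA loci, %d siRNA clusters, %d decoys | %d libraries\n",
              nchar(x$genome[[1]]), nrow(x$mirna), nrow(x$sirna),
              nrow(x$structural), nrow(x$design)))
  invisible(x)
}

# count exact occurrences of pattern in subject (plus strand only)
#' @keywords internal
count_occurrences <- function(subject, pattern) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  sum(hits > 0)
}

# draw the planted miRNA loci (roles, sequences, hairpins); runs inside the
# caller's seeded context
#' @keywords internal
build_planted_mirnas <- function(cfg) {
  n <- cfg$n_mirna_loci
  if (n == 0) {
    return(tibble(
      locus_id = character(), precursor = character(), genome_seq = character(),
      strand = character(), arm = character(), mature = character(),
      star = character(), mature_s_prec = integer(), mature_e_prec = integer(),
      star_s_prec = integer(), star_e_prec = integer(),
      loop_s_prec = integer(), loop_e_prec = integer(),
      role = character(), home_organ = character()
    ))
  }
  n_os <- round(cfg$fraction_organ_specific * n)
  n_common <- round(cfg$fraction_common * n)
  n_rest <- n - n_os - n_common
  n_traj <- n_rest %/% 2
  n_bg <- n_rest - n_traj
  roles <- c(rep("organ_specific", n_os), rep("common", n_common),
             rep("trajectory", n_traj), rep("background", n_bg))
  # spread organ-specific loci across organs (every organ gets specific
  # miRNAs once there are at least as many such loci as organs)
  organ_cycle <- rep(sample(cfg$organs), length.out = max(n_os, 1))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in 1:25) {
      L <- sample(c(20L, 21L, 22L), 1, prob = c(0.15, 0.7, 0.15))
      mature <- rand_dna(L)
      hp <- build_hairpin(mature,
                          loop_length = sample(8:14, 1),
                          arm_padding = sample(2:6, 1),
                          arm = sample(c("5p", "3p"), 1))
      # mature and star must not be trivially degenerate
      if (hp$mature != hp$star) break
    }
    strand <- sample(c("+", "-"), 1)
    rows[[i]] <- tibble(
      locus_id = sprintf("MIR%03d", i),
      precursor = hp$precursor,
      genome_seq = if (strand == "+") hp$precursor else dna_revcomp(hp$precursor),
      strand = strand,
      arm = hp$arm,
      mature = hp$mature,
      star = hp$star,
      mature_s_prec = hp$mature_span[1],
      mature_e_prec = hp$mature_span[2],
      star_s_prec = hp$star_span[1],
      star_e_prec = hp$star_span[2],
      loop_s_prec = hp$loop_span[1],
      loop_e_prec = hp$loop_span[2],
      role = roles[i],
      home_organ = if (roles[i] == "organ_specific") organ_cycle[i] else NA_character_
    )
  }
  bind_rows(rows)
}

# designed TP5M per miRNA locus x sample and the resulting expected
# per-library read counts for every emitting feature
#' @keywords internal
design_abundances <- function(cfg, mirna, sirna, structural, samples) {
  R <- cfg$reads_per_library
  frac_struct <- 0.05
  frac_junk <- 0.005
  D <- R * (1 - frac_struct - frac_junk)  # designed genome-matched non-structural total
  n_stage <- cfg$stages_per_organ
  sample_organ <- sub("_S[0-9]+$", "", samples)
  sample_stage <- as.integer(sub("^.*_S", "", samples))

  rows <- list()
  for (i in seq_len(nrow(mirna))) {
    role <- mirna$role[i]
    tp5m <- switch(role,
      common = {
        base <- stats::rlnorm(1, log(20000), 1)
        base * stats::rlnorm(length(samples), 0, 0.2)
      },
      organ_specific = {
        base <- stats::rlnorm(1, log(5000), 0.5)
        ifelse(sample_organ == mirna$home_organ[i],
               base * stats::rlnorm(length(samples), 0, 0.15), 0)
      },
      trajectory = {
        base <- stats::rlnorm(1, log(8000), 0.5)
        mult <- if (n_stage > 1) {
          cfg$fc_trajectory_fold^((sample_stage - 1) / (n_stage - 1))
        } else rep(1, length(samples))
        base * mult * stats::rlnorm(length(samples), 0, 0.1)
      },
      background = runif(length(samples), 1, 8)
    )
    rows[[i]] <- tibble(
      feature_id = mirna$locus_id[i], type = "mirna_arm",
      sample = samples, tp5m_design = tp5m
    )
  }
  mi <- bind_rows(rows)
  if (nrow(mi) == 0) {
    mi <- tibble(feature_id = character(), type = character(),
                 sample = character(), tp5m_design = numeric())
  }
  # keep total designed miRNA TP5M well below the 5e6 budget
  if (nrow(mi) > 0) {
    tot <- mi |> group_by(.data$sample) |> summarise(s = sum(.data$tp5m_design))
    if (max(tot$s) > 2e6) {
      mi$tp5m_design <- mi$tp5m_design * 2e6 / max(tot$s)
    }
  }
  star <- mi |>
    mutate(type = "star",
           feature_id = paste0(.data$feature_id, "*"),
           tp5m_design = 0.15 * .data$tp5m_design)
  mi_all <- bind_rows(mi, star) |>
    mutate(mean_counts = .data$tp5m_design * D / 5e6)

  # siRNA clusters absorb the remaining genome-matched budget
  mi_tot <- tibble(sample = samples) |>
    left_join(mi_all |> group_by(.data$sample) |>
                summarise(s = sum(.data$mean_counts)),
              by = "sample") |>
    mutate(s = dplyr::coalesce(.data$s, 0))
  sir <- NULL
  if (nrow(sirna) > 0) {
    sir <- tidyr::expand_grid(feature_id = sirna$cluster_id, sample = samples) |>
      left_join(mi_tot, by = "sample") |>
      mutate(type = "sirna",
             tp5m_design = NA_real_,
             mean_counts = (D - .data$s) / nrow(sirna)) |>
      select(-"s")
  }
  dec <- NULL
  if (nrow(structural) > 0) {
    dec <- tidyr::expand_grid(feature_id = structural$id, sample = samples) |>
      mutate(type = "decoy", tp5m_design = NA_real_,
             mean_counts = frac_struct * R / nrow(structural))
  }
  junk <- tibble(feature_id = "JUNK", type = "junk", sample = samples,
                 tp5m_design = NA_real_, mean_counts = frac_junk * R)
  bind_rows(mi_all, sir, dec, junk) |>
    select("feature_id", "type", "sample", "tp5m_design", "mean_counts")
}
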