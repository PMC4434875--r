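#' Simulate small-RNA sequencing libraries from a planted genome
#'
#' For every organ x stage x replicate library, read counts for each emitting
#' feature are drawn from a negative binomial with the designed mean and the
#' configured dispersion (variance = mu + dispersion * mu^2; dispersion 0
#' gives the Poisson limit). miRNA arms additionally emit isomiR end-variants
#' (end shifts of 1-3 nt with geometric decay, at the configured spread),
#' siRNA clusters emit many distinct low-count 24-nt tags from both strands,
#' and structural decoys emit fragments of the structural reference
#' sequences. The 3' adapter is appended to every read; a small fraction of
#' adapter-free junk reads exercises the trimming statistics.
#'
#' Identical config + truth (same seed) give byte-identical output.
#'
#' @param config the [sim_config()] used to build `truth`.
#' @param truth a `sim_truth` from [plant_genome()].
#' @return a list of class `sim_libraries`: `reads` (named list of tibbles
#'   with columns `read`, `count`; adapter included), `design` (library
#'   metadata) and `expected` (per-library expected counts per feature).
#' @export
simulate_libraries <- function(config, truth) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) abort("config must be a sim_config object")
  if (!inherits(truth, "sim_truth")) abort("truth must come from plant_genome()")
  if (cfg$replicates < 1) abort("replicates must be >= 1")

  design <- truth$design
  genome <- truth$genome[[1]]
  draw <- function(n, mu) {
    if (cfg$nb_dispersion > 0) {
      rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      rpois(n, mu)
    }
  }

  # precompute per-locus extended reference oriented to the mature strand,
  # so isomiR end shifts of up to 3 nt can reach into genomic flanks
  flank <- 6L
  mir <- truth$mirna
  ext <- vector("list", nrow(mir))
  if (nrow(mir) > 0) {
    for (i in seq_len(nrow(mir))) {
      gs <- max(1L, mir$start[i] - flank)
      ge <- min(nchar(genome), mir$end[i] + flank)
      s <- substr(genome, gs, ge)
      if (mir$strand[i] == "-") s <- dna_revcomp(s)
      off <- if (mir$strand[i] == "-") mir$end[i] + flank - ge else mir$start[i] - gs
      # local precursor position p maps to ext position p + off
      ext[[i]] <- list(seq = s, off = off)
    }
  }
  # isomiR variant menu: end (5'/3') x direction (trim/extend) x magnitude 1:3
  vgrid <- expand.grid(end = c("5p", "3p"), dir = c("trim", "ext"),
                       mag = 1:3, stringsAsFactors = FALSE)
  vprob <- 0.5^vgrid$mag
  vprob <- vprob / sum(vprob)

  exp_tbl <- truth$abundance_design |>
    inner_join(design, by = "sample", relationship = "many-to-many") |>
    select("feature_id", "type", "library", "sample", "tp5m_design",
           "mean_counts")

  reads <- setNames(vector("list", nrow(design)), design$library)
  withr::with_seed(cfg$seed + 1009L, {
    for (li in seq_len(nrow(design))) {
      lib <- design$library[li]
      smp <- design$sample[li]
      ad <- exp_tbl |> filter(.data$library == lib)
      parts <- list()

      if (nrow(mir) > 0) {
        arm_means <- ad |> filter(.data$type == "mirna_arm")
        arm_means <- arm_means[match(mir$locus_id, arm_means$feature_id), ]
        star_means <- ad |> filter(.data$type == "star")
        star_means <- star_means[match(paste0(mir$locus_id, "*"),
                                       star_means$feature_id), ]
        for (i in seq_len(nrow(mir))) {
          total <- draw(1, arm_means$mean_counts[i])
          if (total > 0) {
            n_exact <- stats::rbinom(1, total, 1 - cfg$isomir_spread)
            n_var <- total - n_exact
            seqs <- mir$mature[i]
            cnts <- n_exact
            if (n_var > 0) {
              alloc <- as.vector(rmultinom(1, n_var, vprob))
              for (v in which(alloc > 0)) {
                vs <- isomir_sequence(ext[[i]], mir$mature_s_prec[i],
                                      mir$mature_e_prec[i],
                                      vgrid$end[v], vgrid$dir[v], vgrid$mag[v])
                if (!is.na(vs)) {
                  seqs <- c(seqs, vs); cnts <- c(cnts, alloc[v])
                }
              }
            }
            keep <- cnts > 0
            if (any(keep)) parts[[length(parts) + 1]] <-
              tibble(read = seqs[keep], count = cnts[keep])
          }
          st <- draw(1, star_means$mean_counts[i])
          if (st > 0) parts[[length(parts) + 1]] <-
            tibble(read = mir$star[i], count = st)
        }
      }

      if (nrow(truth$sirna) > 0) {
        sir_means <- ad |> filter(.data$type == "sirna")
        sir_means <- sir_means[match(truth$sirna$cluster_id,
                                     sir_means$feature_id), ]
        for (i in seq_len(nrow(truth$sirna))) {
          B <- draw(1, sir_means$mean_counts[i])
          if (B == 0) next
          n_pos <- 40L
          span_s <- truth$sirna$start[i]
          starts <- span_s + sample.int(truth$sirna$end[i] - span_s - 22L,
                                        n_pos, replace = TRUE) - 1L
          strands <- sample(c("+", "-"), n_pos, replace = TRUE)
          cnts <- as.vector(rmultinom(1, B, rep(1, n_pos)))
          tags <- substr(rep(genome, n_pos), starts, starts + 23L)
          tags <- ifelse(strands == "-", dna_revcomp(tags), tags)
          keep <- cnts > 0
          parts[[length(parts) + 1]] <- tibble(read = tags[keep],
                                               count = cnts[keep])
        }
      }

      if (nrow(truth$structural) > 0) {
        dec_means <- ad |> filter(.data$type == "decoy")
        dec_means <- dec_means[match(truth$structural$id,
                                     dec_means$feature_id), ]
        for (i in seq_len(nrow(truth$structural))) {
          B <- draw(1, dec_means$mean_counts[i])
          if (B == 0) next
          n_frag <- 30L
          fl <- sample(16:36, n_frag, replace = TRUE)
          fs <- vapply(fl, function(l) {
            sample.int(nchar(truth$structural$sequence[i]) - l + 1L, 1)
          }, integer(1))
          frags <- substr(rep(truth$structural$sequence[i], n_frag),
                          fs, fs + fl - 1L)
          cnts <- as.vector(rmultinom(1, B, rep(1, n_frag)))
          keep <- cnts > 0
          parts[[length(parts) + 1]] <- tibble(read = frags[keep],
                                               count = cnts[keep])
        }
      }

      tab <- if (length(parts)) {
        bind_rows(parts) |>
          mutate(read = paste0(.data$read, cfg$adapter_sequence))
      } else {
        tibble(read = character(), count = integer())
      }

      junk_mean <- ad$mean_counts[ad$type == "junk"]
      nj <- if (length(junk_mean)) draw(1, junk_mean) else 0L
      if (nj > 0) {
        jn <- vapply(seq_len(min(nj, 50L)), function(i) rand_dna(40L),
                     character(1))
        jc <- as.vector(rmultinom(1, nj, rep(1, length(jn))))
        tab <- bind_rows(tab, tibble(read = jn[jc > 0], count = jc[jc > 0]))
      }

      reads[[lib]] <- tab |>
        group_by(.data$read) |>
        summarise(count = as.integer(sum(.data$count))) |>
        arrange(.data$read)
    }
  })

  structure(list(reads = reads, design = design, expected = exp_tbl),
            class = "sim_libraries")
}

# sequence of an isomiR end variant on the extended, strand-oriented
# precursor reference; NA when the shift would leave the reference
#' @keywords internal
isomir_sequence <- function(ext, ms, me, end, dir, mag) {
  s <- ms; e <- me
  if (end == "5p") {
    s <- if (dir == "trim") s + mag else s - mag
  } else {
    e <- if (dir == "trim") e - mag else e + mag
  }
  ps <- s + ext$off; pe <- e + ext$off
  if (ps < 1 || pe > nchar(ext$seq) || pe - ps + 1 < 16) return(NA_character_)
  substr(ext$seq, ps, pe)
}

#' @export
print.sim_libraries <- function(x, ...) {
  cat(sprintf("<sim_libraries> %d libraries, %.0f reads on average\n",
              length(x$reads),
              mean(vapply(x$reads, function(t) sum(t$count), numeric(1)))))
  invisible(x)
}
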