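#' Simulation configuration
#'
#' Bundles every knob of the synthetic small-RNA dataset: a random genome
#' carrying hairpin miRNA loci, heterogeneous 24-nt siRNA clusters and
#' structural-RNA decoys, sequenced as organ x stage x replicate libraries
#' with negative-binomial count noise, isomiR end-variants and a fixed 3'
#' adapter, plus an mRNA compendium whose planted targets are anti-correlated
#' with their miRNAs.
#'
#' Defaults describe the study conditions used throughout the test-suite:
#' a 100 kb genome, 30 miRNA loci, 10 siRNA clusters, 5 structural decoys,
#' 6 organs x 2 stages x 2 replicates and 200,000 reads per library.
#'
#' @param genome_length genome size in bp.
#' @param n_mirna_loci number of planted miRNA hairpin loci.
#' @param n_sirna_clusters number of heterogeneous 24-nt siRNA cluster loci.
#' @param n_structural_decoys number of structural-RNA (rRNA/tRNA-like) decoys,
#'   planted in the genome and listed in the structural reference set.
#' @param organs character vector of organ labels.
#' @param stages_per_organ developmental stages per organ.
#' @param replicates biological replicates per organ x stage sample.
#' @param reads_per_library expected total reads per library.
#' @param nb_dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 gives the Poisson limit.
#' @param isomir_spread probability that a read from a miRNA arm is an
#'   end-variant (isomiR) rather than the exact planted mature sequence.
#' @param adapter_sequence 3' adapter appended to every simulated read.
#' @param fraction_organ_specific fraction of miRNA loci expressed in a single
#'   home organ only.
#' @param fraction_common fraction of miRNA loci expressed in every sample.
#' @param fc_trajectory_fold planted fold change between first and last stage
#'   for trajectory loci (>= 1).
#' @param n_target_pairs number of planted miRNA:target transcript pairs.
#' @param target_coupling_r expected Pearson correlation between a planted
#'   target and its miRNA, in \[-1, 0\].
#' @param seed integer seed governing every random choice.
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 20000, n_mirna_loci = 5,
#'                   n_sirna_clusters = 2, n_structural_decoys = 1,
#'                   reads_per_library = 20000, seed = 1)
sim_config <- function(genome_length = 100000,
                       n_mirna_loci = 30,
                       n_sirna_clusters = 10,
                       n_structural_decoys = 5,
                       organs = c("bud", "inflorescence", "flower",
                                  "stamen", "berry", "rachis"),
                       stages_per_organ = 2,
                       replicates = 2,
                       reads_per_library = 200000,
                       nb_dispersion = 0.1,
                       isomir_spread = 0.15,
                       adapter_sequence = "TGGAATTCTCGGGTGCCAAGG",
                       fraction_organ_specific = 0.3,
                       fraction_common = 0.4,
                       fc_trajectory_fold = 5,
                       n_target_pairs = 10,
                       target_coupling_r = -0.8,
                       seed = 20150516) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_mirna_loci = as.integer(n_mirna_loci),
    n_sirna_clusters = as.integer(n_sirna_clusters),
    n_structural_decoys = as.integer(n_structural_decoys),
    organs = as.character(organs),
    stages_per_organ = as.integer(stages_per_organ),
    replicates = as.integer(replicates),
    reads_per_library = as.integer(reads_per_library),
    nb_dispersion = as.numeric(nb_dispersion),
    isomir_spread = as.numeric(isomir_spread),
    adapter_sequence = check_dna(adapter_sequence, "adapter_sequence"),
    fraction_organ_specific = as.numeric(fraction_organ_specific),
    fraction_common = as.numeric(fraction_common),
    fc_trajectory_fold = as.numeric(fc_trajectory_fold),
    n_target_pairs = as.integer(n_target_pairs),
    target_coupling_r = as.numeric(target_coupling_r),
    seed = as.integer(seed)
  )
  if (cfg$reads_per_library <= 0) abort("reads_per_library must be > 0")
  if (cfg$replicates < 1) abort("replicates must be >= 1")
  if (cfg$nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  fr <- c(cfg$fraction_organ_specific, cfg$fraction_common, cfg$isomir_spread)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (cfg$fraction_organ_specific + cfg$fraction_common > 1) {
    abort("fraction_organ_specific + fraction_common must be <= 1")
  }
  if (cfg$fc_trajectory_fold < 1) abort("fc_trajectory_fold must be >= 1")
  if (cfg$target_coupling_r < -1 || cfg$target_coupling_r > 0) {
    abort("target_coupling_r must lie in [-1, 0]")
  }
  if (length(cfg$organs) < 1) abort("at least one organ is required")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d bp | %d miRNA loci, %d siRNA clusters, %d decoys\n",
              x$genome_length, x$n_mirna_loci, x$n_sirna_clusters,
              x$n_structural_decoys))
  cat(sprintf("  design: %d organs x %d stages x %d replicates, %d reads/library\n",
              length(x$organs), x$stages_per_organ, x$replicates,
              x$reads_per_library))
  cat(sprintf("  noise: NB dispersion %.3g, isomiR spread %.3g | seed %d\n",
              x$nb_dispersion, x$isomir_spread, x$seed))
  invisible(x)
}

# sample metadata table implied by a config: one row per library
#' @keywords internal
config_design <- function(cfg) {
  grid <- expand.grid(
    replicate = seq_len(cfg$replicates),
    stage = paste0("S", seq_len(cfg$stages_per_organ)),
    organ = cfg$organs,
    stringsAsFactors = FALSE
  )
  tibble(
    library = sprintf("%s_%s_R%d", grid$organ, grid$stage, grid$replicate),
    sample = sprintf("%s_%s", grid$organ, grid$stage),
    organ = grid$organ,
    stage = grid$stage,
    replicate = as.integer(grid$replicate)
  )
}
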