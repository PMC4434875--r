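test_that("constructed hairpins place the star with 2-nt 3' overhangs", {
  # 21-nt mature, 2-nt padding, 10-nt loop -> 60-nt precursor with 25-nt arms
  withr::with_seed(5, {
    mature <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                    collapse = "")
  })
  hp <- build_hairpin(mature, loop_length = 10, arm_padding = 2, seed = 9)
  expect_equal(nchar(hp$precursor), 60)
  expect_equal(hp$mature_span, c(3, 23))
  expect_equal(hp$star_span, c(40, 60))
  expect_equal(hp$loop_span, c(26, 35))
  # brute-force pairing check of the palindromic stem: position i pairs n+1-i
  ch <- strsplit(hp$precursor, "")[[1]]
  for (i in 1:25) {
    expect_gt(oracle_pair_weight(ch[i], ch[61 - i]), 0)
  }
  # overhang geometry: star 3' end extends 2 past the partner of mature start
  expect_equal(hp$star_span[2], (60 + 1 - hp$mature_span[1]) + 2)
  expect_equal(hp$star_span[1], 60 + 1 - (hp$mature_span[2] - 2))
})

test_that("hairpin construction enforces the length gate and is deterministic", {
  expect_error(build_hairpin(strrep("A", 19)), "20-22")
  expect_error(build_hairpin(strrep("ACGTA", 5)), "20-22")  # 25 nt
  expect_error(build_hairpin(strrep("ACGTACG", 3), loop_length = 2), "loop")
  m <- strrep("ACGTA", 4)  # 20 nt
  a <- build_hairpin(m, seed = 7)
  b <- build_hairpin(m, seed = 7)
  expect_identical(a$precursor, b$precursor)
  expect_false(identical(build_hairpin(m, seed = 7)$precursor,
                         build_hairpin(m, seed = 8)$precursor))
})

test_that("3p-arm matures get mirrored duplex geometry", {
  m <- substr(strrep("GATCC", 5), 1, 21)
  hp <- build_hairpin(m, loop_length = 10, arm_padding = 3, arm = "3p",
                      seed = 2)
  n <- nchar(hp$precursor)
  # star of the star returns the mature span (involution on a perfect stem)
  f <- fold_hairpin(hp$precursor)
  st <- infer_star(f, hp$mature_span)
  expect_equal(st$star_span, hp$star_span)
  back <- infer_star(f, st$star_span)
  expect_equal(back$star_span, hp$mature_span)
  expect_true(st$canonical)
})

test_that("planted genomes host every feature exactly once at its coordinates", {
  cfg <- sim_config(genome_length = 40000, n_mirna_loci = 10,
                    n_sirna_clusters = 2, n_structural_decoys = 2,
                    organs = c("bud", "leaf"), reads_per_library = 5000,
                    seed = 21)
  truth <- plant_genome(cfg)
  g <- truth$genome[[1]]
  expect_equal(nchar(g), 40000)
  for (i in seq_len(nrow(truth$mirna))) {
    m <- truth$mirna[i, ]
    found <- substr(g, m$start, m$end)
    expected <- if (m$strand == "+") m$precursor else dna_revcomp(m$precursor)
    expect_identical(found, expected)
    # exact substring search recovers the locus exactly once
    expect_equal(oracle_count_hits(m$precursor, g), 1)
  }
  # mature genomic span matches the mature sequence
  m1 <- truth$mirna[1, ]
  gm <- substr(g, m1$mature_start, m1$mature_end)
  if (m1$strand == "-") gm <- dna_revcomp(gm)
  expect_identical(gm, m1$mature)
})

test_that("degenerate and undersized genome configs behave as specified", {
  cfg0 <- sim_config(genome_length = 5000, n_mirna_loci = 0,
                     n_sirna_clusters = 0, n_structural_decoys = 0,
                     organs = "bud", reads_per_library = 100, seed = 1)
  t0 <- plant_genome(cfg0)
  expect_equal(nrow(t0$mirna), 0)
  expect_equal(nrow(t0$sirna), 0)
  expect_equal(nchar(t0$genome[[1]]), 5000)
  expect_error(
    plant_genome(sim_config(genome_length = 2000, n_mirna_loci = 10,
                            organs = "bud", reads_per_library = 100,
                            seed = 1)),
    "too small")
  g1 <- plant_genome(sim_config(genome_length = 5000, n_mirna_loci = 0,
                                n_sirna_clusters = 0,
                                n_structural_decoys = 0, organs = "bud",
                                reads_per_library = 100, seed = 1))
  g2 <- plant_genome(sim_config(genome_length = 5000, n_mirna_loci = 0,
                                n_sirna_clusters = 0,
                                n_structural_decoys = 0, organs = "bud",
                                reads_per_library = 100, seed = 2))
  expect_false(identical(g1$genome, g2$genome))
})

test_that("designed per-library means are conserved and role-consistent", {
  s <- small_sim()
  des <- s$truth$abundance_design
  sums <- tapply(des$mean_counts, des$sample, sum)
  expect_true(all(abs(sums - s$cfg$reads_per_library) < 1e-6))
  # organ-specific loci have zero designed abundance outside the home organ
  os <- s$truth$mirna[s$truth$mirna$role == "organ_specific", ]
  for (i in seq_len(nrow(os))) {
    dd <- des[des$feature_id == os$locus_id[i], ]
    away <- !startsWith(dd$sample, os$home_organ[i])
    expect_true(all(dd$tp5m_design[away] == 0))
    expect_true(any(dd$tp5m_design[!away] > 0))
  }
})

test_that("library simulation is reproducible and count noise follows the model", {
  cfg <- sim_config(genome_length = 20000, n_mirna_loci = 3,
                    n_sirna_clusters = 1, n_structural_decoys = 1,
                    organs = "bud", stages_per_organ = 1, replicates = 50,
                    reads_per_library = 4000, nb_dispersion = 0,
                    isomir_spread = 0, seed = 31)
  truth <- plant_genome(cfg)
  l1 <- simulate_libraries(cfg, truth)
  l2 <- simulate_libraries(cfg, truth)
  expect_identical(l1$reads, l2$reads)

  # Poisson limit: observed mature counts across 50 replicate libraries have
  # mean within 3 standard errors of the designed mean
  loc <- truth$mirna[truth$mirna$role == "common", ][1, ]
  des <- truth$abundance_design
  mu <- des$mean_counts[des$feature_id == loc$locus_id][1]
  obs <- vapply(l1$reads, function(tab) {
    i <- match(paste0(loc$mature, cfg$adapter_sequence), tab$read)
    if (is.na(i)) 0 else tab$count[i]
  }, numeric(1))
  se <- sqrt(mu / length(obs))
  expect_lt(abs(mean(obs) - mu), 3 * se)
})

test_that("default libraries show the 21/24-nt bimodal size profile", {
  s <- small_sim()
  sp <- size_profile_and_qc(s$tabs[[1]], min_distinct = 50)
  expect_true(sp$qc$pass)
  prof <- sp$profile
  a <- function(l) prof$abundance[prof$length == l]
  expect_gt(a(21), a(20)); expect_gt(a(21), a(22))
  expect_gt(a(24), a(23)); expect_gt(a(24), a(25))
})

test_that("planted matures are observed whenever their design warrants it", {
  s <- small_sim()
  des <- s$truth$abundance_design
  mir <- s$truth$mirna
  for (li in seq_len(nrow(s$truth$design))) {
    lib <- s$truth$design$library[li]
    smp <- s$truth$design$sample[li]
    tab <- s$tabs[[lib]]
    for (i in seq_len(nrow(mir))) {
      d <- des$tp5m_design[des$feature_id == mir$locus_id[i] &
                             des$sample == smp & des$type == "mirna_arm"]
      if (d >= 10) {
        expect_true(mir$mature[i] %in% tab$sequence,
                    label = sprintf("%s in %s", mir$locus_id[i], lib))
      }
    }
  }
})

test_that("mRNA atlas couples planted targets at the requested correlation", {
  s <- small_sim()
  # noiseless anti-coupling: sample correlation exactly -1 on transformed scale
  mr <- generate_mrna_atlas(s$truth, coupling_r = -1, seed = 5)
  tx <- mr$transcripts[!is.na(mr$transcripts$mirna_id), ]
  for (i in seq_len(min(3, nrow(tx)))) {
    y <- as.numeric(mr$expression[
      mr$expression$transcript_id == tx$transcript_id[i],
      -1])
    x <- as.numeric(mr$mirna_expression[
      mr$mirna_expression$mirna_id == tx$mirna_id[i], -1])
    expect_equal(cor(log10(1 + x), log10(1 + y)), -1, tolerance = 1e-12)
  }
  # planted sites score <= 3 (they are perfect complements: score 0)
  for (i in seq_len(nrow(tx))) {
    mature <- s$truth$mirna$mature[s$truth$mirna$locus_id == tx$mirna_id[i]]
    site <- substr(tx$sequence[i], tx$site_start[i],
                   tx$site_start[i] + nchar(mature) - 1)
    expect_lte(score_duplex(mature, site)$score, 3)
  }
  expect_error(generate_mrna_atlas(s$truth, coupling_r = -1.2), "-1, 1")
})

test_that("mRNA coupling hits its expectation across replicate draws", {
  s <- small_sim()
  rs <- numeric(40)
  for (k in seq_len(40)) {
    mr <- generate_mrna_atlas(s$truth, coupling_r = -0.8, seed = 1000 + k)
    tx <- mr$transcripts[!is.na(mr$transcripts$mirna_id), ][1, ]
    y <- as.numeric(mr$expression[
      mr$expression$transcript_id == tx$transcript_id, -1])
    x <- as.numeric(mr$mirna_expression[
      mr$mirna_expression$mirna_id == tx$mirna_id, -1])
    rs[k] <- cor(log10(1 + x), log10(1 + y))
  }
  expect_lt(abs(mean(rs) - (-0.8)), 0.1)
})

test_that("simulation round-trips through the on-disk formats", {
  s <- small_sim()
  dir <- withr::local_tempdir()
  write_simulation(s$truth, s$libs, dir, format = "fasta")
  expect_true(file.exists(file.path(dir, "genome.fa")))
  expect_true(file.exists(file.path(dir, "truth.gff3")))
  lib1 <- s$truth$design$library[1]
  rt <- read_reads(file.path(dir, paste0(lib1, ".fa")))
  orig <- s$libs$reads[[lib1]]
  expect_equal(sum(rt$count), sum(orig$count))
  expect_setequal(rt$read, orig$read)
  gff <- readLines(file.path(dir, "truth.gff3"))
  expect_match(gff[1], "gff-version 3")
  expect_equal(sum(grepl("miRNA_primary_transcript", gff)),
               nrow(s$truth$mirna))
})
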