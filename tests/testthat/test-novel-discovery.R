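test_that("unannotated planted miRNA loci are nominated and accepted", {
  s <- small_sim()
  truth <- s$truth
  # hide two loci from the annotation; they must be rediscovered
  hidden <- truth$mirna$locus_id[truth$mirna$role == "common"][1:2]
  annotated <- truth$mirna[!truth$mirna$locus_id %in% hidden,
                           c("chrom", "start", "end")]
  clusters <- nominate_loci(s$tabs, truth$genome, annotated)
  expect_gt(nrow(clusters), 0)
  hid <- truth$mirna[truth$mirna$locus_id %in% hidden, ]
  for (i in seq_len(nrow(hid))) {
    hit <- clusters[clusters$start <= hid$end[i] &
                      clusters$end >= hid$start[i], ]
    expect_gt(nrow(hit), 0, label = hid$locus_id[i])
    expect_equal(hit$status[1], "nominated")
    expect_equal(hit$dominant_sequence[1], hid$mature[i])
    val <- validate_candidate(hit[1, ], truth$genome, s$tabs)
    expect_true(val$accepted, label = hid$locus_id[i])
    expect_equal(val$star, hid$star[i])
  }
  # no cluster inside an annotated precursor
  ann_hit <- purrr::pmap_lgl(
    list(clusters$dominant_start, clusters$dominant_end),
    function(s_, e_) any(s_ <= annotated$end & e_ >= annotated$start))
  expect_false(any(ann_hit))
})

test_that("siRNA clusters fall at the length gate and decoys never pass", {
  s <- small_sim()
  truth <- s$truth
  clusters <- nominate_loci(s$tabs, truth$genome,
                            truth$mirna[, c("chrom", "start", "end")])
  # clusters overlapping planted siRNA spans have 24-nt dominants
  for (i in seq_len(nrow(truth$sirna))) {
    hit <- clusters[clusters$start <= truth$sirna$end[i] &
                      clusters$end >= truth$sirna$start[i], ]
    if (nrow(hit) == 0) next
    expect_true(all(hit$status == "discarded_length"),
                label = truth$sirna$cluster_id[i])
  }
  # nothing overlapping a structural decoy is ever accepted (structural
  # tags are excluded upstream, so no cluster should even be nominated)
  for (i in seq_len(nrow(truth$structural))) {
    hit <- clusters[clusters$start <= truth$structural$end[i] &
                      clusters$end >= truth$structural$start[i], ]
    expect_equal(nrow(hit), 0)
  }
})

test_that("heterogeneous read dispersion is an explicit rejection reason", {
  s <- small_sim()
  truth <- s$truth
  hid <- truth$mirna[truth$mirna$role == "common", ][1, ]
  cand <- tibble::tibble(
    cluster_id = "CLX", chrom = "chr1",
    start = hid$mature_start, end = hid$mature_end,
    dominant_sequence = hid$mature,
    dominant_start = hid$mature_start, dominant_end = hid$mature_end,
    dominant_strand = hid$strand, dominant_tp5m = 100, total_tp5m = 100,
    window_start = max(1L, hid$start - 60L),
    window_end = hid$end + 60L, status = "nominated")
  # clean duplex-dominated table: accepted
  tabs_ok <- list(L = fake_tag_table(c(hid$mature, hid$star), c(80, 20)))
  ok <- validate_candidate(cand, truth$genome, tabs_ok)
  expect_true(ok$accepted)
  # scatter 40% of reads across non-duplex window positions: rejected
  loop_tag <- substr(hid$precursor, hid$loop_s_prec - 8L,
                     hid$loop_s_prec + 15L)
  off_tag <- substr(hid$precursor, hid$mature_s_prec + 8L,
                    hid$mature_e_prec + 8L)
  tabs_bad <- list(L = fake_tag_table(
    c(hid$mature, hid$star, loop_tag, off_tag), c(40, 15, 25, 20)))
  bad <- validate_candidate(cand, truth$genome, tabs_bad)
  expect_false(bad$accepted)
  expect_match(bad$reasons, "read dispersion")
})

test_that("duplex pairing quality gates reject bad hairpins", {
  s <- small_sim()
  truth <- s$truth
  hidden <- truth$mirna$locus_id[truth$mirna$role == "common"][1]
  annotated <- truth$mirna[truth$mirna$locus_id != hidden,
                           c("chrom", "start", "end")]
  clusters <- nominate_loci(s$tabs, truth$genome, annotated)
  hid <- truth$mirna[truth$mirna$locus_id == hidden, ]
  hit <- clusters[clusters$start <= hid$end & clusters$end >= hid$start, ][1, ]
  # impossible stem requirement -> "not hairpin-like"
  strict <- candidate_criteria(min_stem = 200)
  expect_match(validate_candidate(hit, truth$genome, s$tabs,
                                  strict)$reasons, "not hairpin-like")
  # zero-mismatch requirement may or may not trip; monotonicity is the
  # contract: relaxing a threshold never rejects a previously accepted locus
  base <- validate_candidate(hit, truth$genome, s$tabs,
                             candidate_criteria())
  relaxed <- validate_candidate(hit, truth$genome, s$tabs,
                                candidate_criteria(max_mismatch = 10,
                                                   max_bulge = 10,
                                                   min_duplex_fraction = 0,
                                                   min_stem = 10))
  if (base$accepted) expect_true(relaxed$accepted)
})

test_that("family assignment applies the >90% identity rule with edit distance", {
  ref <- tibble::tibble(
    family = c("miR156", "miR172"),
    sequence = c("TGACAGAAGAGAGTGAGCACA",  # 21 nt
                 "AGAATCTTGATGATGCTGCAT"))
  # 2 edits from miR156: identity 19/21 = 90.5% -> assigned
  two <- ref$sequence[1]
  substr(two, 3, 3) <- "T"; substr(two, 10, 10) <- "C"
  # 3 edits: 18/21 = 85.7% -> novel
  three <- two; substr(three, 15, 15) <- "A"
  res <- assign_family_by_similarity(c(ref$sequence[1], two, three), ref)
  expect_equal(res$family, c("miR156", "miR156", "novel"))
  expect_equal(res$identity[1], 1)
  expect_equal(res$distance[1], 0)
  expect_equal(res$identity[2], 19 / 21, tolerance = 1e-12)
  # tie-break: equal distance to two families -> lexicographically first
  ref2 <- tibble::tibble(family = c("b-fam", "a-fam"),
                         sequence = c(two, two))
  expect_equal(assign_family_by_similarity(two, ref2)$family, "a-fam")
  expect_error(assign_family_by_similarity(two, ref[0, ]), "non-empty")
})

test_that("candidate statistics report the 5'-uridine fraction", {
  withr::with_seed(4, {
    m <- rand_seq(132, 21)
  })
  m <- paste0(c(rep("T", 60), rep("A", 72)), substr(m, 2, 21))
  st <- candidate_stats(tibble::tibble(mature = m))
  expect_equal(st$n, 132)
  expect_equal(st$five_prime_u_fraction, 60 / 132, tolerance = 1e-12)
  empty <- candidate_stats(tibble::tibble(mature = character()))
  expect_true(is.na(empty$five_prime_u_fraction))
  allu <- candidate_stats(tibble::tibble(mature = rep("TGACT", 3)))
  expect_equal(allu$five_prime_u_fraction, 1)
})
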