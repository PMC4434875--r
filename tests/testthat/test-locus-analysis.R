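test_that("folding solves small cases and rejects pairless sequences", {
  f <- fold_hairpin("GGGAAACCC", min_stem = 3)
  expect_equal(f$score, 9)  # three G:C pairs
  expect_equal(f$dot_bracket, "(((...)))")
  expect_equal(f$loop, c(4, 6))
  polyA <- fold_hairpin(strrep("A", 50))
  expect_equal(polyA$score, 0)
  expect_false(polyA$hairpin)
  expect_equal(polyA$stem_pairs, 0)
})

test_that("the folding DP equals exhaustive enumeration on short sequences", {
  withr::with_seed(101, {
    for (k in 1:60) {
      n <- sample(5:12, 1)
      s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
      expect_equal(fold_hairpin(s, min_stem = 1)$score, oracle_fold_max(s),
                   label = s)
    }
  })
})

test_that("folding is deterministic and respects the minimum loop", {
  s <- paste0(strrep("GC", 10), strrep("A", 3), strrep("GC", 10))
  f1 <- fold_hairpin(s)
  f2 <- fold_hairpin(s)
  expect_identical(f1$partner, f2$partner)
  # no hairpin loop shorter than min_loop
  op <- which(f1$partner > seq_along(f1$partner))
  if (length(op)) {
    expect_true(all(f1$partner[op] - op - 1 >=
                      ifelse(f1$partner[op] - op - 1 < 0, 0, 3) * 0 + 3 |
                      f1$partner[op] - op - 1 >= 3))
  }
})

test_that("dominant isoform selection matches the shifted-variant scenario", {
  hp <- build_hairpin(paste0("T", strrep("GACTC", 4)), seed = 41,
                      arm_padding = 5, loop_length = 12)
  pre <- hp$precursor
  ann <- hp$mature                               # annotated mature
  var <- substr(pre, hp$mature_span[1] + 3,
                hp$mature_span[2] + 3)           # starts 3 nt downstream
  tabs <- list(L = fake_tag_table(c(ann, var), c(6, 4243)))
  # counts become TP5M but proportions are preserved: variant dominates
  res <- dominant_isoform(pre, ann, tabs)
  expect_equal(res$dominant_sequence, var)
  expect_equal(res$isomir_class, "shift_variant")
  expect_equal(res$offset, 3)
  expect_gt(res$abundance, res$annotated_abundance)
})

test_that("annotated sequence wins exact ties and classifies as none", {
  hp <- build_hairpin(strrep("CAGTT", 4), seed = 42, arm_padding = 4)
  pre <- hp$precursor
  ann <- hp$mature
  var <- substr(pre, hp$mature_span[1], hp$mature_span[2] + 1)
  tabs <- list(L = fake_tag_table(c(ann, var), c(100, 100)))
  res <- dominant_isoform(pre, ann, tabs)
  expect_equal(res$dominant_sequence, ann)
  expect_equal(res$isomir_class, "none")
  # same-start longer variant dominating -> length_variant
  tabs2 <- list(L = fake_tag_table(c(ann, var), c(10, 100)))
  res2 <- dominant_isoform(pre, ann, tabs2)
  expect_equal(res2$isomir_class, "length_variant")
  expect_equal(res2$offset, 0)
  # library-order invariance
  tabs3 <- list(A = fake_tag_table(ann, 10), B = fake_tag_table(var, 100))
  tabs4 <- rev(tabs3)
  expect_equal(dominant_isoform(pre, ann, tabs3)$dominant_sequence,
               dominant_isoform(pre, ann, tabs4)$dominant_sequence)
  expect_error(dominant_isoform(pre, ann, list(L = fake_tag_table(
    strrep("T", 21), 5))), "silent locus")
})

test_that("star inference reproduces perfect-stem geometry", {
  # 60-nt perfect stem: arms 25 nt, loop 26-35, mature at 3-23
  withr::with_seed(55, {
    mature <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                    collapse = "")
  })
  hp <- build_hairpin(mature, loop_length = 10, arm_padding = 2, seed = 13)
  f <- fold_hairpin(hp$precursor)
  st <- infer_star(f, c(3, 23))
  expect_equal(st$star_span, c(40, 60))
  expect_true(st$canonical)
  # in-loop mature rejected
  expect_error(infer_star(f, c(20, 40)), "loop")
  # star of the star is the mature (involution)
  expect_equal(infer_star(f, st$star_span)$star_span, c(3, 23))
})

test_that("star inference recovers every planted star on canonical hairpins", {
  withr::with_seed(77, {
    ok <- 0
    for (k in 1:20) {
      L <- sample(20:22, 1)
      m <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
      hp <- build_hairpin(m, loop_length = sample(8:14, 1),
                          arm_padding = sample(2:6, 1),
                          arm = sample(c("5p", "3p"), 1))
      f <- fold_hairpin(hp$precursor)
      st <- infer_star(f, hp$mature_span)
      if (identical(st$star_span, hp$star_span) && st$canonical) ok <- ok + 1
    }
    expect_equal(ok, 20)
  })
})

test_that("additional duplexes classify tandem, phased and overlapping layouts", {
  # long perfect stem: arm 90 nt, loop 10 -> explicit partner table
  withr::with_seed(88, {
    arm <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                 collapse = "")
  })
  pre <- paste0(arm, strrep("A", 5), strrep("C", 5), dna_revcomp(arm))
  f <- fold_hairpin(pre)
  expect_true(f$hairpin)
  primary <- c(3, 23)
  st1 <- infer_star(f, primary)
  mk <- function(span) substr(pre, span[1], span[2])
  case <- function(second_start) {
    second <- c(second_start, second_start + 20)
    tabs <- list(L = fake_tag_table(
      c(mk(primary), mk(st1$star_span), mk(second)), c(500, 100, 400)))
    detect_additional_duplexes(pre, f, tabs, primary,
                               primary_star_span = st1$star_span,
                               abundance_min = 10)
  }
  tandem <- case(24)   # gap 0
  expect_equal(tandem$phase_class, "tandem")
  phased <- case(45)   # gap 45 - 23 - 1 = 21
  expect_equal(phased$phase_class, "phased(21)")
  unph <- case(40)     # gap 16
  expect_equal(unph$phase_class, "unphased(16)")
})

test_that("overlapping second duplexes report the overlapped length", {
  withr::with_seed(89, {
    arm <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                 collapse = "")
  })
  pre <- paste0(arm, strrep("A", 5), strrep("C", 5), dna_revcomp(arm))
  f <- fold_hairpin(pre)
  primary <- c(3, 23)
  st1 <- infer_star(f, primary)
  second <- c(11, 31)  # gap = 11 - 23 - 1 = -13 -> 13-bp overlap
  mk <- function(span) substr(pre, span[1], span[2])
  tabs <- list(L = fake_tag_table(c(mk(primary), mk(second)), c(500, 400)))
  res <- detect_additional_duplexes(pre, f, tabs, primary,
                                    primary_star_span = st1$star_span,
                                    abundance_min = 10)
  expect_equal(res$phase_class, "overlapping(13)")
})

test_that("antisense pairs require opposite strands and reciprocal overlap", {
  loci <- tibble::tibble(
    locus_id = c("A", "B", "C", "D"),
    chrom = "chr1",
    start = c(100, 100, 500, 590),
    end = c(200, 200, 620, 680),
    strand = c("+", "-", "+", "-"))
  res <- detect_antisense(loci)
  expect_equal(nrow(res), 1)  # A-B full overlap; C-D overlap < 50%
  expect_setequal(c(res$locus_1, res$locus_2), c("A", "B"))
  same <- loci; same$strand <- "+"
  expect_equal(nrow(detect_antisense(same)), 0)
})
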