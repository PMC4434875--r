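test_that("duplex scoring follows the penalty table", {
  m <- "ACGTACGTACGTACGTACGTA"  # 21 nt
  perfect <- dna_revcomp(m)
  expect_equal(score_duplex(m, perfect)$score, 0)
  expect_equal(score_duplex(m, perfect)$alignment, strrep("|", 21))

  # single mismatch at miRNA position 15 (outside 2-13): +1
  s15 <- perfect
  # miRNA position 15 holds G and faces site position 21 - 15 + 1 = 7;
  # replace the complementary C with A (G:A mismatch, not a wobble)
  stopifnot(substr(m, 15, 15) == "G")
  substr(s15, 7, 7) <- "A"
  expect_equal(score_duplex(m, s15)$score, 1)

  # G:U wobble at position 5 (inside 2-13): 0.5 doubled = 1
  # miRNA position 5 is A; make the site base G? A:G is a mismatch - use a
  # miRNA position holding T so the site can offer G (T:G wobble)
  m2 <- m
  expect_equal(substr(m2, 5, 5), "A")
  substr(m2, 5, 5) <- "T"
  s5 <- dna_revcomp(m2)
  substr(s5, 21 - 5 + 1, 21 - 5 + 1) <- "G"  # faces the T at position 5
  sc <- score_duplex(m2, s5)
  expect_equal(sc$score, 1)
  expect_equal(substr(sc$alignment, 5, 5), "o")

  # mismatch inside the doubled region costs 2
  s3 <- perfect
  stopifnot(substr(m, 3, 3) == "G")
  substr(s3, 21 - 3 + 1, 21 - 3 + 1) <- "A"  # G:A mismatch at position 3
  expect_equal(score_duplex(m, s3)$score, 2)
  expect_error(score_duplex(m, "ACGT"), "length")
  expect_error(score_duplex("ACN", "ACG"), "outside")
})

test_that("per-position penalties are strand-symmetric", {
  # pen(a, b) = pen(b, a) for every base combination
  pm <- srnatlas:::.target_penalty_matrix()
  expect_equal(pm, t(pm))
})

test_that("the scanner matches the brute-force all-window scorer", {
  withr::with_seed(404, {
    tx <- setNames(rand_seq(3, 300), paste0("tx", 1:3))
    mi <- setNames(rand_seq(2, 21), paste0("mi", 1:2))
  })
  # plant a perfect site and a 1-mismatch site
  site <- dna_revcomp(mi[[1]])
  substr(tx[[1]], 50, 70) <- site
  near <- site; substr(near, 18, 18) <- "A"
  substr(tx[[2]], 100, 120) <- near
  hits <- scan_targets(mi, tx, compute_cutoff = 40, report_cutoff = 40)
  for (t in names(tx)) for (mm in names(mi)) {
    want <- oracle_scan(mi[[mm]], tx[[t]], 40)
    got <- hits[hits$mirna_id == mm & hits$transcript_id == t, ]
    got <- got[order(got$site_start), ]
    expect_equal(got$site_start, want$start, label = paste(mm, t))
    expect_equal(got$score, want$score, label = paste(mm, t))
  }
})

test_that("cutoffs separate reported from internal hits at the 3/3.5 boundary", {
  m <- "ACGTACGTACGTACGTACGTA"
  perfect <- dna_revcomp(m)
  # three mismatches outside 2-13: positions 15, 16, 17 -> score 3.0
  s3.0 <- perfect
  for (p in 21 - c(15, 16, 17) + 1) {
    b <- substr(s3.0, p, p)
    substr(s3.0, p, p) <- c(A = "C", C = "A", G = "A", T = "C")[[b]]
  }
  stopifnot(score_duplex(m, s3.0)$score == 3)
  # 3.5: add a wobble outside the doubled region (position 20, miRNA base T)
  s3.5 <- s3.0
  p20 <- 21 - 20 + 1
  stopifnot(substr(m, 20, 20) == "T")
  substr(s3.5, p20, p20) <- "G"
  stopifnot(score_duplex(m, s3.5)$score == 3.5)
  tx <- c(keep = paste0("AAAA", s3.0, "AAAA"),
          drop = paste0("AAAA", s3.5, "AAAA"))
  hits <- scan_targets(c(mi = m), tx)
  expect_true("keep" %in% hits$transcript_id)
  expect_false("drop" %in% hits$transcript_id)
  # identical site in two transcripts -> two hits in deterministic order
  tx2 <- c(a = tx[["keep"]], b = tx[["keep"]])
  h2 <- scan_targets(c(mi = m), tx2)
  expect_equal(h2$transcript_id, c("a", "b"))
})

test_that("planted target sites are recovered at their designed score", {
  s <- small_sim()
  mr <- generate_mrna_atlas(s$truth, seed = 7)
  tx <- setNames(mr$transcripts$sequence, mr$transcripts$transcript_id)
  planted <- mr$transcripts[!is.na(mr$transcripts$mirna_id), ]
  mi <- setNames(
    s$truth$mirna$mature[match(unique(planted$mirna_id),
                               s$truth$mirna$locus_id)],
    unique(planted$mirna_id))
  hits <- scan_targets(mi, tx)
  for (i in seq_len(nrow(planted))) {
    h <- hits[hits$mirna_id == planted$mirna_id[i] &
                hits$transcript_id == planted$transcript_id[i], ]
    expect_true(any(h$site_start == planted$site_start[i] & h$score == 0),
                label = planted$transcript_id[i])
  }
})

test_that("correlation p-values match the t-distribution and cor.test", {
  n <- 24
  # exact r by construction
  r_of <- function(r) {
    x <- seq_len(n)
    z <- as.vector(scale(x))
    y <- r * z + sqrt(1 - r^2) * as.vector(scale(sin(seq_len(n) * 2.3)))
    cbind(x = x, y = y)
  }
  for (r_target in c(-0.9, -0.1, 0.9)) {
    d <- r_of(r_target)
    r <- cor(d[, 1], d[, 2])
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p_oracle <- 2 * pt(-abs(t_stat), df = n - 2)
    ct <- cor.test(d[, 1], d[, 2])
    expect_equal(p_oracle, ct$p.value, tolerance = 1e-10)
  }
})

test_that("the anti-correlation filter enforces sign and significance", {
  n <- 24
  samples <- paste0("s", seq_len(n))
  withr::with_seed(405, {
    base <- 10^rnorm(n, 2, 0.5)
  })
  mk_mat <- function(id, vals, col1) {
    out <- tibble::tibble(!!col1 := id)
    for (i in seq_len(n)) out[[samples[i]]] <- vals[i]
    out
  }
  z <- as.vector(scale(log10(1 + base)))
  strong_neg <- 10^(2 - 0.9 * z) - 1   # r ~ -1 on the transformed scale
  strong_pos <- 10^(2 + 0.9 * z) - 1
  withr::with_seed(406, weak <- 10^rnorm(n, 2, 0.5))
  mirna_mat <- mk_mat("mi1", base, "mirna_id")
  tx_mat <- dplyr::bind_rows(mk_mat("neg", strong_neg, "transcript_id"),
                             mk_mat("pos", strong_pos, "transcript_id"),
                             mk_mat("weak", weak, "transcript_id"))
  hits <- tibble::tibble(mirna_id = "mi1",
                         transcript_id = c("neg", "pos", "weak"))
  res <- correlate_and_filter(hits, mirna_mat, tx_mat)
  expect_true(res$retained[res$transcript_id == "neg"])
  expect_lt(res$p_value[res$transcript_id == "neg"], 1e-8)
  # positive correlation rejected despite tiny p (sign rule)
  expect_false(res$retained[res$transcript_id == "pos"])
  expect_lt(res$p_value[res$transcript_id == "pos"], 1e-8)
  expect_false(res$retained[res$transcript_id == "weak"])
  # fewer than 4 shared samples -> untestable
  small <- mirna_mat[, 1:4]
  res2 <- correlate_and_filter(hits[1, ], small, tx_mat[, 1:4])
  expect_false(res2$testable)
  expect_false(res2$retained)
})
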