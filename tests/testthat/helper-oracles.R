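# Independent oracles used across the suite. These deliberately use naive,
# exhaustive or closed-form computations, never the package's own fast paths.

oracle_pair_weight <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(3)
  if (key %in% c("AT", "TA")) return(2)
  if (key %in% c("GT", "TG")) return(1)
  0
}

# exhaustive maximum-weight nested pairing with a minimum loop constraint
oracle_fold_max <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  memo <- new.env()
  best <- function(i, j) {
    if (j - i <= min_loop) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    # enumerate: j unpaired, or j paired with any k
    b <- best(i, j - 1)
    for (k in i:(j - min_loop - 1)) {
      w <- oracle_pair_weight(ch[k], ch[j])
      if (w == 0) next
      left <- if (k > i) best(i, k - 1) else 0
      inner <- if (k + 1 <= j - 1) best(k + 1, j - 1) else 0
      b <- max(b, left + w + inner)
    }
    memo[[key]] <- b
    b
  }
  if (n < 2) return(0)
  best(1, n)
}

# naive both-strand exact substring occurrence count
oracle_count_hits <- function(tag, chroms) {
  rc <- srnatlas::dna_revcomp(tag)
  count1 <- function(pat, s) {
    n <- 0L
    start <- 1L
    repeat {
      p <- regexpr(pat, substr(s, start, nchar(s)), fixed = TRUE)
      if (p < 0) break
      n <- n + 1L
      start <- start + p
    }
    n
  }
  sum(vapply(chroms, function(s) count1(tag, s) + count1(rc, s), integer(1)))
}

# brute-force all-window target scoring
oracle_scan <- function(mirna, transcript, cutoff) {
  L <- nchar(mirna)
  out <- list()
  if (nchar(transcript) < L) return(data.frame())
  for (s in 1:(nchar(transcript) - L + 1)) {
    site <- substr(transcript, s, s + L - 1)
    sc <- srnatlas::score_duplex(mirna, site)$score
    if (sc <= cutoff) out[[length(out) + 1]] <- data.frame(start = s, score = sc)
  }
  if (length(out) == 0) return(data.frame(start = integer(), score = numeric()))
  do.call(rbind, out)
}

# definition-level organ-specificity oracle
oracle_specificity <- function(calls) {
  ids <- unique(calls$mirna_id)
  res <- lapply(ids, function(id) {
    cc <- calls[calls$mirna_id == id, ]
    usable <- cc[cc$usable, ]
    expressed <- cc[cc$expressed, ]
    cls <- "neither"
    org <- NA_character_
    if (nrow(usable) > 0 && nrow(expressed) > 0 &&
        all(usable$expressed)) {
      cls <- "common"
    } else if (nrow(expressed) > 0 &&
               length(unique(expressed$organ)) == 1) {
      cls <- "organ_specific"
      org <- unique(expressed$organ)
    }
    data.frame(mirna_id = id, class = cls, organ = org,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# adjusted Rand index (closed form over the contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_i * sum_j / comb2(n)
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# enumerate every leaf order consistent with an hclust tree (all subtree
# flips) and return the minimum sum of adjacent distances
oracle_best_leaf_order_cost <- function(hc, d) {
  orders <- function(id) {
    if (id < 0) return(list(-id))
    a <- orders(hc$merge[id, 1])
    b <- orders(hc$merge[id, 2])
    out <- list()
    for (x in a) for (y in b) {
      out[[length(out) + 1]] <- c(x, y)
      out[[length(out) + 1]] <- c(y, x)
    }
    out
  }
  all_orders <- orders(nrow(hc$merge))
  min(vapply(all_orders, function(o) {
    sum(d[cbind(o[-length(o)], o[-1])])
  }, numeric(1)))
}

# small simulated dataset reused by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genome_length = 30000, n_mirna_loci = 8,
                        n_sirna_clusters = 3, n_structural_decoys = 2,
                        organs = c("bud", "leaf", "berry"),
                        reads_per_library = 30000, n_target_pairs = 4,
                        seed = 11)
      truth <- plant_genome(cfg)
      libs <- simulate_libraries(cfg, truth)
      tabs <- preprocess_libraries(libs, truth)
      cache <<- list(cfg = cfg, truth = truth, libs = libs, tabs = tabs)
    }
    cache
  }
})

# hand-built normalized tag table (counts become TP5M against their own sum)
fake_tag_table <- function(seqs, counts, library_id = "lib") {
  tab <- tibble::tibble(sequence = seqs, count = as.integer(counts),
                        hits = 1L, structural = FALSE)
  tab$tp5m <- tab$count * 5e6 / sum(tab$count)
  srnatlas:::new_tag_table(tab, library_id = library_id,
                           totals = list(denominator = sum(tab$count)))
}

rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
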