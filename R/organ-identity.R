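#' Log-transform an abundance matrix and compute correlation distances
#'
#' Abundances are mapped through `log10(1 + x)` - chosen so a value of zero
#' transforms to exactly zero - and sample profiles are compared with the
#' one-minus-Pearson distance over all miRNAs in the matrix. Distances are
#' invariant to positive affine transforms of a profile; a constant
#' (zero-variance) profile has undefined distances, reported as `NA` with
#' the offending pairs listed.
#'
#' @param mat wide abundance tibble (`mirna_id` + sample or library
#'   columns), nonnegative.
#' @return list of class `srna_dist`: `distance` (symmetric matrix, 0
#'   diagonal, values in \[0, 2\]), `transformed` (wide tibble of
#'   log10(1 + x) values), `missing_pairs` (tibble of undefined pairs).
#' @export
transform_and_distance <- function(mat) {
  samples <- setdiff(names(mat), "mirna_id")
  m <- as.matrix(mat[, samples, drop = FALSE])
  if (any(m < 0, na.rm = TRUE)) abort("abundances must be nonnegative")
  tm <- log10(1 + m)
  r <- suppressWarnings(cor(tm))
  d <- 1 - r
  diag(d) <- 0
  dimnames(d) <- list(samples, samples)
  miss <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  missing_pairs <- tibble(
    sample_1 = samples[miss[, 1]],
    sample_2 = samples[miss[, 2]]
  )
  transformed <- bind_cols(tibble(mirna_id = mat$mirna_id),
                           as_tibble(tm))
  structure(list(distance = d, transformed = transformed,
                 missing_pairs = missing_pairs),
            class = "srna_dist")
}

#' Cluster samples by average linkage with optimal leaf ordering
#'
#' Agglomerative hierarchical clustering (average linkage by default) of a
#' sample distance matrix, followed by exact optimal leaf ordering: among
#' all leaf orders consistent with the tree (subtree flips), the one
#' minimizing the sum of adjacent-leaf distances is found by dynamic
#' programming. The exact search is used up to 64 leaves; beyond that the
#' hclust order is kept unchanged.
#'
#' @param dist an `srna_dist` from [transform_and_distance()], or a square
#'   symmetric distance matrix with dimnames.
#' @param linkage linkage method passed to [stats::hclust()]
#'   (default "average").
#' @param leaf_order "optimal" (default) or "none".
#' @return an `hclust` object (class `c("srna_dendro", "hclust")`) with
#'   `$order` optimized; attribute `adjacent_cost` holds the ordered sum of
#'   adjacent-leaf distances.
#' @export
cluster_samples <- function(dist, linkage = "average",
                            leaf_order = c("optimal", "none")) {
  leaf_order <- match.arg(leaf_order)
  d <- if (inherits(dist, "srna_dist")) dist$distance else dist
  if (anyNA(d)) {
    miss <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    abort(paste0("distance matrix has missing pairs: ",
                 paste(sprintf("%s-%s", rownames(d)[miss[, 1]],
                               colnames(d)[miss[, 2]]), collapse = ", ")))
  }
  hc <- hclust(as.dist(d), method = linkage)
  if (leaf_order == "optimal" && nrow(d) >= 3 && nrow(d) <= 64) {
    hc$order <- optimal_leaf_order(hc$merge, d)
  }
  ord <- hc$order
  attr(hc, "adjacent_cost") <- sum(d[cbind(ord[-length(ord)], ord[-1])])
  class(hc) <- c("srna_dendro", "hclust")
  hc
}

# exact optimal leaf ordering (dynamic programming over subtree flips)
#' @keywords internal
optimal_leaf_order <- function(merge, d) {
  n <- nrow(d)
  node <- function(id) {
    if (id < 0) {
      leaf <- -id
      M <- matrix(Inf, n, n)
      M[leaf, leaf] <- 0
      return(list(leaves = leaf, M = M, kind = "leaf"))
    }
    A <- node(merge[id, 1])
    B <- node(merge[id, 2])
    leaves <- c(A$leaves, B$leaves)
    M <- matrix(Inf, n, n)
    bm <- matrix(NA_integer_, n, n)
    bk <- matrix(NA_integer_, n, n)
    left_is_A <- matrix(NA, n, n)
    fill <- function(L, R, a_left) {
      for (u in L$leaves) {
        for (k in R$leaves) {
          # best inner boundary m of the left block ending the block
          best <- Inf; bestm <- NA_integer_
          for (m in L$leaves) {
            v <- L$M[u, m] + d[m, k]
            if (v < best) { best <- v; bestm <- m }
          }
          for (w in R$leaves) {
            v <- best + R$M[k, w]
            if (v < M[u, w]) {
              M[u, w] <<- v
              bm[u, w] <<- bestm
              bk[u, w] <<- k
              left_is_A[u, w] <<- a_left
            }
          }
        }
      }
    }
    fill(A, B, TRUE)
    fill(B, A, FALSE)
    list(leaves = leaves, M = M, bm = bm, bk = bk,
         left_is_A = left_is_A, A = A, B = B, kind = "internal")
  }
  root <- node(nrow(merge))
  # best (u, w) at root
  best <- Inf; bu <- NA; bw <- NA
  for (u in root$leaves) for (w in root$leaves) {
    if (root$M[u, w] < best) { best <- root$M[u, w]; bu <- u; bw <- w }
  }
  rebuild <- function(v, u, w) {
    if (v$kind == "leaf") return(u)
    L <- if (v$left_is_A[u, w]) v$A else v$B
    R <- if (v$left_is_A[u, w]) v$B else v$A
    c(rebuild(L, u, v$bm[u, w]), rebuild(R, v$bk[u, w], w))
  }
  rebuild(root, bu, bw)
}

#' Export a dendrogram as a Newick tree with branch lengths
#'
#' @param hc an `hclust` / `srna_dendro` object.
#' @param file optional path; when NULL the Newick string is returned.
#' @return the Newick string (invisibly when written to file).
#' @export
export_newick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(hc))
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Principal component analysis of sample profiles
#'
#' Features (miRNAs) are z-scored to mean 0 and unit variance before the
#' decomposition; zero-variance features are dropped (and recorded).
#' Component signs are fixed by making each component's largest-magnitude
#' loading positive, and variance fractions sum to 1.
#'
#' @param mat wide abundance tibble (`mirna_id` + sample columns), >= 2
#'   samples and >= 2 features with nonzero variance.
#' @param transform apply log10(1 + x) before z-scoring (default TRUE,
#'   matching the distance analysis).
#' @return list of class `srna_pca`: `scores` (tibble sample x PC),
#'   `loadings` (tibble mirna_id x PC), `variance_fraction` (numeric),
#'   `dropped_features` (character).
#' @export
pca_samples <- function(mat, transform = TRUE) {
  samples <- setdiff(names(mat), "mirna_id")
  if (length(samples) < 2) abort("need >= 2 samples")
  m <- as.matrix(mat[, samples, drop = FALSE])
  rownames(m) <- mat$mirna_id
  if (transform) m <- log10(1 + m)
  x <- t(m)  # samples x features
  v <- apply(x, 2, sd)
  dropped <- colnames(x)[v == 0 | is.na(v)]
  x <- x[, v > 0 & !is.na(v), drop = FALSE]
  if (ncol(x) < 2) abort("need >= 2 features with nonzero variance")
  z <- scale(x)
  p <- prcomp(z, center = FALSE, scale. = FALSE)
  # deterministic sign: largest-|loading| positive
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(
      scores = bind_cols(tibble(sample = rownames(p$x)), as_tibble(p$x)),
      loadings = bind_cols(tibble(mirna_id = rownames(p$rotation)),
                           as_tibble(p$rotation)),
      variance_fraction = vf,
      dropped_features = dropped
    ),
    class = "srna_pca"
  )
}

#' @export
print.srna_pca <- function(x, ...) {
  cat(sprintf("<srna_pca> %d samples, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), length(x$variance_fraction),
              100 * x$variance_fraction[1],
              100 * (x$variance_fraction[2] %||% NA_real_)))
  invisible(x)
}
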