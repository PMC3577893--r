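#' F-linkage threshold clustering
#'
#' Deterministic agglomerative clustering controlled by a dissimilarity
#' threshold `t` and a cluster-shape factor `F`.  Two elements are *linked*
#' when their dissimilarity is at most `t`.  Starting from singletons, a
#' cluster pair (A, B) is mergeable when the fraction
#' `f = linked cross-pairs / (|A| * |B|)` satisfies `f >= F` and `f > 0`
#' (so `F = 0` still demands at least one link).  The mergeable pair with
#' the largest `f` is merged first; ties are broken by the smaller maximal
#' cross-distance, then the smaller mean cross-distance, then the
#' lexicographically smallest member ids.  `F = 0` reproduces single
#' linkage (connected components of the link graph) and `F = 1` complete
#' linkage (every internal pair linked; the maximal-cross-distance
#' tie-break makes the schedule coincide with the complete-linkage
#' dendrogram cut, so cluster counts are non-increasing in the threshold),
#' with intermediate values interpolating the cluster shape between the
#' two.
#'
#' @param d A `"distmat"` (see [as_distmat()]).
#' @param threshold Dissimilarity threshold `t` as a fraction in `[0, 1]`
#'   (a percentage threshold is divided by 100 at the caller's side).
#' @param F Cluster-shape factor in `[0, 1]`.
#' @return A named character vector mapping element ids to cluster labels.
#'   Clusters are labelled `"C1"`, `"C2"`, ... in order of their
#'   lexicographically smallest member, so labels are stable under
#'   re-serialization.
#' @export
f_linkage_cluster <- function(d, threshold, F = 0.5) {
  d <- as_distmat(d)
  stopifnot(threshold >= 0, threshold <= 1, F >= 0, F <= 1)
  ids <- rownames(d)
  n <- length(ids)
  dm <- unclass(d)
  link <- (dm <= threshold) * 1
  diag(link) <- 0
  # Per-cluster running state; all pairwise quantities merge additively.
  cnt <- link                 # linked cross-pairs between clusters
  dsum <- dm                  # summed cross-distances between clusters
  dmax <- dm                  # maximal cross-distance between clusters
  size <- rep(1L, n)
  minid <- ids                # lexicographically smallest member per cluster
  alive <- rep(TRUE, n)
  parent <- seq_len(n)        # element -> index of its current cluster
  repeat {
    k <- which(alive)
    if (length(k) < 2L) break
    f <- cnt[k, k, drop = FALSE] / outer(size[k], size[k])
    elig <- f >= F & cnt[k, k, drop = FALSE] > 0
    elig[lower.tri(elig, diag = TRUE)] <- FALSE
    if (!any(elig)) break
    idx <- which(elig, arr.ind = TRUE)
    fv <- f[elig]
    meand <- (dsum[k, k, drop = FALSE] / outer(size[k], size[k]))[elig]
    maxd <- dmax[k, k, drop = FALSE][elig]
    id1 <- pmin(minid[k][idx[, 1L]], minid[k][idx[, 2L]])
    id2 <- pmax(minid[k][idx[, 1L]], minid[k][idx[, 2L]])
    best <- order(-fv, maxd, meand, id1, id2)[1L]
    a <- k[min(idx[best, ])]; b <- k[max(idx[best, ])]
    cnt[a, ] <- cnt[a, ] + cnt[b, ]; cnt[, a] <- cnt[, a] + cnt[, b]
    dsum[a, ] <- dsum[a, ] + dsum[b, ]; dsum[, a] <- dsum[, a] + dsum[, b]
    dmax[a, ] <- pmax(dmax[a, ], dmax[b, ]); dmax[, a] <- pmax(dmax[, a], dmax[, b])
    size[a] <- size[a] + size[b]
    minid[a] <- min(minid[a], minid[b])
    cnt[a, a] <- 0; dsum[a, a] <- 0
    alive[b] <- FALSE
    parent[parent == b] <- a
  }
  reps <- minid[parent]
  labs <- sort(unique(reps))
  stats::setNames(paste0("C", match(reps, labs)), ids)
}

#' Partition-agreement indices over (partially) labelled references
#'
#' Agreement between a computed partition and a reference partition,
#' evaluated over pairs of labelled elements only: unlabelled elements are
#' ignored entirely, so a partial reference (e.g. only the database
#' sequences carrying full species names) imposes no penalty.  Three
#' pair-counting indices are available: the plain Rand index
#' `(a + b) / C(n, 2)`; the Hubert-Arabie adjusted Rand index; and the
#' modified Rand index `MRI = 2 * Rand - 1` (range `[-1, 1]`), whose
#' theoretical maximum 1.0 is attained exactly when the restricted
#' partitions coincide.
#'
#' @param p Named character vector: the computed partition.
#' @param reference Named character vector over the labelled subset (labels
#'   are species names or any cluster ids).
#' @param metric One of `"modified_rand"` (default), `"rand"`,
#'   `"adjusted_rand"`.
#' @return A single numeric agreement value.
#' @export
rand_family <- function(p, reference,
                        metric = c("modified_rand", "rand", "adjusted_rand")) {
  metric <- match.arg(metric)
  common <- intersect(names(reference), names(p))
  if (length(common) < 2L)
    stop("need at least two labelled elements present in the partition")
  x <- factor(p[common]); y <- factor(reference[common])
  n <- length(common)
  ct <- table(x, y)
  sum_ij <- sum(choose(ct, 2))
  sum_i <- sum(choose(rowSums(ct), 2))
  sum_j <- sum(choose(colSums(ct), 2))
  total <- choose(n, 2)
  a <- sum_ij                                  # together in both
  b <- total - sum_i - sum_j + sum_ij          # apart in both
  rand <- (a + b) / total
  switch(metric,
    rand = rand,
    modified_rand = 2 * rand - 1,
    adjusted_rand = {
      expected <- sum_i * sum_j / total
      maxi <- (sum_i + sum_j) / 2
      if (maxi == expected) 1 else (sum_ij - expected) / (maxi - expected)
    })
}

#' Number of clusters in a partition
#' @param p Named character vector partition.
#' @return Integer.
#' @export
n_clusters <- function(p) length(unique(unname(p)))
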