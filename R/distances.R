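#' Validate / construct a symmetric dissimilarity matrix
#'
#' @param d Square numeric matrix of dissimilarities in `[0, 1]` with
#'   identical row and column names (the element ids).
#' @return The matrix, validated, with class `"distmat"` prepended.
#' @export
as_distmat <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix needs identical row and column names")
  if (any(!is.finite(d))) stop("distance matrix contains non-finite values")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  diag(d) <- 0
  d <- (d + t(d)) / 2
  class(d) <- c("distmat", class(d))
  d
}

#' Smith-Waterman percent similarity between two sequences
#'
#' Optimal local alignment under affine gap costs; the similarity is
#' `100 * identities / alignment columns` (gap columns included), the
#' convention of the EMBOSS `water` tool.  Gap characters are stripped
#' before alignment.  Default scoring is EDNAFULL-like: match +5,
#' mismatch -4, gap open 10, gap extend 0.5.
#'
#' @param a,b Residue strings (or length-1 named character vectors).
#' @param match,mismatch Match score and mismatch penalty (penalty given as
#'   a negative score).
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return A one-row data.frame: `query`, `subject`, `percent_similarity`,
#'   `score` (the raw optimal local-alignment score).
#' @export
sw_similarity <- function(a, b, match = 5, mismatch = -4,
                          gap_open = 10, gap_extend = 0.5) {
  qa <- gsub("[-?]", "", toupper(a[[1L]]))
  qb <- gsub("[-?]", "", toupper(b[[1L]]))
  if (!nzchar(qa) || !nzchar(qb)) stop("cannot align an empty sequence")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(qa, qb, type = "local",
                                       substitutionMatrix = sub,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  pct <- Biostrings::pid(aln, type = "PID1")
  data.frame(query = if (!is.null(names(a))) names(a)[1L] else "query",
             subject = if (!is.null(names(b))) names(b)[1L] else "subject",
             percent_similarity = pct,
             score = Biostrings::score(aln))
}

#' Uncorrected pairwise distance matrix from an alignment
#'
#' p-distance with pairwise deletion: `d(i, j)` is the proportion of
#' mismatching sites among columns where both sequences carry an unambiguous
#' base (gaps, `?` and ambiguity codes are excluded per pair).  A pair with
#' no shared sites is an error, since its distance is undefined.
#'
#' @param msa An `"msa"` object.
#' @return A `"distmat"` of fractional dissimilarities.
#' @export
p_distance_matrix <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  seqs <- gsub("[^ACGT]", "n", unclass(msa))
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  names(bin) <- names(msa)
  d <- as.matrix(ape::dist.dna(ape::as.matrix.DNAbin(bin), model = "raw",
                               pairwise.deletion = TRUE))
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1L, ]
    stop("no shared non-gap columns between ", rownames(d)[bad[1L]],
         " and ", colnames(d)[bad[2L]])
  }
  as_distmat(d)
}

#' Filter alignment members by non-gap overlap with a target set
#'
#' Retains every target plus every other record whose number of columns that
#' are simultaneously non-gap in it and in at least one target reaches
#' `min_overlap`.  This reduces a heterogeneous rDNA alignment to a core set
#' comparable with the targets.  With `informative_only = TRUE` only
#' variable alignment columns are counted as informative overlap, the
#' alternative reading of "informative sites".
#'
#' @param msa An `"msa"` object.
#' @param target_ids Ids of the target (anchor) records.
#' @param min_overlap Minimum number of overlap sites (> 0).
#' @param informative_only Count only columns with >= 2 distinct bases over
#'   the whole alignment?
#' @return The filtered `"msa"`; the retained ids additionally carry the
#'   per-record overlap counts in attribute `"overlap"`.
#' @seealso [overlap_table()] for retained-size-versus-threshold tables.
#' @export
overlap_filter <- function(msa, target_ids, min_overlap,
                           informative_only = FALSE) {
  stopifnot(inherits(msa, "msa"))
  if (!all(target_ids %in% names(msa)))
    stop("target ids absent from alignment: ",
         paste(setdiff(target_ids, names(msa)), collapse = ", "))
  if (min_overlap <= 0) stop("min_overlap must be positive")
  ov <- overlap_counts(msa, target_ids, informative_only)
  keep <- names(msa) %in% target_ids | ov >= min_overlap
  out <- as_msa(unclass(msa)[keep])
  attr(out, "overlap") <- ov[keep]
  out
}

overlap_counts <- function(msa, target_ids, informative_only = FALSE) {
  chars <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(chars) <- names(msa)
  nongap <- !(chars %in% c("-", "?"))
  dim(nongap) <- dim(chars); dimnames(nongap) <- dimnames(chars)
  cols <- rep(TRUE, ncol(chars))
  if (informative_only) {
    cols <- apply(chars, 2L, function(col) {
      b <- col[!(col %in% c("-", "?"))]
      length(unique(b)) >= 2L
    })
  }
  tgt_cov <- colSums(nongap[target_ids, , drop = FALSE]) > 0L
  use <- cols & tgt_cov
  stats::setNames(as.integer(nongap[, use, drop = FALSE] %*% rep(1L, sum(use))),
                  names(msa))
}

#' Retained alignment size as a function of the overlap threshold
#'
#' @inheritParams overlap_filter
#' @param thresholds Integer vector of overlap thresholds.
#' @return data.frame with columns `min_overlap` and `retained`.
#' @export
overlap_table <- function(msa, target_ids, thresholds,
                          informative_only = FALSE) {
  ov <- overlap_counts(msa, target_ids, informative_only)
  is_target <- names(msa) %in% target_ids
  data.frame(min_overlap = as.integer(thresholds),
             retained = vapply(thresholds, function(th)
               sum(is_target | ov >= th), integer(1)))
}

#' Screen sequence sets against per-host representative sequences
#'
#' Cross-compares every member sequence of each host's set against that
#' host's designated representative by Smith-Waterman percent similarity,
#' the screening used to justify reducing each host to a single
#' representative sequence.
#'
#' @param groups Named list (host -> named character vector of member
#'   sequences).
#' @param representatives Named character vector or named list
#'   (host -> representative sequence).
#' @param categories Optional named character vector mapping member ids to a
#'   source category (e.g. culture / nodule / gut-specific / gut-clone).
#' @param ... Scoring parameters passed to [sw_similarity()].
#' @return data.frame with columns `host`, `member`, `category`,
#'   `percent_similarity`; per-host and per-category min/max summaries in
#'   attribute `"summary"` (also available via `summary()` on the result of
#'   `[screen_representatives()]`).
#' @export
screen_representatives <- function(groups, representatives, categories = NULL,
                                   ...) {
  missing_rep <- setdiff(names(groups), names(representatives))
  if (length(missing_rep))
    stop("host(s) without representative: ", paste(missing_rep, collapse = ", "))
  rows <- list()
  for (h in names(groups)) {
    members <- groups[[h]]
    if (!length(members)) {
      warning("host ", h, " has no member sequences")
      next
    }
    rep_seq <- stats::setNames(representatives[[h]], paste0(h, "_rep"))
    for (i in seq_along(members)) {
      r <- sw_similarity(stats::setNames(members[i], names(members)[i]),
                         rep_seq, ...)
      rows[[length(rows) + 1L]] <-
        data.frame(host = h, member = names(members)[i],
                   category = if (!is.null(categories))
                     unname(categories[names(members)[i]]) else NA_character_,
                   percent_similarity = r$percent_similarity)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(host = character(), member = character(),
                         category = character(), percent_similarity = numeric())
  summ <- function(key) {
    if (!nrow(out) || all(is.na(out[[key]]))) return(NULL)
    sp <- split(out$percent_similarity, out[[key]])
    data.frame(group = names(sp),
               min = vapply(sp, min, numeric(1)),
               max = vapply(sp, max, numeric(1)), row.names = NULL)
  }
  attr(out, "summary") <- list(by_host = summ("host"),
                               by_category = summ("category"))
  out
}

#' Write / read a square distance matrix as TSV
#'
#' @param d A `"distmat"` (write) or a TSV path (read).
#' @param path Output path.
#' @return `read_distmat()` returns a `"distmat"`; `write_distmat()` returns
#'   `path` invisibly.
#' @export
write_distmat <- function(d, path) {
  utils::write.table(as.matrix(unclass(d)), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_distmat
#' @export
read_distmat <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  as_distmat(m)
}
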