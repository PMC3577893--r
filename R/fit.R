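#' Fit threshold-clustering parameters against a reference partition
#'
#' Scans a grid of cluster-shape factors `F` and dissimilarity thresholds
#' `t`, clusters the distance matrix with [f_linkage_cluster()] at every
#' combination, and scores the agreement of the result with a (possibly
#' partial) reference partition using a pair-counting index (default:
#' modified Rand index).  For each `F` the maximal agreement and the set of
#' thresholds attaining it (with min / max / median) are reported; the
#' per-`F` median optimal threshold is the canonical fitted value used for
#' downstream clustering, identification and coverage analyses.
#'
#' @param d A `"distmat"` covering at least the labelled elements.
#' @param reference Named character vector over the labelled subset
#'   (element id -> species/cluster label); at least two labelled elements
#'   must be present in `d`.
#' @param F_grid Numeric vector of `F` values (default `c(0, 0.5, 1)`, the
#'   three representative cluster shapes).
#' @param t_grid Numeric vector of thresholds, or `NULL` to scan `0` to
#'   `max(d)` in steps of `t_step`.
#' @param t_step Grid step used when `t_grid` is `NULL`; the default 0.0005
#'   (0.05 percentage points) matches the resolution at which optimal
#'   thresholds are conventionally reported.
#' @param metric Agreement metric, see [rand_family()].
#' @return An object of class `"threshold_fit"`: list with `grid`
#'   (data.frame `F`, `t`, `agreement`), `optima` (per-`F` data.frame with
#'   `F`, `agreement`, `t_min`, `t_max`, `t_median`, `n_optimal`), and the
#'   inputs (`d`, `reference`, `metric`, `call`).
#' @examples
#' sim <- simulate_dataset(synth_config(n_species = 3, seqs_per_species = 3,
#'                                      seed = 7))
#' d <- p_distance_matrix(sim$msa)
#' fit <- fit_thresholds(d, sim$truth$species)
#' coef(fit)
#' @export
fit_thresholds <- function(d, reference, F_grid = c(0, 0.5, 1),
                           t_grid = NULL, t_step = 0.0005,
                           metric = c("modified_rand", "rand",
                                      "adjusted_rand")) {
  d <- as_distmat(d)
  metric <- match.arg(metric)
  if (!length(F_grid)) stop("F_grid must be non-empty")
  if (is.null(t_grid)) t_grid <- seq(0, max(d), by = t_step)
  if (!length(t_grid)) stop("t_grid must be non-empty")
  if (length(intersect(names(reference), rownames(d))) < 2L)
    stop("reference must label at least two elements of the distance matrix")
  grid <- expand.grid(t = sort(unique(t_grid)), F = sort(unique(F_grid)),
                      KEEP.OUT.ATTRS = FALSE)[, c("F", "t")]
  grid$agreement <- mapply(function(F, t) {
    rand_family(f_linkage_cluster(d, t, F), reference, metric)
  }, grid$F, grid$t)
  optima <- do.call(rbind, lapply(split(grid, grid$F), function(g) {
    best <- max(g$agreement)
    ts <- g$t[g$agreement == best]
    data.frame(F = g$F[1L], agreement = best, t_min = min(ts),
               t_max = max(ts), t_median = stats::median(ts),
               n_optimal = length(ts))
  }))
  rownames(optima) <- NULL
  structure(list(grid = grid, optima = optima, d = d, reference = reference,
                 metric = metric, call = match.call()),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("Threshold-clustering fit (", x$metric, " agreement, ",
      length(intersect(names(x$reference), rownames(x$d))),
      " labelled of ", nrow(x$d), " elements)\n\n", sep = "")
  print(format(x$optima, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
summary.threshold_fit <- function(object, ...) {
  structure(list(optima = object$optima, metric = object$metric,
                 n = nrow(object$d),
                 n_labelled = length(intersect(names(object$reference),
                                               rownames(object$d))),
                 grid_size = nrow(object$grid)),
            class = "summary.threshold_fit")
}

#' @export
print.summary.threshold_fit <- function(x, ...) {
  cat("Threshold-clustering parameter fit\n")
  cat("  elements:", x$n, "(", x$n_labelled, "labelled )\n")
  cat("  grid evaluations:", x$grid_size, " metric:", x$metric, "\n")
  print(format(x$optima, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @describeIn fit_thresholds Median optimal threshold per `F`, as a named
#'   numeric vector.
#' @param object,... S3 method arguments.
#' @export
coef.threshold_fit <- function(object, ...) {
  stats::setNames(object$optima$t_median, paste0("F=", object$optima$F))
}

#' Plot agreement curves of a threshold fit
#'
#' Agreement as a function of the dissimilarity threshold, one curve per
#' `F` value (grey-to-black ramp), the standard clustering-optimization
#' plot.
#'
#' @param x A `"threshold_fit"`.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @export
plot.threshold_fit <- function(x, ...) {
  tg <- sort(unique(x$grid$t))
  Fs <- sort(unique(x$grid$F))
  m <- sapply(Fs, function(F)
    x$grid$agreement[x$grid$F == F][order(x$grid$t[x$grid$F == F])])
  cols <- grDevices::gray(seq(0.7, 0, length.out = length(Fs)))
  graphics::matplot(tg * 100, m, type = "l", lty = 1, col = cols,
                    xlab = "dissimilarity threshold [%]",
                    ylab = paste(x$metric, "agreement"), ...)
  graphics::legend("bottomright", legend = paste("F =", Fs), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Identify query sequences by cluster co-membership
#'
#' Clusters references and queries together and labels every query by the
#' reference labels found in its cluster: a single label is an
#' identification, several distinct labels are reported as ambiguous, and a
#' cluster containing no labelled reference marks the query as `NOVEL`
#' (a taxon not yet represented among the references).
#'
#' @param d A `"distmat"` covering references and queries.
#' @param reference Named character vector over the labelled references;
#'   query ids must not appear in it.
#' @param threshold,F Clustering parameters (see [f_linkage_cluster()]).
#' @param query_ids Ids to report on; defaults to all elements of `d`
#'   absent from `reference`.
#' @return data.frame with columns `query`, `cluster`, `labels`
#'   (`;`-collapsed reference labels in the query's cluster), `status`
#'   (`identified` / `ambiguous` / `NOVEL`).
#' @export
identify_queries <- function(d, reference, threshold, F = 0.5,
                             query_ids = NULL) {
  d <- as_distmat(d)
  if (is.null(query_ids)) query_ids <- setdiff(rownames(d), names(reference))
  if (length(intersect(query_ids, names(reference))))
    stop("query ids overlap the labelled reference set")
  p <- f_linkage_cluster(d, threshold, F)
  out <- lapply(query_ids, function(q) {
    cl <- p[[q]]
    mates <- names(p)[p == cl]
    labs <- sort(unique(unname(reference[intersect(mates, names(reference))])))
    data.frame(query = q, cluster = cl,
               labels = paste(labs, collapse = ";"),
               status = if (!length(labs)) "NOVEL"
                        else if (length(labs) == 1L) "identified"
                        else "ambiguous")
  })
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(query = character(), cluster = character(),
                         labels = character(), status = character())
  attr(res, "partition") <- p
  res
}

#' @describeIn fit_thresholds Identify queries using the fitted median
#'   optimal threshold for a chosen `F` (see [identify_queries()]).
#' @param newdata A `"distmat"` covering references and queries (defaults
#'   to the fitted matrix).
#' @param F Which fitted `F` value to use (defaults to the first of the
#'   fitted grid).
#' @export
predict.threshold_fit <- function(object, newdata = NULL, F = NULL, ...) {
  if (is.null(newdata)) newdata <- object$d
  if (is.null(F)) F <- object$optima$F[1L]
  row <- match(F, object$optima$F)
  if (is.na(row)) stop("F = ", F, " was not part of the fitted grid")
  identify_queries(newdata, object$reference,
                   threshold = object$optima$t_median[row], F = F)
}
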