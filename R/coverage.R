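# Temporal coverage of OTU discovery and host associations: given one
# clustering of the full sequence set and per-accession deposition years,
# tabulate per evaluation year the cumulative cluster count, mean
# sequences per cluster, mean distinct host genera/species per cluster
# and mean clusters per host genus/species.  Host affiliations are often
# absent from database records, so host-per-cluster means may drop below
# one: clusters with no known host contribute zero.

#' Temporal coverage series for one clustering
#'
#' @param partition Named character vector (accession -> cluster) from
#'   [f_linkage_cluster()].
#' @param meta data.frame with columns `accession`, `host_genus`,
#'   `host_species`, `deposition_year` (as from
#'   [parse_genbank_flatfiles()]); every partition element needs a row,
#'   and elements with missing year are excluded with a warning.
#' @param years Numeric vector of evaluation years; defaults to every
#'   distinct deposition year, sorted.
#' @return data.frame with one row per year: `year`,
#'   `cumulative_clusters`, `mean_sequences_per_cluster`,
#'   `mean_host_genera_per_cluster`, `mean_host_species_per_cluster`,
#'   `mean_clusters_per_host_genus`, `mean_clusters_per_host_species`.
#' @export
coverage_series <- function(partition, meta, years = NULL) {
  miss <- setdiff(names(partition), meta$accession)
  if (length(miss))
    stop("metadata missing for: ", paste(miss, collapse = ", "))
  idx <- match(names(partition), meta$accession)
  year <- meta$deposition_year[idx]
  if (anyNA(year)) {
    warning(sum(is.na(year)), " element(s) without deposition year excluded")
    keep <- !is.na(year)
    partition <- partition[keep]; idx <- idx[keep]; year <- year[keep]
  }
  if (is.null(years)) years <- sort(unique(year))
  if (!length(years)) stop("empty evaluation-year grid")
  genus <- meta$host_genus[idx]
  species <- meta$host_species[idx]
  rows <- lapply(sort(years), function(y) {
    sel <- year <= y
    if (!any(sel))
      return(data.frame(year = y, cumulative_clusters = 0L,
                        mean_sequences_per_cluster = NA_real_,
                        mean_host_genera_per_cluster = NA_real_,
                        mean_host_species_per_cluster = NA_real_,
                        mean_clusters_per_host_genus = NA_real_,
                        mean_clusters_per_host_species = NA_real_))
    cl <- partition[sel]
    clusters <- unique(unname(cl))
    n_distinct_hosts <- function(h) {
      per <- vapply(clusters, function(cc)
        length(unique(stats::na.omit(h[sel][cl == cc]))), integer(1))
      mean(per)
    }
    clusters_per_host <- function(h) {
      hv <- h[sel]
      hosts <- unique(stats::na.omit(hv))
      if (!length(hosts)) return(NA_real_)
      mean(vapply(hosts, function(hh)
        length(unique(unname(cl[!is.na(hv) & hv == hh]))), integer(1)))
    }
    data.frame(year = y,
               cumulative_clusters = length(clusters),
               mean_sequences_per_cluster = sum(sel) / length(clusters),
               mean_host_genera_per_cluster = n_distinct_hosts(genus),
               mean_host_species_per_cluster = n_distinct_hosts(species),
               mean_clusters_per_host_genus = clusters_per_host(genus),
               mean_clusters_per_host_species = clusters_per_host(species))
  })
  do.call(rbind, rows)
}

#' Coverage series over a grid of clustering parameters
#'
#' Clusters the distance matrix at every `(F, t)` combination and computes
#' the coverage series for each, the sensitivity analysis accompanying
#' temporal-trend plots.  By default the full set is clustered once and
#' filtered by year; `recluster_per_year = TRUE` instead re-clusters the
#' cumulative subset available at each evaluation year.
#'
#' @param d A `"distmat"`.
#' @param meta Metadata table, see [coverage_series()].
#' @param params data.frame with columns `F` and `t` (fractions), or a
#'   list of `c(F =, t =)` vectors.  [default_sensitivity_params()] builds
#'   the conventional grid.
#' @param years Evaluation years (default: observed deposition years).
#' @param recluster_per_year Re-cluster each cumulative subset instead of
#'   filtering one clustering?
#' @return Long-format data.frame: `F`, `t`, plus the columns of
#'   [coverage_series()].
#' @export
sensitivity_grid <- function(d, meta, params, years = NULL,
                             recluster_per_year = FALSE) {
  d <- as_distmat(d)
  if (is.list(params) && !is.data.frame(params))
    params <- do.call(rbind, lapply(params, function(p)
      data.frame(F = p[["F"]], t = p[["t"]])))
  if (!nrow(params)) stop("params must be non-empty")
  out <- lapply(seq_len(nrow(params)), function(i) {
    Fv <- params$F[i]; tv <- params$t[i]
    if (!recluster_per_year) {
      p <- f_linkage_cluster(d, tv, Fv)
      cs <- coverage_series(p, meta, years)
    } else {
      idx <- match(rownames(d), meta$accession)
      yr <- meta$deposition_year[idx]
      ys <- if (is.null(years)) sort(unique(yr[!is.na(yr)])) else sort(years)
      cs <- do.call(rbind, lapply(ys, function(y) {
        keep <- rownames(d)[!is.na(yr) & yr <= y]
        if (length(keep) < 2L) {
          p <- stats::setNames(rep("C1", length(keep)), keep)
        } else {
          p <- f_linkage_cluster(as_distmat(unclass(d)[keep, keep]), tv, Fv)
        }
        coverage_series(p, meta, years = y)
      }))
    }
    cbind(F = Fv, t = tv, cs)
  })
  do.call(rbind, out)
}

#' The conventional sensitivity parameter grid
#'
#' Three representative cluster shapes (`F` = 0, 0.5, 1) crossed with
#' thresholds 1-5% in 1%-point steps, plus any fitted optimal thresholds
#' supplied.
#'
#' @param optimal Optional data.frame with columns `F` and `t` (e.g. the
#'   `optima` of a [fit_thresholds()] result renamed to `t = t_median`).
#' @return data.frame with columns `F`, `t`, `optimal`.
#' @export
default_sensitivity_params <- function(optimal = NULL) {
  g <- expand.grid(F = c(0, 0.5, 1), t = (1:5) / 100)
  g$optimal <- FALSE
  if (!is.null(optimal) && nrow(optimal)) {
    add <- data.frame(F = optimal$F, t = optimal$t, optimal = TRUE)
    g <- rbind(g, add)
  }
  g[order(g$F, g$t), , drop = FALSE]
}
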