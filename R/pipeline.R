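# End-to-end orchestration: simulate or read inputs, compute distances,
# infer the phenotype-vs-marker species boundaries, fit clustering
# parameters, identify queries and tabulate temporal coverage, writing
# every intermediate artifact to the output directory.  The configuration
# is a plain named list (or a YAML file with the same structure), so a
# run is reproducible from a single text file plus a seed.

#' Run the delimitation/identification pipeline end to end
#'
#' Stages (toggled via `config$stages`, executed in this order):
#' `simulate`, `distances`, `parsimony`, `boundaries`, `optimize`,
#' `identify`, `coverage`.  Each stage consumes the artifacts of earlier
#' stages; a missing dependency is an error naming the required upstream
#' stage.
#'
#' @param config Named list or path to a YAML file.  Recognised entries:
#'   \describe{
#'     \item{out_dir}{Output directory (created if absent).}
#'     \item{seed}{Integer seed recorded in the report and used for
#'       simulation and bootstrapping.}
#'     \item{stages}{Character vector of stage names (default: all).}
#'     \item{simulate}{List of [synth_config()] arguments.}
#'     \item{inputs}{List of file paths (`alignment`, `metadata`,
#'       `char_matrix`, `reference`) used when `simulate` is not run.}
#'     \item{cluster}{List: `F_grid`, `t_step` or `t_grid`, `metric`.}
#'     \item{parsimony}{List: `bootstrap_replicates`, `max_taxa`,
#'       `with_bremer`.}
#'     \item{boundaries}{List of [boundary_config()] arguments.}
#'     \item{coverage}{List: `years`, `recluster_per_year`,
#'       `extra_params` (data.frame F/t).}
#'   }
#' @return A `"pipeline_report"`: list of per-stage summaries, parameters,
#'   seeds and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  all_stages <- c("simulate", "distances", "parsimony", "boundaries",
                  "optimize", "identify", "coverage")
  stages <- config$stages %||% all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  art <- list()   # in-memory artifacts
  paths <- list() # written files
  report <- list(seed = seed, stages = stages,
                 package_version = as.character(utils::packageVersion("otudelim")))
  need <- function(what, from) {
    if (is.null(art[[what]]))
      stop("stage dependency missing: requires '", what,
           "' (run the ", from, " stage or provide the input file)")
    art[[what]]
  }

  # ---- inputs / simulation
  if ("simulate" %in% stages) {
    sc <- do.call(synth_config, c(config$simulate %||% list(),
                                  if (is.null(config$simulate$seed))
                                    list(seed = seed)))
    sim <- simulate_dataset(sc)
    art$msa <- sim$msa
    art$meta <- sim$meta
    art$char_matrix <- sim$phenotype
    art$reference <- sim$labels
    art$truth <- sim$truth
    paths$alignment <- file.path(out_dir, "alignment.fasta")
    write_fasta(unclass(sim$msa), paths$alignment)
    paths$metadata <- file.path(out_dir, "metadata.tsv")
    utils::write.table(sim$meta, paths$metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$reference <- file.path(out_dir, "reference_partition.tsv")
    write_partition(sim$labels, paths$reference)
    report$simulate <- list(n_sequences = length(sim$msa),
                            n_species = sc$n_species,
                            n_labelled = length(sim$labels))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (!is.null(inp$alignment)) art$msa <- as_msa(read_fasta(inp$alignment))
    if (!is.null(inp$metadata))
      art$meta <- utils::read.table(inp$metadata, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
    if (!is.null(inp$char_matrix)) art$char_matrix <- read_char_matrix(inp$char_matrix)
    if (!is.null(inp$reference)) art$reference <- read_partition(inp$reference)
  }

  # ---- distances
  if ("distances" %in% stages) {
    msa <- need("msa", "simulate")
    art$distances <- p_distance_matrix(msa)
    paths$distances <- file.path(out_dir, "distances.tsv")
    write_distmat(art$distances, paths$distances)
    report$distances <- list(n = nrow(art$distances),
                             max = max(art$distances))
  }

  # ---- parsimony + boundaries (species boundaries from phenotype vs DNA)
  if ("parsimony" %in% stages) {
    cm <- need("char_matrix", "simulate")
    msa <- need("msa", "simulate")
    pcfg <- config$parsimony %||% list()
    combined <- combine_char_matrices(dna_char_matrix(msa), cm)
    art$annotated <- do.call(annotate_tree,
                             c(list(m = combined, seed = seed), pcfg))
    paths$tree <- file.path(out_dir, "annotated_tree.nwk")
    write_newick(art$annotated, paths$tree)
    report$parsimony <- list(
      taxa = length(art$annotated$tree$tip.label),
      score_total = sum(art$annotated$branch$length_total))
  }
  if ("boundaries" %in% stages) {
    at <- need("annotated", "parsimony")
    bargs <- config$boundaries %||% list()
    if (is.null(bargs$phenotype_partitions))
      bargs$phenotype_partitions <-
        setdiff(at$partitions, bargs$seq_partition %||% "ITS")
    bcfg <- do.call(boundary_config, bargs)
    at <- mark_within_species(at, bcfg)
    art$annotated <- at
    sp <- species_partition(at, bcfg)
    art$reference <- sp
    paths$species <- file.path(out_dir, "species_partition.tsv")
    write_partition(sp, paths$species)
    report$boundaries <- list(n_species = n_clusters(sp),
                              n_marked = sum(at$branch$within_species))
  }

  # ---- optimize
  if ("optimize" %in% stages) {
    d <- need("distances", "distances")
    ref <- need("reference", "simulate or boundaries")
    ccfg <- config$cluster %||% list()
    fit <- fit_thresholds(d, ref,
                          F_grid = ccfg$F_grid %||% c(0, 0.5, 1),
                          t_grid = ccfg$t_grid,
                          t_step = ccfg$t_step %||% 0.0005,
                          metric = ccfg$metric %||% "modified_rand")
    art$fit <- fit
    paths$optimization <- file.path(out_dir, "optimization_grid.tsv")
    utils::write.table(fit$grid, paths$optimization, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$optimize <- list(optima = fit$optima)
  }

  # ---- identify
  if ("identify" %in% stages) {
    d <- need("distances", "distances")
    fit <- need("fit", "optimize")
    idres <- predict(fit, newdata = d)
    art$identification <- idres
    paths$identification <- file.path(out_dir, "identification.tsv")
    utils::write.table(idres, paths$identification, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$partition <- file.path(out_dir, "cluster_partition.tsv")
    write_partition(attr(idres, "partition"), paths$partition)
    report$identify <- list(
      n_queries = nrow(idres),
      n_novel = sum(idres$status == "NOVEL"),
      n_ambiguous = sum(idres$status == "ambiguous"))
    if (!is.null(art$truth)) {
      p <- attr(idres, "partition")
      report$identify$agreement_with_truth <-
        rand_family(p, art$truth$species, "modified_rand")
      report$identify$recovered_species <- n_clusters(p)
    }
  }

  # ---- coverage
  if ("coverage" %in% stages) {
    d <- need("distances", "distances")
    meta <- need("meta", "simulate")
    vcfg <- config$coverage %||% list()
    params <- default_sensitivity_params(
      if (!is.null(art$fit))
        data.frame(F = art$fit$optima$F, t = art$fit$optima$t_median))
    if (!is.null(vcfg$extra_params))
      params <- rbind(params,
                      cbind(as.data.frame(vcfg$extra_params), optimal = NA))
    cov <- sensitivity_grid(d, meta, params, years = vcfg$years,
                            recluster_per_year = isTRUE(vcfg$recluster_per_year))
    art$coverage <- cov
    paths$coverage <- file.path(out_dir, "coverage.tsv")
    utils::write.table(cov, paths$coverage, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    report$coverage <- list(n_param_combinations = nrow(params),
                            years = sort(unique(cov$year)))
  }

  report$artifacts <- paths
  paths$report <- file.path(out_dir, "report.yaml")
  yaml::write_yaml(serializable(report), paths$report)
  report$artifacts <- paths
  structure(c(report, list(state = art)), class = "pipeline_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# yaml cannot serialise data.frames nicely; flatten them
serializable <- function(x) {
  if (is.data.frame(x)) return(lapply(as.list(x), serializable))
  if (is.list(x)) return(lapply(x, serializable))
  x
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("Stages:", paste(x$stages, collapse = " -> "), "\n")
  for (st in intersect(c("simulate", "distances", "parsimony", "boundaries",
                         "optimize", "identify", "coverage"), names(x))) {
    cat("  ", st, ": ", sep = "")
    s <- x[[st]]
    if (st == "optimize") {
      cat("\n"); print(format(s$optima, digits = 4), row.names = FALSE)
    } else {
      cat(paste(names(s), vapply(s, function(v)
        paste(format(unlist(v), digits = 4), collapse = ","),
        character(1)), sep = "=", collapse = ", "), "\n")
    }
  }
  invisible(x)
}
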