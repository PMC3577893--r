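#' Coded character matrices for parsimony analysis
#'
#' A `"char_matrix"` holds integer-coded states for taxa x characters,
#' together with each character's type (`unordered`: any state change costs
#' one step; `ordered`: a change from state i to state j costs `|i - j|`
#' steps) and a data-partition tag (e.g. `ITS`, `macromorphology`,
#' `physiology`) used for partitioned branch statistics.
#'
#' @param states Integer matrix (taxa in rows, characters in columns) with
#'   `NA` for missing; row names are taxon ids.
#' @param type Character vector, one of `"unordered"`/`"ordered"` per column.
#' @param partition Character vector of partition tags, one per column.
#' @return An object of class `"char_matrix"`: a list with elements
#'   `states`, `type`, `partition`.
#' @export
char_matrix <- function(states, type, partition) {
  states <- as.matrix(states)
  mode(states) <- "integer"
  if (is.null(rownames(states))) stop("states must have taxon row names")
  if (length(type) != ncol(states) || length(partition) != ncol(states))
    stop("type and partition must have one entry per character")
  if (!all(type %in% c("unordered", "ordered")))
    stop("character types must be 'unordered' or 'ordered'")
  if (is.null(colnames(states)))
    colnames(states) <- sprintf("c%03d", seq_len(ncol(states)))
  structure(list(states = states, type = as.character(type),
                 partition = as.character(partition)),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Coded character matrix: ", nrow(x$states), " taxa x ",
      ncol(x$states), " characters\n", sep = "")
  tab <- table(x$partition)
  cat("Partitions: ",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Recode an aligned DNA matrix as unordered parsimony characters
#'
#' Bases A/C/G/T become unordered states 0-3; gaps, `?` and ambiguity codes
#' are recoded as missing, following the convention of treating alignment
#' gaps as missing data when scoring trees.
#'
#' @param msa An `"msa"` object (see [as_msa()]).
#' @param partition_tag Partition label for all resulting characters
#'   (default `"ITS"`).
#' @param drop_constant Drop columns with fewer than two observed states
#'   (they can never contribute steps)?
#' @return A `"char_matrix"`.
#' @export
dna_char_matrix <- function(msa, partition_tag = "ITS", drop_constant = TRUE) {
  stopifnot(inherits(msa, "msa"))
  chars <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(chars) <- names(msa)
  states <- matrix(match(chars, c("A", "C", "G", "T")) - 1L, nrow = nrow(chars),
                   dimnames = dimnames(chars))
  if (drop_constant) {
    keep <- apply(states, 2L, function(col) length(unique(col[!is.na(col)])) >= 2L)
    states <- states[, keep, drop = FALSE]
  }
  colnames(states) <- sprintf("%s%04d", tolower(partition_tag), seq_len(ncol(states)))
  char_matrix(states, rep("unordered", ncol(states)),
              rep(partition_tag, ncol(states)))
}

#' Combine character matrices over the same taxa
#'
#' @param ... `"char_matrix"` objects sharing the same taxon set.
#' @return A single `"char_matrix"` with all characters, taxa aligned by id.
#' @export
combine_char_matrices <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 1L, all(vapply(ms, inherits, TRUE, "char_matrix")))
  taxa <- rownames(ms[[1L]]$states)
  for (m in ms[-1L])
    if (!setequal(rownames(m$states), taxa))
      stop("character matrices cover different taxon sets")
  char_matrix(do.call(cbind, lapply(ms, function(m) m$states[taxa, , drop = FALSE])),
              unlist(lapply(ms, `[[`, "type")),
              unlist(lapply(ms, `[[`, "partition")))
}

#' Count parsimony-informative characters
#'
#' A character is parsimony-informative when at least two of its states each
#' occur in at least two taxa (missing values excluded); only such
#' characters can favour one topology over another.
#'
#' @param m A `"char_matrix"`.
#' @param partition_tag Optional tag: count only characters of this
#'   partition.
#' @return Integer count.
#' @export
parsimony_informative_count <- function(m, partition_tag = NULL) {
  stopifnot(inherits(m, "char_matrix"))
  cols <- seq_len(ncol(m$states))
  if (!is.null(partition_tag)) cols <- which(m$partition == partition_tag)
  sum(vapply(cols, function(j) {
    tab <- table(m$states[, j], useNA = "no")
    sum(tab >= 2L) >= 2L
  }, logical(1)))
}
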