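#' Read a FASTA file into a named character vector of sequences
#'
#' Sequences are returned as upper-case IUPAC DNA strings; the gap symbol
#' `-` and the missing symbol `?` are allowed.  Record ids are the first
#' whitespace-delimited token of each header line and must be unique.
#'
#' @param path Path to a FASTA file (plain or aligned).
#' @return A named character vector of residues, one element per record, in
#'   file order.  The full header lines are kept in the `"description"`
#'   attribute.
#' @seealso [write_fasta()], [as_msa()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  desc <- names(set)
  ids <- vapply(strsplit(desc, "[ \t]+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- grepl(sprintf("[^%s?-]", paste(iupac_codes(), collapse = "")), seqs)
  if (any(bad))
    stop("illegal residue characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty residues in record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  attr(seqs, "description") <- desc
  seqs
}

iupac_codes <- function() strsplit("ACGTRYSWKMBDHVN", "")[[1]]

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of residues (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Coerce aligned sequences to a multiple-sequence-alignment object
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return An object of class `"msa"`: the input vector with the alignment
#'   length in attribute `"length"`.
#' @export
as_msa <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 2L, !is.null(names(seqs)))
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("aligned sequences must all have equal length; found lengths ",
         paste(len, collapse = ", "))
  structure(seqs, length = len, class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", length(x), " sequences x ",
      attr(x, "length"), " columns\n", sep = "")
  invisible(x)
}

#' Parse GenBank flat files into a metadata table
#'
#' Extracts, per `LOCUS` record: accession (LOCUS name), organism
#' (`ORGANISM` line), host, country and deposition year.  The host is taken
#' from the `/host` qualifier, falling back to `/isolation_source`; the host
#' genus is the first whitespace token and the host species is set only when
#' a second token other than `sp.`/`spp.` is present (GenBank hosts are
#' frequently determined to genus only).  The deposition year comes from the
#' LOCUS-line date.  No host is ever invented: absent qualifier means `NA`.
#'
#' @param paths Character vector of GenBank flat-file paths.
#' @param incomplete_year Optional integer year: records deposited in this
#'   (still running, hence incompletely sampled) year are recoded as
#'   `incomplete_year - 0.5` so that cumulative series do not overstate the
#'   final year.
#' @return A data.frame with columns `accession`, `organism`, `host_genus`,
#'   `host_species`, `country`, `deposition_year`.
#' @export
parse_genbank_flatfiles <- function(paths, incomplete_year = NULL) {
  recs <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("GenBank flat file not found: ", p)
    lines <- readLines(p, warn = FALSE)
    starts <- grep("^LOCUS", lines)
    if (!length(starts)) {
      warning("no LOCUS record in ", p, "; file skipped")
      next
    }
    ends <- c(starts[-1L] - 1L, length(lines))
    for (k in seq_along(starts)) {
      rec <- tryCatch(
        parse_genbank_record(lines[starts[k]:ends[k]]),
        error = function(e) {
          warning("skipping unparseable GenBank record in ", p, ": ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(accession = character(), organism = character(),
                      host_genus = character(), host_species = character(),
                      country = character(), deposition_year = numeric())
  rownames(out) <- NULL
  if (!is.null(incomplete_year)) {
    hit <- !is.na(out$deposition_year) & out$deposition_year == incomplete_year
    out$deposition_year[hit] <- incomplete_year - 0.5
  }
  out
}

parse_genbank_record <- function(lines) {
  locus <- strsplit(trimws(lines[1L]), "[ \t]+")[[1]]
  if (length(locus) < 2L) stop("malformed LOCUS line")
  accession <- locus[2L]
  datefield <- grep("^\\d{1,2}-[A-Z]{3}-\\d{4}$", locus, value = TRUE)
  year <- NA_real_
  if (length(datefield)) {
    year <- as.numeric(sub(".*-(\\d{4})$", "\\1", datefield[1L]))
  } else {
    warning("no date on LOCUS line of ", accession, "; year set missing")
  }
  org_i <- grep("^ {0,4}ORGANISM", lines)
  organism <- if (length(org_i)) trimws(sub("^ *ORGANISM +", "", lines[org_i[1L]]))
              else NA_character_
  host <- genbank_qualifier(lines, "host")
  if (is.na(host)) host <- genbank_qualifier(lines, "isolation_source")
  country <- genbank_qualifier(lines, "country")
  hg <- hs <- NA_character_
  if (!is.na(host)) {
    toks <- strsplit(trimws(host), "[ \t]+")[[1]]
    hg <- toks[1L]
    if (length(toks) >= 2L && !(toks[2L] %in% c("sp.", "spp.", "sp", "spp")))
      hs <- paste(toks[1L], toks[2L])
  }
  data.frame(accession = accession, organism = organism, host_genus = hg,
             host_species = hs, country = country, deposition_year = year)
}

# Extract the (first) value of a /qualifier="..." in a FEATURES block;
# values may continue over several lines.
genbank_qualifier <- function(lines, name) {
  pat <- paste0("^ +/", name, "=\"")
  i <- grep(pat, lines)
  if (!length(i)) return(NA_character_)
  val <- sub(paste0(pat, "?"), "", lines[i[1L]])
  while (!grepl("\"", val) && i[1L] < length(lines)) {
    i[1L] <- i[1L] + 1L
    val <- paste(val, trimws(lines[i[1L]]))
  }
  trimws(sub("\".*$", "", sub("\"$", "", val)))
}

#' Read a coded character matrix with type and partition header rows
#'
#' The expected CSV layout is: a header row naming the taxon-id column and
#' the characters; a row with taxon id `!type` giving each character's type
#' (`unordered` or `ordered`); a row with taxon id `!partition` giving each
#' character's data-partition tag (e.g. `ITS`, `macromorphology`,
#' `physiology`); then one row per taxon with integer states or `?` for
#' missing.
#'
#' @param path CSV file path.
#' @return A `"char_matrix"` object; see [char_matrix()].
#' @export
read_char_matrix <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(raw) < 3L) stop("character matrix needs !type, !partition and taxa rows")
  ids <- raw[[1L]]
  ti <- match("!type", ids); pi <- match("!partition", ids)
  if (is.na(ti) || is.na(pi))
    stop("character matrix must contain '!type' and '!partition' rows")
  body <- raw[-c(ti, pi), , drop = FALSE]
  states <- as.matrix(body[, -1L, drop = FALSE])
  rownames(states) <- body[[1L]]
  bad <- !grepl("^(\\?|-|-?\\d+)$", states)
  if (any(bad))
    stop("unknown state symbols: ", paste(unique(states[bad]), collapse = ", "))
  states[states %in% c("?", "-")] <- NA
  mode(states) <- "integer"
  char_matrix(states,
              type = as.character(raw[ti, -1L]),
              partition = as.character(raw[pi, -1L]))
}

#' Write a coded character matrix in the layout read by [read_char_matrix()]
#'
#' @param m A `"char_matrix"` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_char_matrix <- function(m, path) {
  stopifnot(inherits(m, "char_matrix"))
  st <- m$states
  st[is.na(st)] <- "?"
  tab <- rbind(`!type` = m$type, `!partition` = m$partition, st)
  df <- data.frame(taxon = rownames(tab), tab, check.names = FALSE)
  colnames(df) <- c("taxon", colnames(m$states))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write partition TSV files (element <TAB> cluster)
#'
#' @param path TSV path with two columns `element` and `cluster` (header
#'   optional on read).
#' @return `read_partition()` returns a named character vector mapping
#'   element ids to cluster labels; `write_partition()` returns `path`
#'   invisibly.
#' @export
read_partition <- function(path) {
  tab <- utils::read.table(path, sep = "\t", colClasses = "character",
                           col.names = c("element", "cluster"))
  if (tab$element[1L] == "element") tab <- tab[-1L, , drop = FALSE]
  if (anyDuplicated(tab$element))
    stop("duplicate elements in partition file: ", path)
  stats::setNames(tab$cluster, tab$element)
}

#' @rdname read_partition
#' @param partition Named character vector (element -> cluster label).
#' @export
write_partition <- function(partition, path) {
  utils::write.table(
    data.frame(element = names(partition), cluster = unname(partition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
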