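#' Construct a reference database
#'
#' Pairs reference sequences with species-level lineages. Every sequence
#' id must have a lineage and vice versa; ids are unique and sequences
#' non-empty.
#'
#' @param sequences named character vector of DNA sequences (names = ids).
#' @param taxonomy named list of lineages (character vectors of prefixed
#'   labels), keyed by the same ids.
#' @return An object of class `refdb` with elements `sequences` and
#'   `taxonomy`.
#' @export
ref_db <- function(sequences, taxonomy) {
  if (length(sequences) == 0L) stop("empty reference database", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequence ids must be unique and non-empty", call. = FALSE)
  }
  if (any(!nzchar(sequences))) stop("empty sequence in reference", call. = FALSE)
  missing_tax <- setdiff(ids, names(taxonomy))
  if (length(missing_tax)) {
    stop("sequences without taxonomy: ", paste(utils::head(missing_tax, 5),
         collapse = ", "), call. = FALSE)
  }
  extra_tax <- setdiff(names(taxonomy), ids)
  if (length(extra_tax)) {
    stop("taxonomy entries without sequences: ",
         paste(utils::head(extra_tax, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(sequences = toupper(sequences),
                 taxonomy = taxonomy[ids]),
            class = "refdb")
}

#' @export
print.refdb <- function(x, ...) {
  keys <- species_keys(x)
  cat(sprintf("<refdb> %d sequences, %d distinct class lineages\n",
              length(x$sequences), length(keys)))
  invisible(x)
}

#' Distinct class lineages of a reference database
#'
#' The classification classes are the distinct (possibly truncated)
#' lineages of the reference; each is keyed by its formatted string.
#'
#' @param refdb a [ref_db()] object.
#' @return Sorted character vector of lineage keys.
#' @export
species_keys <- function(refdb) {
  sort(unique(vapply(refdb$taxonomy, format_lineage, character(1))))
}

.iupac <- c("A","C","G","T","N","R","Y","S","W","K","M","B","D","H","V")

#' Read reference sequences from a FASTA file
#'
#' The id is the header token up to the first whitespace; sequences are
#' uppercased. Duplicate ids, an empty file, or characters outside the
#' IUPAC nucleotide alphabet are errors.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in FASTA: ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  out <- toupper(as.character(seqs))
  names(out) <- ids
  bad <- vapply(out, function(s) {
    chars <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    any(!chars %in% .iupac)
  }, logical(1))
  if (any(bad)) {
    stop("non-nucleotide characters in sequence: ", ids[bad][1],
         call. = FALSE)
  }
  out
}

#' Write sequences to a FASTA file
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_reference_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), filepath = path)
  invisible(path)
}

#' Read a Greengenes-style taxonomy map
#'
#' Two tab-separated columns: sequence id and semicolon-delimited lineage.
#' A header row (`Feature ID<TAB>Taxon`) is detected by its first field
#' not starting with a rank-prefixed lineage in column two and skipped.
#'
#' @param path TSV file path.
#' @return Named list of lineages keyed by sequence id.
#' @export
read_taxonomy_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty taxonomy map: ", path, call. = FALSE)
  start <- 1L
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 1L &&
      tolower(trimws(first[1])) %in% c("feature id", "feature-id", "id",
                                       "otu id", "#otu id")) {
    start <- 2L
  }
  out <- list()
  for (i in seq(start, length(lines))) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L) {
      stop(sprintf("taxonomy map line %d: expected 2 tab-separated columns, found %d",
                   i, length(fields)), call. = FALSE)
    }
    id <- trimws(fields[1])
    if (id %in% names(out)) {
      stop(sprintf("taxonomy map line %d: duplicate id '%s'", i, id),
           call. = FALSE)
    }
    out[[id]] <- parse_lineage(fields[2])
  }
  out
}

#' Write a taxonomy map
#' @param taxonomy named list of lineages.
#' @param path output TSV path.
#' @param header write a `Feature ID`/`Taxon` header row.
#' @export
write_taxonomy_map <- function(taxonomy, path, header = TRUE) {
  lines <- vapply(names(taxonomy), function(id) {
    paste(id, format_lineage(taxonomy[[id]]), sep = "\t")
  }, character(1))
  if (header) lines <- c("Feature ID\tTaxon", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a read set
#'
#' @param reads named character vector of read sequences (names = ids).
#' @param truth optional named list of true lineages covering every read.
#' @return An object of class `read_set`.
#' @export
read_set <- function(reads, truth = NULL) {
  ids <- names(reads)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("read ids must be unique and non-empty", call. = FALSE)
  }
  if (!is.null(truth)) {
    missing <- setdiff(ids, names(truth))
    if (length(missing)) {
      stop("truth lineages missing for reads: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    truth <- truth[ids]
  }
  structure(list(reads = toupper(reads), truth = truth), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads%s\n", length(x$reads),
              if (is.null(x$truth)) "" else " (with truth lineages)"))
  invisible(x)
}

#' Trim reads to a fixed length
#'
#' Each read is truncated to its first `length` bases; reads shorter than
#' `length` are dropped and counted in the `dropped` attribute, keeping
#' the fixed-geometry contract that the sentence encoder needs.
#'
#' @param reads a [read_set()].
#' @param length trim length in nt (e.g. 150).
#' @return A `read_set` of trimmed reads, with attribute `dropped` giving
#'   the number of removed short reads.
#' @export
trim_reads <- function(reads, length = 150L) {
  stopifnot(inherits(reads, "read_set"))
  if (!is.numeric(length) || length <= 0L) {
    stop("trim length must be a positive integer", call. = FALSE)
  }
  keep <- nchar(reads$reads) >= length
  trimmed <- substr(reads$reads[keep], 1L, length)
  out <- read_set(trimmed,
                  truth = if (is.null(reads$truth)) NULL else reads$truth[keep])
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Write classification output
#'
#' Three tab-separated columns (with header): read id, semicolon-joined
#' lineage (the literal `Unassigned` for the empty lineage), and the
#' achieved confidence. Round-trips through [read_assignments()].
#'
#' @param assignments a data frame as returned by [classify_reads()]:
#'   columns `read_id`, `lineage` (formatted string), `confidence`.
#' @param path output TSV path.
#' @export
write_assignments <- function(assignments, path) {
  stopifnot(is.data.frame(assignments),
            all(c("read_id", "lineage", "confidence") %in% names(assignments)))
  utils::write.table(
    assignments[, c("read_id", "lineage", "confidence")],
    file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read classification output written by [write_assignments()]
#' @param path TSV path.
#' @return Data frame with columns `read_id`, `lineage`, `confidence`.
#' @export
read_assignments <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  names(df) <- c("read_id", "lineage", "confidence")
  df
}
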