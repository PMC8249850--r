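#' @title Greengenes-style taxonomic lineages
#'
#' @description A lineage is an ordered path through the seven canonical
#' ranks (kingdom, phylum, class, order, family, genus, species), written
#' with Greengenes prefixes (`k__`, `p__`, ..., `s__`). Lineages may be
#' truncated: a depth-4 lineage stops at order. Within the package a
#' lineage is a plain character vector of prefixed labels, e.g.
#' `c("k__Bacteria", "p__Firmicutes")`; the empty vector means Unassigned.
#'
#' @name lineage
NULL

.rank_prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
.rank_names <- c("kingdom", "phylum", "class", "order", "family",
                 "genus", "species")

#' Parse a semicolon-delimited Greengenes lineage string
#'
#' Labels must carry the canonical rank prefixes in order with no gaps.
#' An empty label (e.g. `"s__"`) truncates the lineage at the previous
#' rank; any non-empty labels after an empty one are dropped with a
#' warning. The empty string parses to the empty (Unassigned) lineage, as
#' does the literal `"Unassigned"`.
#'
#' @param text a single lineage string such as
#'   `"k__Bacteria; p__Firmicutes"`.
#' @return Character vector of prefixed rank labels (length 0--7).
#' @examples
#' parse_lineage("k__Bacteria; p__Firmicutes")
#' parse_lineage("")
#' @export
parse_lineage <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("lineage text must be a single character string", call. = FALSE)
  }
  text <- trimws(text)
  if (text == "" || text == "Unassigned") return(character(0))
  parts <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  if (length(parts) > 7L) {
    stop("lineage has more than 7 ranks: ", text, call. = FALSE)
  }
  out <- character(0)
  for (i in seq_along(parts)) {
    tok <- parts[i]
    prefix <- substr(tok, 1L, 3L)
    if (prefix != .rank_prefixes[i]) {
      stop(sprintf(
        "lineage rank %d: expected prefix '%s' but found token '%s'",
        i, .rank_prefixes[i], tok), call. = FALSE)
    }
    label <- substr(tok, 4L, nchar(tok))
    if (label == "") {
      rest <- parts[-seq_len(i)]
      if (any(nchar(sub("^.{3}", "", rest)) > 0L)) {
        warning(sprintf(
          "empty rank '%s' truncates lineage; dropping trailing ranks: %s",
          tok, paste(rest, collapse = "; ")), call. = FALSE)
      }
      return(out)
    }
    out <- c(out, tok)
  }
  out
}

#' Format a lineage back into a semicolon-delimited string
#'
#' Inverse of [parse_lineage()] on its normalized output. The empty
#' lineage formats as `"Unassigned"`.
#'
#' @param lineage character vector of prefixed rank labels.
#' @return A single string.
#' @export
format_lineage <- function(lineage) {
  if (length(lineage) == 0L) return("Unassigned")
  paste(lineage, collapse = "; ")
}

#' Depth of the longest common rank prefix of two lineages
#'
#' @param a,b lineages as character vectors.
#' @return Integer depth (0 if they differ at kingdom).
#' @export
lineage_common_depth <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  same <- a[seq_len(n)] == b[seq_len(n)]
  if (all(same)) n else sum(cumprod(same))
}

#' Truncate a lineage to a given depth
#' @param lineage character vector of prefixed labels.
#' @param depth target depth (1 = kingdom, 7 = species).
#' @return The first `min(depth, length(lineage))` labels.
#' @export
truncate_lineage <- function(lineage, depth) {
  lineage[seq_len(min(length(lineage), depth))]
}

#' Map a rank name to its depth
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return Integer depth 1--7.
#' @export
rank_depth <- function(rank) {
  rank <- match.arg(rank, .rank_names)
  match(rank, .rank_names)
}
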