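#' Configuration for the synthetic taxonomy/community generator
#'
#' Describes the study conditions emulated by the generators: a 7-rank
#' taxonomy tree, reference sequences evolved by substitution along the
#' tree, skewed (Dirichlet) community compositions, and fixed-length
#' prefix reads with optional substitution errors. Everything is
#' deterministic given `seed`.
#'
#' @param branching integer vector of length 7: number of taxa spawned at
#'   each rank (kingdoms, phyla per kingdom, ..., species per genus).
#' @param seq_length reference sequence length in nt (default 250,
#'   V4-amplicon-like).
#' @param divergence per-rank substitution rates applied when deriving a
#'   child taxon's sequence from its parent's, kingdom through species.
#' @param p_share probability that a species is assigned a byte-identical
#'   copy of a sister species' sequence (the exact-match classifier's
#'   only failure mode; default 0).
#' @param seqs_per_species reference records per species (default 1).
#' @param within_species_divergence substitution rate for additional
#'   per-species records beyond the first.
#' @param n_samples number of community samples (default 5).
#' @param concentration symmetric Dirichlet concentration for community
#'   proportions (0.1 gives strongly skewed communities).
#' @param reads_per_sample sequencing depth per sample (default 100).
#' @param read_length read length in nt (default 150).
#' @param error_rate per-base read substitution error rate (default
#'   0.001, short-read-like).
#' @param seed mandatory integer seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(branching = c(1L, 2L, 1L, 1L, 2L, 3L, 2L),
                         seq_length = 250L,
                         divergence = c(0.15, 0.10, 0.08, 0.06,
                                        0.05, 0.03, 0.02),
                         p_share = 0,
                         seqs_per_species = 1L,
                         within_species_divergence = 0.002,
                         n_samples = 5L,
                         concentration = 0.1,
                         reads_per_sample = 100L,
                         read_length = 150L,
                         error_rate = 0.001,
                         seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (length(branching) != 7L || any(branching < 1L)) {
    stop("branching must be 7 factors, all >= 1", call. = FALSE)
  }
  if (length(divergence) != 7L || any(divergence < 0) || any(divergence > 1)) {
    stop("divergence must be 7 rates in [0, 1]", call. = FALSE)
  }
  if (p_share < 0 || p_share > 1) stop("p_share must be in [0, 1]", call. = FALSE)
  if (concentration <= 0) stop("concentration must be > 0", call. = FALSE)
  if (read_length > seq_length) {
    stop("read_length cannot exceed seq_length", call. = FALSE)
  }
  structure(list(
    branching = as.integer(branching), seq_length = as.integer(seq_length),
    divergence = divergence, p_share = p_share,
    seqs_per_species = as.integer(seqs_per_species),
    within_species_divergence = within_species_divergence,
    n_samples = as.integer(n_samples), concentration = concentration,
    reads_per_sample = as.integer(reads_per_sample),
    read_length = as.integer(read_length), error_rate = error_rate,
    seed = as.integer(seed)), class = "synth_config")
}

.bases <- c("A", "C", "G", "T")

.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(.bases, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a reference database from a 7-rank taxonomy tree
#'
#' A root sequence is drawn uniformly over A/C/G/T; each child taxon's
#' sequence substitutes a rank-specific fraction of its parent's
#' positions. With probability `p_share` a species (after the first in
#' its genus) is assigned a byte-identical copy of a sister species'
#' sequence. A divergence rate expected to produce fewer than one
#' substitution triggers a warning, not an error. Between-species
#' sequence sharing is controlled by `p_share` alone: a non-shared
#' species sequence is redrawn until its `read_length` prefix differs
#' from every other species', so `p_share = 0` guarantees unique (even
#' after trimming) sequences and the exact-match classifier's defining
#' in-sample property.
#'
#' @param config a [synth_config()].
#' @return A [ref_db()] with `seqs_per_species` records per species.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  low <- config$divergence * config$seq_length < 1 & config$divergence > 0
  if (any(low)) {
    warning("divergence at rank(s) ", paste(which(low), collapse = ","),
            " expects < 1 substitution", call. = FALSE)
  }
  with_seed(config$seed, {
    root <- paste(sample(.bases, config$seq_length, replace = TRUE),
                  collapse = "")
    nodes <- list(list(seq = root, lineage = character(0), path = ""))
    species_prefixes <- character(0)
    for (r in seq_len(7L)) {
      prefix <- .rank_prefixes[r]
      nxt <- list()
      for (node in nodes) {
        siblings <- list()
        for (j in seq_len(config$branching[r])) {
          path <- if (node$path == "") as.character(j) else
            paste0(node$path, ".", j)
          child_seq <- if (r == 7L && j > 1L && length(siblings) &&
                           stats::runif(1) < config$p_share) {
            siblings[[sample.int(length(siblings), 1L)]]
          } else if (r == 7L) {
            # between-species sharing is controlled by p_share alone:
            # redraw on read-length-prefix collision with any other species
            s <- .mutate_seq(node$seq, config$divergence[r])
            tries <- 0L
            while (substr(s, 1L, config$read_length) %in% species_prefixes &&
                   config$divergence[r] > 0 && tries < 100L) {
              s <- .mutate_seq(node$seq, config$divergence[r])
              tries <- tries + 1L
            }
            if (tries >= 100L) {
              warning("could not make a unique species sequence after 100 tries",
                      call. = FALSE)
            }
            s
          } else {
            .mutate_seq(node$seq, config$divergence[r])
          }
          if (r == 7L) {
            species_prefixes <- c(species_prefixes,
                                  substr(child_seq, 1L, config$read_length))
          }
          siblings[[j]] <- child_seq
          nxt[[length(nxt) + 1L]] <- list(
            seq = child_seq,
            lineage = c(node$lineage,
                        paste0(prefix, toupper(.rank_names[r]), path)),
            path = path)
        }
      }
      nodes <- nxt
    }
    seqs <- character(0); tax <- list()
    for (node in nodes) {
      for (rep_i in seq_len(config$seqs_per_species)) {
        id <- sprintf("ref_%s_%d", node$path, rep_i)
        s <- if (rep_i == 1L) node$seq else
          .mutate_seq(node$seq, config$within_species_divergence)
        seqs[id] <- s
        tax[[id]] <- node$lineage
      }
    }
    ref_db(seqs, tax)
  })
}

#' Simulate skewed community compositions
#'
#' Per sample, species proportions are drawn from a symmetric Dirichlet
#' with the configured concentration (via normalized gamma draws) and
#' counts from a multinomial at the configured depth.
#'
#' @param refdb a [simulate_reference()] result.
#' @param config the same [synth_config()].
#' @return List of named count vectors (lineage key -> count), one per
#'   sample; attribute `proportions` holds the underlying Dirichlet
#'   draws.
#' @export
simulate_communities <- function(refdb, config) {
  stopifnot(inherits(refdb, "refdb"), inherits(config, "synth_config"))
  keys <- species_keys(refdb)
  with_seed(config$seed + 1L, {
    props <- list()
    out <- lapply(seq_len(config$n_samples), function(i) {
      g <- stats::rgamma(length(keys), shape = config$concentration)
      while (sum(g) == 0) g <- stats::rgamma(length(keys),
                                             shape = config$concentration)
      p <- g / sum(g)
      props[[i]] <<- stats::setNames(p, keys)
      counts <- stats::rmultinom(1L, size = config$reads_per_sample,
                                 prob = p)[, 1]
      stats::setNames(as.numeric(counts), keys)
    })
    names(out) <- paste0("sample", seq_along(out))
    attr(out, "proportions") <- props
    out
  })
}

#' Simulate reads from community compositions
#'
#' Reads are drawn species-by-species according to the community counts:
#' a uniformly chosen reference record of the species, truncated to its
#' first `read_length` bases (the same prefix-trimming convention used
#' throughout), with i.i.d. substitution errors at the configured rate.
#' Every read carries its true lineage.
#'
#' @param refdb a [simulate_reference()] result.
#' @param communities a [simulate_communities()] result (or any list of
#'   named count vectors).
#' @param config the same [synth_config()].
#' @return A [read_set()] with truth lineages for every read.
#' @export
simulate_reads <- function(refdb, communities, config) {
  stopifnot(inherits(refdb, "refdb"), inherits(config, "synth_config"))
  cls <- vapply(refdb$taxonomy, format_lineage, character(1))
  with_seed(config$seed + 2L, {
    reads <- character(0); truth <- list()
    for (si in seq_along(communities)) {
      counts <- communities[[si]]
      counts <- counts[counts > 0]
      ri <- 0L
      for (key in names(counts)) {
        pool <- names(cls)[cls == key]
        if (length(pool) == 0L) {
          stop("community species absent from reference: ", key,
               call. = FALSE)
        }
        picks <- if (length(pool) == 1L) {
          rep(pool, counts[[key]])
        } else sample(pool, counts[[key]], replace = TRUE)
        for (j in seq_along(picks)) {
          ri <- ri + 1L
          id <- sprintf("s%d_r%d", si, ri)
          raw <- substr(refdb$sequences[[picks[j]]], 1L, config$read_length)
          reads[id] <- .mutate_seq(raw, config$error_rate)
          truth[[id]] <- refdb$taxonomy[[picks[j]]]
        }
      }
    }
    read_set(reads, truth)
  })
}
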