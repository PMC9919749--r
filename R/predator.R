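IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

# Uppercase, RNA U -> T, and validate against the IUPAC nucleotide alphabet.
normalize_sequence <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  s <- chartr("u", "t", x)
  s <- toupper(s)
  s <- gsub("U", "T", s, fixed = TRUE)
  if (nchar(s) == 0L) stop("empty ", what)
  bad <- setdiff(unique(strsplit(s, "")[[1L]]), IUPAC_DNA)
  if (length(bad)) {
    stop("non-IUPAC character(s) in ", what, ": ",
         paste(bad, collapse = ", "))
  }
  s
}

#' Percent identity of two sequences under ends-free global alignment
#'
#' Aligns two nucleotide sequences with a Needleman-Wunsch-style dynamic
#' programme in which terminal gaps are free (appropriate for comparing
#' near-full-length 16S rRNA gene sequences of unequal trimming). Percent
#' identity is the number of identical aligned bases divided by the number
#' of alignment columns, terminal-gap overhangs excluded. Among co-optimal
#' alignments the one with the most matches (then fewest columns) defines
#' the reported identity, so the value is deterministic. IUPAC ambiguity
#' codes are accepted but never count as matches; `U` is normalized to `T`
#' and case is ignored.
#'
#' @param a,b Nucleotide sequence strings.
#' @param match,mismatch,gap Alignment scores (defaults +1/-1/-2, linear gap).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' global_percent_identity("ACGTACGTAC", "ACGTACGTAC")  # 100
#' @export
global_percent_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  r <- align_details(a, b, match, mismatch, gap)
  r$percent_identity
}

#' @rdname global_percent_identity
#' @return `align_details()` returns a list with `score`, `matches`,
#'   `columns` and `percent_identity`.
#' @export
align_details <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- normalize_sequence(a, "query sequence")
  b <- normalize_sequence(b, "reference sequence")
  .align_endsfree(a, b, match, mismatch, gap)
}

#' Reference database of verified predatory isolates
#'
#' Bundles 16S rRNA gene sequences of experimentally verified predatory
#' isolates with their taxonomy strings for use in [classify_predator()].
#'
#' @param sequences Named character vector (or `Biostrings::DNAStringSet`)
#'   of reference sequences; names are unique record ids.
#' @param taxonomy Optional character vector of semicolon-ranked taxonomy
#'   strings, parallel to `sequences` (or named by record id).
#' @param provenance Free-text description of the sequence source.
#' @return A `predator_db` object.
#' @export
predator_db <- function(sequences, taxonomy = NULL, provenance = "") {
  if (inherits(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  stopifnot(is.character(sequences))
  if (length(sequences) == 0L) stop("reference predator database is empty")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("reference sequences must carry unique ids")
  }
  seqs <- vapply(sequences, normalize_sequence, character(1),
                 what = "reference sequence")
  if (is.null(taxonomy)) {
    taxonomy <- stats::setNames(rep("", length(seqs)), names(seqs))
  } else {
    if (is.null(names(taxonomy))) names(taxonomy) <- names(seqs)
    taxonomy <- taxonomy[names(seqs)]
    taxonomy[is.na(taxonomy)] <- ""
  }
  structure(list(sequences = seqs, taxonomy = taxonomy,
                 provenance = provenance),
            class = "predator_db")
}

#' Classify one query sequence against the predator reference database
#'
#' The query is aligned to every reference; the best hit is the reference
#' with the highest percent identity (ties broken by lexicographically first
#' reference id). A query is a potential predator when its best identity is
#' at least `threshold` — genus-level relatedness to a verified predatory
#' isolate, with the inclusive 94.5% genus boundary as default.
#'
#' @param query A nucleotide sequence string.
#' @param db A [predator_db()].
#' @param threshold Percent-identity threshold (default 94.5, inclusive).
#' @param ... Scoring parameters passed to [global_percent_identity()].
#' @return One-row data frame: `query`, `best_ref`, `percent_identity`,
#'   `is_potential_predator`.
#' @export
classify_predator <- function(query, db, threshold = 94.5, ...) {
  if (!inherits(db, "predator_db")) stop("db must be a predator_db")
  ids <- sort(names(db$sequences))  # lexicographic tie-break
  pid <- vapply(ids, function(id) {
    global_percent_identity(query, db$sequences[[id]], ...)
  }, numeric(1))
  best <- ids[which.max(pid)]
  data.frame(best_ref = best,
             percent_identity = unname(pid[best]),
             is_potential_predator = unname(pid[best]) >= threshold,
             row.names = NULL)
}

#' Screen a batch of query sequences for potential predators
#'
#' @param queries Named character vector or `Biostrings::DNAStringSet` of
#'   query sequences (e.g. OTU/ASV representative 16S sequences).
#' @param db A [predator_db()].
#' @param threshold Percent-identity threshold (default 94.5, inclusive).
#' @param query_taxonomy Optional named character vector giving a taxonomy
#'   group per query; when absent the best-hit reference taxonomy is used
#'   for the per-group summary.
#' @param ... Scoring parameters passed down.
#' @return A list of class `predator_screen` with `hits` (one row per query:
#'   `query`, `best_ref`, `percent_identity`, `is_potential_predator`,
#'   `group`, `error`) and `summary` (per-group counts of screened queries
#'   and potential predators). Per-sequence input errors are reported in the
#'   `error` column rather than aborting the batch.
#' @export
screen_batch <- function(queries, db, threshold = 94.5,
                         query_taxonomy = NULL, ...) {
  if (inherits(queries, "XStringSet")) {
    queries <- stats::setNames(as.character(queries), names(queries))
  }
  stopifnot(is.character(queries))
  if (length(queries) == 0L) stop("no query sequences supplied")
  if (is.null(names(queries))) {
    names(queries) <- paste0("query", seq_along(queries))
  }
  rows <- lapply(names(queries), function(qid) {
    hit <- try(classify_predator(queries[[qid]], db, threshold, ...),
               silent = TRUE)
    if (inherits(hit, "try-error")) {
      data.frame(query = qid, best_ref = NA_character_,
                 percent_identity = NA_real_, is_potential_predator = NA,
                 error = trimws(attr(hit, "condition")$message),
                 row.names = NULL)
    } else {
      data.frame(query = qid, hit, error = NA_character_, row.names = NULL)
    }
  })
  hits <- do.call(rbind, rows)
  hits$group <- if (!is.null(query_taxonomy)) {
    unname(query_taxonomy[hits$query])
  } else {
    unname(db$taxonomy[hits$best_ref])
  }
  ok <- hits[!is.na(hits$is_potential_predator), , drop = FALSE]
  grp <- if (nrow(ok)) ifelse(is.na(ok$group) | ok$group == "",
                              "(ungrouped)", ok$group) else character()
  summary <- if (nrow(ok)) {
    agg <- stats::aggregate(list(n_queries = rep(1L, nrow(ok)),
                                 n_potential_predators =
                                   as.integer(ok$is_potential_predator)),
                            by = list(group = grp), FUN = sum)
    agg[order(agg$group), , drop = FALSE]
  } else {
    data.frame(group = character(), n_queries = integer(),
               n_potential_predators = integer())
  }
  structure(list(hits = hits, summary = summary, threshold = threshold),
            class = "predator_screen")
}

#' @export
print.predator_screen <- function(x, ...) {
  n <- nrow(x$hits)
  np <- sum(x$hits$is_potential_predator, na.rm = TRUE)
  cat("Predator screen:", n, "queries,", np,
      sprintf("potential predators (identity >= %.1f%%)\n", x$threshold))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
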