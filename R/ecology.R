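#' Activity ratio of a taxon (rRNA : rRNA-gene relative abundance)
#'
#' The ratio of transcript-based to gene-based relative abundance is a
#' common proxy for per-capita metabolic activity: values well above 1
#' indicate taxa over-represented among active ribosomes relative to their
#' genomic abundance.
#'
#' @param rna_relab,dna_relab Proportions in `[0, 1]`.
#' @return `rna_relab / dna_relab`, or `NA` where `dna_relab` is zero.
#' @examples
#' activity_ratio(0.175, 0.054)
#' @export
activity_ratio <- function(rna_relab, dna_relab) {
  if (any(rna_relab < 0 | rna_relab > 1, na.rm = TRUE) ||
      any(dna_relab < 0 | dna_relab > 1, na.rm = TRUE)) {
    stop("relative abundances must lie in [0, 1]")
  }
  out <- rna_relab / dna_relab
  out[dna_relab == 0] <- NA_real_
  out
}

#' Spearman rank correlation with small-sample exact p-values
#'
#' Computes the Spearman coefficient (Pearson correlation of mid-ranks) and
#' a two-sided p-value: the exact permutation null for `n <= 10` without
#' ties, otherwise the t-distribution approximation. In the presence of
#' ties the approximation is used and noted.
#'
#' @param x,y Equal-length numeric vectors (`NA` pairs dropped).
#' @return List: `rho`, `p`, `n`, `note` (`NA` or a reason such as
#'   `"constant input"` / `"ties: approximate p"`).
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) {
    return(list(rho = NA_real_, p = NA_real_, n = n, note = "n < 4"))
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p = NA_real_, n = n, note = "constant input"))
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- n <= 10L && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       note = if (ties && n <= 10L) "ties: approximate p" else NA_character_)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment (via [stats::p.adjust()]) with input
#' validation; output order corresponds to input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Two-group comparison (Mann-Whitney U / Wilcoxon signed-rank)
#'
#' Two-sided rank test: Mann-Whitney U for independent samples, Wilcoxon
#' signed-rank for paired samples. The exact null distribution is used for
#' small samples (`n <= 12` per group) without ties; otherwise the normal
#' approximation with continuity and tie correction. Identical paired
#' samples (all differences zero) return `p = 1`.
#'
#' @param a,b Numeric vectors.
#' @param paired Paired test? Requires equal lengths.
#' @return List: `statistic`, `p`, `method`, `note`.
#' @export
group_compare <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    if (length(a) < 5L) stop("paired test requires n >= 5")
    if (all(a == b)) {
      return(list(statistic = 0, p = 1,
                  method = "Wilcoxon signed rank", note = "all differences zero"))
    }
    nmax <- length(a)
  } else {
    if (length(a) < 3L || length(b) < 3L) {
      stop("unpaired test requires n >= 3 per group")
    }
    nmax <- max(length(a), length(b))
  }
  d <- if (paired) a - b else c(a, b)
  ties <- anyDuplicated(if (paired) abs(d[d != 0]) else d) > 0L
  exact <- nmax <= 12L && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, method = wt$method,
       note = if (ties && nmax <= 12L) "ties: approximate p" else NA_character_)
}

#' Correlate taxon abundances with sample variables, FDR-controlled
#'
#' Spearman rank correlation of every taxon x variable pair with
#' pairwise-complete-case handling, Benjamini-Hochberg adjustment within the
#' chosen family, and significance at `p_adj < alpha`. Mirrors the standard
#' abundance-vs-performance screen of wastewater microbiome surveys, where
#' each performance metric has its own sample coverage (hence per-pair `n`).
#'
#' @param abundance Numeric matrix, taxa x samples (row names = taxa).
#' @param metadata Data frame or matrix, samples x variables (row names =
#'   samples, matching `colnames(abundance)`).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param family BH family: `"per_variable"` (default; each variable
#'   corrected across taxa) or `"global"` (one family over all pairs).
#' @param min_n Minimum overlapping samples per pair (default 4).
#' @return Data frame: `taxon`, `variable`, `n`, `rho`, `p`, `p_adj`,
#'   `significant`. Pairs skipped for constant input or insufficient overlap
#'   are recorded in `attr(, "skipped")` with a reason.
#' @export
correlation_screen <- function(abundance, metadata, alpha = 0.05,
                               family = c("per_variable", "global"),
                               min_n = 4L) {
  family <- match.arg(family)
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)))
  metadata <- as.data.frame(metadata)
  common <- intersect(colnames(abundance), rownames(metadata))
  if (length(common) == 0L) stop("no overlapping samples between tables")
  abundance <- abundance[, common, drop = FALSE]
  metadata <- metadata[common, , drop = FALSE]

  rows <- list(); skipped <- list()
  for (v in colnames(metadata)) {
    mv <- metadata[[v]]
    for (t in rownames(abundance)) {
      r <- spearman_assoc(abundance[t, ], mv)
      if (is.na(r$rho)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(taxon = t, variable = v, reason = r$note)
        next
      }
      if (r$n < min_n) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(taxon = t, variable = v, reason = "insufficient overlap")
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(taxon = t, variable = v, n = r$n, rho = r$rho, p = r$p)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(), variable = character(), n = integer(),
               rho = numeric(), p = numeric())
  if (nrow(res)) {
    res$p_adj <- if (family == "global") bh_adjust(res$p) else
      stats::ave(res$p, res$variable, FUN = bh_adjust)
    res$significant <- res$p_adj < alpha
  } else {
    res$p_adj <- numeric(); res$significant <- logical()
  }
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  res
}
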