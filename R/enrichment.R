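#' Filter and labeling configuration for enrichment-factor analysis
#'
#' Thresholds follow the printed rules of SIP incorporator identification:
#' genera must exceed 1% and ASVs 0.1% relative read abundance in the heavy
#' rRNA fraction of at least one 13C treatment x timepoint (strict `>`), and
#' taxa with an enrichment factor strictly greater than `ef_threshold` are
#' called 13C-labeled. `pseudocount` reads are added per taxon before
#' normalizing the selected fractions, keeping the heavy/light abundance
#' ratios finite; with `pseudocount = 0` a zero light-fraction abundance
#' yields status `undefined_ratio` instead of an enrichment factor.
#'
#' @param genus_min_heavy_relab Genus-level heavy-fraction filter (default 0.01).
#' @param asv_min_heavy_relab ASV-level heavy-fraction filter (default 0.001).
#' @param ef_threshold Labeling threshold on the enrichment factor (default 0.1).
#' @param pseudocount Reads added per taxon per selected fraction (default 0.5).
#' @return A `filter_config` list.
#' @export
filter_config <- function(genus_min_heavy_relab = 0.01,
                          asv_min_heavy_relab = 0.001,
                          ef_threshold = 0.1,
                          pseudocount = 0.5) {
  stopifnot(genus_min_heavy_relab > 0, asv_min_heavy_relab > 0, ef_threshold > 0,
            pseudocount >= 0)
  structure(list(genus_min_heavy_relab = genus_min_heavy_relab,
                 asv_min_heavy_relab = asv_min_heavy_relab,
                 ef_threshold = ef_threshold,
                 pseudocount = pseudocount),
            class = "filter_config")
}

#' Relative abundance of taxa in one fraction
#'
#' @param counts Named numeric vector (or 1-column matrix) of non-negative
#'   read counts.
#' @param pseudocount Reads added to every taxon before normalization;
#'   `0` gives plain proportions.
#' @return Named numeric vector summing to 1.
#' @examples
#' relative_abundance(c(A = 90, B = 10), pseudocount = 0)
#' @export
relative_abundance <- function(counts, pseudocount = 0.5) {
  counts <- drop(as.matrix(counts))
  if (length(counts) == 0L) stop("degenerate input: empty count table")
  if (any(counts < 0)) stop("counts must be non-negative")
  x <- counts + pseudocount
  tot <- sum(x)
  if (tot <= 0) stop("degenerate input: all counts zero and pseudocount 0")
  x / tot
}

#' Enrichment factor from paired heavy/light relative abundances
#'
#' The enrichment factor of a taxon is the heavy:light relative-abundance
#' ratio in the 13C treatment minus the same ratio in the 12C control:
#' `EF = r13H/r13L - r12H/r12L`. Values may be negative; a zero light
#' abundance makes the corresponding ratio undefined and returns `NA`.
#'
#' @param r13H,r13L Relative abundance in the heavy and light fraction of the
#'   13C gradient.
#' @param r12H,r12L Same for the paired 12C gradient.
#' @return Numeric vector of enrichment factors (`NA` where undefined).
#' @examples
#' enrichment_factor(0.30, 0.10, 0.05, 0.05)  # 2
#' @export
enrichment_factor <- function(r13H, r13L, r12H, r12L) {
  ef <- r13H / r13L - r12H / r12L
  ef[r13L <= 0 | r12L <= 0] <- NA_real_
  ef
}

#' Heavy-fraction abundance filter
#'
#' A taxon enters enrichment-factor analysis only if its relative read
#' abundance in the heavy rRNA fraction of at least one 13C treatment x
#' timepoint strictly exceeds the level-appropriate threshold (1% for
#' genera, 0.1% for ASVs).
#'
#' @param heavy_relabs Numeric vector: the taxon's relative abundance in each
#'   available 13C heavy fraction (one per treatment x timepoint).
#' @param level `"genus"` or `"ASV"`.
#' @param cfg A [filter_config()].
#' @return Logical scalar.
#' @export
passes_abundance_filter <- function(heavy_relabs, level = c("genus", "ASV"),
                                    cfg = filter_config()) {
  level <- match.arg(level)
  if (length(heavy_relabs) == 0L) stop("no 13C heavy fraction available")
  thr <- if (level == "genus") cfg$genus_min_heavy_relab else cfg$asv_min_heavy_relab
  any(heavy_relabs > thr)
}

#' Call a taxon 13C-labeled from its enrichment factor
#'
#' Strict inequality: `ef > threshold`. `NA` enrichment factors give `NA`.
#'
#' @param ef Numeric vector of enrichment factors.
#' @param threshold Labeling threshold (default 0.1).
#' @return Logical vector.
#' @export
call_labeled <- function(ef, threshold = 0.1) {
  ef > threshold
}

#' Floor enrichment factors for display
#'
#' For visualization only: negative and very small positive enrichment
#' factors are clipped to `10^-1.5` so that they can be drawn on a log
#' scale. Never used for labeling calls.
#'
#' @param ef Numeric vector.
#' @param floor Display floor (default `10^-1.5`).
#' @return `pmax(ef, floor)`.
#' @export
display_floor <- function(ef, floor = 10^-1.5) {
  pmax(ef, floor)
}

#' Aggregate an ASV count table to genus level
#'
#' Sums member-ASV counts per genus; column totals are conserved exactly.
#' ASVs without a genus assignment are pooled under
#' `"unclassified:<highest resolved rank>"` (the `family` column when
#' present, otherwise `"unknown"`); the same placeholder applies to ASVs
#' absent from the taxonomy map.
#'
#' @param counts Integer matrix, ASVs x fractions, with ASV row names.
#' @param taxonomy Data frame with columns `taxon`, `genus` and optionally
#'   `family` (`NA` genus allowed).
#' @return Numeric matrix, genera x fractions.
#' @export
aggregate_to_genus <- function(counts, taxonomy) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  need <- c("taxon", "genus")
  if (!all(need %in% names(taxonomy))) {
    stop("taxonomy must have columns 'taxon' and 'genus'")
  }
  idx <- match(rownames(counts), taxonomy$taxon)
  genus <- as.character(taxonomy$genus[idx])
  fam <- if ("family" %in% names(taxonomy)) as.character(taxonomy$family[idx]) else NA_character_
  fallback <- ifelse(is.na(fam) | fam == "", "unknown", fam)
  genus <- ifelse(is.na(idx) , "unclassified:unknown",
                  ifelse(is.na(genus) | genus == "",
                         paste0("unclassified:", fallback), genus))
  rowsum(counts, group = genus, reorder = TRUE)
}

# Selected heavy/light representative fractions of one gradient, as a list of
# count vectors keyed by window label. Errors propagate (window-empty) unless
# soft = TRUE, in which case NULL is returned.
select_pair <- function(gid, fractions, counts, heavy, light, policy, soft = FALSE) {
  fr <- fractions[fractions$gradient_id == gid, , drop = FALSE]
  res <- try({
    h <- select_representative(fr, heavy, policy)
    l <- select_representative(fr, light, policy)
    hkey <- paste0(gid, ":", h$fraction_index)
    lkey <- paste0(gid, ":", l$fraction_index)
    if (!all(c(hkey, lkey) %in% colnames(counts))) {
      stop("count table lacks column '", hkey, "' or '", lkey, "'")
    }
    list(heavy = counts[, hkey], light = counts[, lkey],
         heavy_key = hkey, light_key = lkey)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    if (soft) return(NULL)
    stop(attr(res, "condition")$message)
  }
  if (soft && sum(res$heavy) == 0) return(NULL)  # no usable heavy reads
  res
}

#' Enrichment-factor table across a paired 13C/12C SIP experiment
#'
#' For every prey x timepoint group, the representative heavy and light
#' fractions of the 13C gradient and of its paired 12C gradient are selected,
#' relative abundances computed (with `cfg$pseudocount`), the heavy-fraction
#' abundance filter applied across all 13C groups, and per-taxon enrichment
#' factors and labeling calls produced at ASV and (if a taxonomy map is
#' given) genus level. Groups whose 12C counterpart is absent or yields no
#' usable heavy-fraction data are retained with status `"missing_12C"` and no
#' enrichment factor. The abundance filter itself is evaluated on plain
#' (pseudocount-free) read proportions of the 13C heavy fractions.
#'
#' @param experiment A `sip_experiment` (see [simulate_experiment()]) or any
#'   list with elements `counts` (ASV x fraction-key matrix, keys
#'   `"gradient_id:fraction_index"`), `fractions` (data frame:
#'   `gradient_id`, `fraction_index`, `density`, `copies`) and `meta`
#'   (data frame: `gradient_id`, `treatment`, `prey`, `timepoint`).
#' @param taxonomy Optional ASV -> genus map (see [aggregate_to_genus()]);
#'   when supplied genus-level records are appended.
#' @param cfg A [filter_config()].
#' @param heavy,light Density windows.
#' @param policy Representative-fraction policy, see [select_representative()].
#' @return Data frame with one row per filter-passing taxon x group:
#'   `taxon`, `level`, `prey`, `timepoint`, `r13H`, `r13L`, `r12H`, `r12L`,
#'   `ef`, `passed_filter`, `labeled`, `status`.
#' @export
ef_table <- function(experiment, taxonomy = NULL, cfg = filter_config(),
                     heavy = heavy_window(), light = light_window(),
                     policy = c("max_copies", "mid_density")) {
  policy <- match.arg(policy)
  check_windows(heavy, light)
  counts <- experiment$counts
  fractions <- experiment$fractions
  meta <- experiment$meta
  stopifnot(is.matrix(counts), is.data.frame(fractions), is.data.frame(meta))

  c13 <- meta[meta$treatment == "C13", , drop = FALSE]
  if (nrow(c13) == 0L) stop("empty experiment: no 13C gradients present")

  levels_list <- list(ASV = counts)
  if (!is.null(taxonomy)) {
    levels_list$genus <- aggregate_to_genus(counts, taxonomy)
  }

  out <- list()
  for (lev in names(levels_list)) {
    lcounts <- levels_list[[lev]]
    # representative fractions of every 13C group
    pairs13 <- lapply(c13$gradient_id, select_pair, fractions = fractions,
                      counts = lcounts, heavy = heavy, light = light,
                      policy = policy)
    names(pairs13) <- c13$gradient_id
    # filter on plain heavy-fraction read proportions across all 13C groups
    heavy_rel <- vapply(pairs13, function(p) relative_abundance(p$heavy, 0),
                        numeric(nrow(lcounts)))
    heavy_rel <- matrix(heavy_rel, nrow = nrow(lcounts),
                        dimnames = list(rownames(lcounts), c13$gradient_id))
    thr <- if (lev == "genus") cfg$genus_min_heavy_relab else cfg$asv_min_heavy_relab
    pass <- apply(heavy_rel > thr, 1L, any)
    keep <- rownames(lcounts)[pass]
    if (length(keep) == 0L) next

    for (g in seq_len(nrow(c13))) {
      gid <- c13$gradient_id[g]
      p13 <- pairs13[[gid]]
      r13H <- relative_abundance(p13$heavy, cfg$pseudocount)
      r13L <- relative_abundance(p13$light, cfg$pseudocount)
      # paired 12C gradient for the same prey x timepoint
      m12 <- meta[meta$treatment == "C12" & meta$prey == c13$prey[g] &
                    meta$timepoint == c13$timepoint[g], , drop = FALSE]
      p12 <- if (nrow(m12)) {
        select_pair(m12$gradient_id[1L], fractions, lcounts, heavy, light,
                    policy, soft = TRUE)
      } else NULL
      if (is.null(p12)) {
        rec <- data.frame(taxon = keep, level = lev, prey = c13$prey[g],
                          timepoint = c13$timepoint[g],
                          r13H = r13H[keep], r13L = r13L[keep],
                          r12H = NA_real_, r12L = NA_real_, ef = NA_real_,
                          passed_filter = TRUE, labeled = NA,
                          status = "missing_12C", row.names = NULL)
      } else {
        r12H <- relative_abundance(p12$heavy, cfg$pseudocount)
        r12L <- relative_abundance(p12$light, cfg$pseudocount)
        ef <- enrichment_factor(r13H[keep], r13L[keep], r12H[keep], r12L[keep])
        status <- ifelse(is.na(ef), "undefined_ratio", "ok")
        rec <- data.frame(taxon = keep, level = lev, prey = c13$prey[g],
                          timepoint = c13$timepoint[g],
                          r13H = r13H[keep], r13L = r13L[keep],
                          r12H = r12H[keep], r12L = r12L[keep], ef = ef,
                          passed_filter = TRUE,
                          labeled = ifelse(is.na(ef), NA,
                                           call_labeled(ef, cfg$ef_threshold)),
                          status = status, row.names = NULL)
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  if (length(out) == 0L) {
    return(data.frame(taxon = character(), level = character(),
                      prey = character(), timepoint = numeric(),
                      r13H = numeric(), r13L = numeric(), r12H = numeric(),
                      r12L = numeric(), ef = numeric(),
                      passed_filter = logical(), labeled = logical(),
                      status = character()))
  }
  do.call(rbind, out)
}

#' Summarize enrichment factors across time and treatments
#'
#' Arithmetic mean of the enrichment factor per taxon over all status-`ok`
#' records (groups lacking usable 12C data are excluded, not imputed),
#' together with the maximum and the number of groups in which the taxon was
#' called labeled.
#'
#' @param ef A data frame from [ef_table()].
#' @param level Which level to summarize (default `"genus"` when present).
#' @return Data frame: `taxon`, `n_groups`, `mean_ef`, `max_ef`, `n_labeled`.
#' @export
summarize_ef <- function(ef, level = NULL) {
  if (is.null(level)) {
    level <- if ("genus" %in% ef$level) "genus" else ef$level[1L]
  }
  ok <- ef[ef$level == level & ef$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) {
    return(data.frame(taxon = character(), n_groups = integer(),
                      mean_ef = numeric(), max_ef = numeric(),
                      n_labeled = integer()))
  }
  sp <- split(ok, ok$taxon)
  res <- data.frame(
    taxon = names(sp),
    n_groups = vapply(sp, nrow, integer(1)),
    mean_ef = vapply(sp, function(d) mean(d$ef), numeric(1)),
    max_ef = vapply(sp, function(d) max(d$ef), numeric(1)),
    n_labeled = vapply(sp, function(d) sum(d$labeled), integer(1)),
    row.names = NULL)
  res[order(-res$mean_ef), , drop = FALSE]
}
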