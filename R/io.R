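# Format numerics for stable, lossless-enough TSV output (12 significant
# digits, no scientific-notation surprises across runs on one platform).
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

write_tsv_with_header <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    chr <- lapply(df, as.character)  # no format() padding
    writeLines(do.call(paste, c(chr, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a taxon x fraction count table from TSV
#'
#' The table must have a header row of fraction keys
#' (`"gradient_id:fraction_index"`), a first column of taxon ids, and
#' non-negative integer cells. Lines starting with `#` are ignored.
#' Duplicate taxon ids and non-integer cells are rejected with the offending
#' location named.
#'
#' @param path TSV path.
#' @return Integer matrix, taxa x fractions.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("count table '", path, "' has no data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  keys <- header[-1L]
  if (anyDuplicated(keys)) stop("duplicate fraction keys in header of ", path)
  nc <- length(header)
  taxa <- character(length(cells) - 1L)
  mat <- matrix(0L, nrow = length(cells) - 1L, ncol = nc - 1L)
  for (i in seq_along(cells)[-1L]) {
    row <- cells[[i]]
    if (length(row) != nc) {
      stop("row ", i, " of ", path, " has ", length(row),
           " fields, expected ", nc)
    }
    taxa[i - 1L] <- row[1L]
    vals <- row[-1L]
    bad <- !grepl("^[0-9]+$", vals)
    if (any(bad)) {
      j <- which(bad)[1L]
      stop("non-integer count '", vals[j], "' at row ", i, " (taxon '",
           row[1L], "'), column '", keys[j], "' of ", path)
    }
    mat[i - 1L, ] <- as.integer(vals)
  }
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon id '", taxa[anyDuplicated(taxa)], "' in ", path)
  }
  dimnames(mat) <- list(taxa, keys)
  mat
}

#' Write a taxon x fraction count table to TSV
#'
#' @param counts Integer matrix, taxa x fractions.
#' @param path Output path.
#' @param header_lines Optional comment lines (written prefixed with `# `).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, header_lines = character()) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- data.frame(taxon = rownames(counts), counts, check.names = FALSE)
  write_tsv_with_header(df, path, header_lines)
}

#' Read fraction metadata (densities and qPCR copies) from TSV
#'
#' Expects columns `gradient_id`, `fraction_index`, `density`, `copies`;
#' `#`-prefixed lines are ignored.
#'
#' @param path TSV path.
#' @return Data frame validated as in [select_representative()].
#' @export
read_fraction_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  check_fractions_df(df)
  df
}

#' Read gradient metadata (treatment, prey, timepoint) from TSV
#'
#' Expects columns `gradient_id`, `treatment`, `prey`, `timepoint`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_gradient_meta <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gradient_id", "treatment", "prey", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gradient metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !df$treatment %in% c("C13", "C12", "control")
  if (any(bad)) stop("unknown treatment '", df$treatment[bad][1L], "' in ", path)
  if (any((df$treatment == "control") != (df$prey == "none"))) {
    stop("prey must be 'none' if and only if treatment is 'control'")
  }
  df
}

#' Read a taxonomy map (taxon, genus, optional family) from TSV
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("taxon", "genus") %in% names(df))) {
    stop("taxonomy table needs columns 'taxon' and 'genus'")
  }
  df
}

#' Read nucleotide sequences from FASTA
#'
#' Ids are the first whitespace-delimited token of each header. Sequences
#' are upper-cased and RNA `U` normalized to `T` (noted via a message);
#' empty files and duplicate ids are rejected.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id '", ids[anyDuplicated(ids)], "' in ", path)
  }
  seqs <- as.character(set)
  if (any(grepl("[Uu]", seqs))) {
    message("RNA alphabet detected in ", path, ": normalizing U to T")
  }
  stats::setNames(vapply(seqs, normalize_sequence, character(1),
                         what = paste0("sequence in ", path),
                         USE.NAMES = FALSE), ids)
}

#' Assemble a pipeline run configuration
#'
#' @param counts,fractions,meta Paths to the count table, fraction metadata
#'   and gradient metadata TSVs (required).
#' @param taxonomy Optional taxonomy TSV (enables genus-level records).
#' @param query_fasta,ref_fasta Optional FASTA paths enabling the predator
#'   screen (queries and verified-predator references).
#' @param ref_taxonomy Optional two-column TSV (`id`, `taxonomy`) for the
#'   reference database.
#' @param abundance,metadata Optional TSV paths (taxa x samples and samples
#'   x variables) enabling the correlation screen.
#' @param heavy,light Density windows.
#' @param filter A [filter_config()].
#' @param policy Representative-fraction policy.
#' @param predator_threshold Percent-identity threshold (default 94.5).
#' @param alpha Significance level of the correlation screen.
#' @param bh_family BH family, see [correlation_screen()].
#' @param seed Integer seed recorded in every output header.
#' @param out_dir Output directory (created if absent).
#' @return A `sip_run_config` list.
#' @export
run_config <- function(counts, fractions, meta, taxonomy = NULL,
                       query_fasta = NULL, ref_fasta = NULL,
                       ref_taxonomy = NULL, abundance = NULL, metadata = NULL,
                       heavy = heavy_window(), light = light_window(),
                       filter = filter_config(),
                       policy = c("max_copies", "mid_density"),
                       predator_threshold = 94.5, alpha = 0.05,
                       bh_family = c("per_variable", "global"),
                       seed = 1L, out_dir = tempfile("predsip_run_")) {
  policy <- match.arg(policy)
  bh_family <- match.arg(bh_family)
  paths <- list(counts = counts, fractions = fractions, meta = meta,
                taxonomy = taxonomy, query_fasta = query_fasta,
                ref_fasta = ref_fasta, ref_taxonomy = ref_taxonomy,
                abundance = abundance, metadata = metadata)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input file for '", nm, "' does not exist: ", p)
    }
  }
  structure(c(paths, list(heavy = heavy, light = light, filter = filter,
                          policy = policy,
                          predator_threshold = predator_threshold,
                          alpha = alpha, bh_family = bh_family,
                          seed = as.integer(seed), out_dir = out_dir)),
            class = "sip_run_config")
}

config_hash <- function(cfg) {
  fields <- c(unlist(cfg$heavy), unlist(cfg$light), unlist(cfg$filter),
              cfg$policy, cfg$predator_threshold, cfg$alpha, cfg$bh_family,
              cfg$seed)
  sprintf("%08x", string_hash(paste(names(fields), fields, collapse = ";")))
}

#' Run the end-to-end SIP analysis pipeline
#'
#' Executes representative-fraction selection, enrichment-factor
#' computation and labeling calls, then (when the corresponding inputs are
#' configured) the predator identity screen and the abundance-vs-variable
#' correlation screen. Writes `ef.tsv`, optionally `predators.tsv` and
#' `correlations.tsv`, and a JSON run manifest recording inputs,
#' configuration hash, seed, package version and any prey x timepoint group
#' lacking usable 12C heavy-fraction data. Identical inputs and
#' configuration produce byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with elements `ef`, `predators`,
#'   `correlations`, `manifest` and `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "sip_run_config"))
  check_windows(cfg$heavy, cfg$light)  # abort on bad config before any work

  counts <- read_count_table(cfg$counts)
  fractions <- read_fraction_table(cfg$fractions)
  meta <- read_gradient_meta(cfg$meta)
  taxonomy <- if (!is.null(cfg$taxonomy)) read_taxonomy(cfg$taxonomy)

  experiment <- list(counts = counts, fractions = fractions, meta = meta)
  ef <- ef_table(experiment, taxonomy = taxonomy, cfg = cfg$filter,
                 heavy = cfg$heavy, light = cfg$light, policy = cfg$policy)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  hdr <- c(paste0("predsip enrichment-factor table"),
           paste0("config_hash: ", hash),
           paste0("seed: ", cfg$seed))
  ef_out <- ef
  for (col in c("r13H", "r13L", "r12H", "r12L", "ef")) {
    ef_out[[col]] <- fmt_num(ef[[col]])
  }
  ef_path <- file.path(cfg$out_dir, "ef.tsv")
  write_tsv_with_header(ef_out, ef_path, hdr)

  missing12 <- unique(ef[ef$status == "missing_12C",
                         c("prey", "timepoint"), drop = FALSE])
  outputs <- list(ef = "ef.tsv")

  predators <- NULL
  if (!is.null(cfg$query_fasta) && !is.null(cfg$ref_fasta)) {
    refs <- read_fasta_seqs(cfg$ref_fasta)
    ref_tax <- NULL
    if (!is.null(cfg$ref_taxonomy)) {
      tt <- utils::read.delim(cfg$ref_taxonomy, comment.char = "#",
                              stringsAsFactors = FALSE)
      ref_tax <- stats::setNames(tt[[2L]], tt[[1L]])
    }
    db <- predator_db(refs, taxonomy = ref_tax,
                      provenance = basename(cfg$ref_fasta))
    queries <- read_fasta_seqs(cfg$query_fasta)
    predators <- screen_batch(queries, db, threshold = cfg$predator_threshold)
    pr <- predators$hits
    pr$percent_identity <- fmt_num(pr$percent_identity)
    prd_path <- file.path(cfg$out_dir, "predators.tsv")
    write_tsv_with_header(
      pr, prd_path, c("predsip predator screen",
                      paste0("config_hash: ", hash),
                      paste0("seed: ", cfg$seed)))
    outputs$predators <- "predators.tsv"
  }

  correlations <- NULL
  if (!is.null(cfg$abundance) && !is.null(cfg$metadata)) {
    ab <- as.matrix(utils::read.delim(cfg$abundance, comment.char = "#",
                                      row.names = 1L, check.names = FALSE))
    md <- utils::read.delim(cfg$metadata, comment.char = "#",
                            row.names = 1L, check.names = FALSE)
    correlations <- correlation_screen(ab, md, alpha = cfg$alpha,
                                       family = cfg$bh_family)
    cr <- correlations
    for (col in c("rho", "p", "p_adj")) cr[[col]] <- fmt_num(cr[[col]])
    cor_path <- file.path(cfg$out_dir, "correlations.tsv")
    write_tsv_with_header(
      cr, cor_path, c("predsip correlation screen",
                      paste0("config_hash: ", hash),
                      paste0("seed: ", cfg$seed)))
    outputs$correlations <- "correlations.tsv"
  }

  manifest <- list(
    package = "predsip",
    version = as.character(utils::packageVersion("predsip")),
    seed = cfg$seed,
    config_hash = hash,
    inputs = lapply(Filter(Negate(is.null),
                           cfg[c("counts", "fractions", "meta", "taxonomy",
                                 "query_fasta", "ref_fasta", "ref_taxonomy",
                                 "abundance", "metadata")]),
                    basename),
    settings = list(
      heavy = unclass(cfg$heavy), light = unclass(cfg$light),
      filter = unclass(cfg$filter), policy = cfg$policy,
      predator_threshold = cfg$predator_threshold, alpha = cfg$alpha,
      bh_family = cfg$bh_family),
    n_ef_records = nrow(ef),
    n_labeled = sum(ef$labeled, na.rm = TRUE),
    missing_12C_groups = if (nrow(missing12)) {
      lapply(seq_len(nrow(missing12)), function(i) {
        list(prey = missing12$prey[i], timepoint = missing12$timepoint[i])
      })
    } else list(),
    outputs = outputs)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(ef = ef, predators = predators, correlations = correlations,
                 manifest = manifest,
                 paths = list(ef = ef_path, manifest = manifest_path,
                              out_dir = cfg$out_dir)))
}
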