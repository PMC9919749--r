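# Deterministic 31-bit polynomial string hash; used to derive per-gradient
# RNG streams from one experiment seed and to fingerprint configurations.
string_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(paste(x, collapse = "|"))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) + string_hash(salt)) %% 2147483647)
}

#' Configuration of the SIP gradient simulator
#'
#' Defaults emulate the study conditions of an rRNA-SIP predation
#' experiment: 13 fractions per isopycnic gradient spanning 1.780-1.900
#' g/ml; unlabeled rRNA banding at `mu0 = 1.812` g/ml (inside the light
#' window); a maximal buoyant-density shift of `delta_max = 0.045` g/ml at
#' 100 atom% 13C, so that fully labeled rRNA at `atom_pct = 0.97` label
#' purity bands at ~1.8557 g/ml, inside the heavy window; NovaSeq-scale
#' amplicon depth of 1e5 reads per fraction; and 15% CV log-normal noise on
#' RT-qPCR copy numbers.
#'
#' @param n_taxa Number of community ASVs (prey-spike taxa are added on top).
#' @param reads_per_fraction Sequencing depth per gradient fraction.
#' @param n_fractions Fractions per gradient (default 13).
#' @param grid_lo,grid_hi Density grid bounds (g/ml).
#' @param mu0 Mean buoyant density of unlabeled rRNA (g/ml).
#' @param delta_max Density shift at 100 atom% 13C (g/ml).
#' @param sigma_bd Within-taxon density spread (g/ml).
#' @param atom_pct 13C label purity of the prey biomass (fraction).
#' @param qpcr_noise_cv Coefficient of variation of qPCR copy noise.
#' @param seed Integer seed (required; all outputs are reproducible).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 60, reads_per_fraction = 1e5, n_fractions = 13,
                       grid_lo = 1.780, grid_hi = 1.900, mu0 = 1.812,
                       delta_max = 0.045, sigma_bd = 0.008, atom_pct = 0.97,
                       qpcr_noise_cv = 0.15, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_taxa >= 2, reads_per_fraction > 0, n_fractions >= 2,
            grid_lo < grid_hi, sigma_bd > 0, delta_max > 0,
            atom_pct > 0, atom_pct <= 1, qpcr_noise_cv >= 0)
  if (mu0 <= grid_lo || mu0 + delta_max >= grid_hi) {
    stop("density grid must cover mu0 and mu0 + delta_max")
  }
  lw <- light_window(); hw <- heavy_window()
  if (mu0 < lw$lo || mu0 > lw$hi) {
    stop("mu0 must lie inside the light window [", lw$lo, ", ", lw$hi, "]")
  }
  muH <- mu0 + atom_pct * delta_max
  if (muH < hw$lo || muH > hw$hi) {
    stop("mu0 + atom_pct * delta_max must lie inside the heavy window [",
         hw$lo, ", ", hw$hi, "]")
  }
  structure(list(n_taxa = as.integer(n_taxa),
                 reads_per_fraction = reads_per_fraction,
                 n_fractions = as.integer(n_fractions),
                 grid_lo = grid_lo, grid_hi = grid_hi, mu0 = mu0,
                 delta_max = delta_max, sigma_bd = sigma_bd,
                 atom_pct = atom_pct, qpcr_noise_cv = qpcr_noise_cv,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic integer split of n into role counts proportional to `prop`.
role_counts <- function(prop, n) {
  if (abs(sum(prop) - 1) > 1e-8) stop("role proportions must sum to 1")
  diff(round(cumsum(c(0, prop)) * n))
}

#' Simulate a microbial community with known 13C-incorporation ground truth
#'
#' Baseline relative abundances are drawn from a log-normal distribution and
#' normalized; each taxon receives a trophic role and a 13C-incorporation
#' level `alpha` in `[0, 1]`: predators consume the labeled prey directly
#' (high alpha), cross-feeders acquire label indirectly (intermediate
#' alpha), inactive taxa stay unlabeled (`alpha = 0`). Two prey-spike taxa
#' (the labeled *E. coli* and *P. putida* amendments, `alpha = 1`) are
#' appended; at `t0 = TRUE` the spiked prey draws 40-50% of the community
#' (its share immediately after amendment), otherwise a small residual.
#' Predator baselines are floored at `min_predator_relab` so that planted
#' incorporators sit above the genus-level abundance filter.
#'
#' @param cfg A [sim_config()].
#' @param roles Named proportions over `c(predator, cross_feeder, inactive)`.
#' @param predator_alpha Length-2 range (or single value) of predator alpha.
#' @param cross_alpha Length-2 range of cross-feeder alpha.
#' @param min_predator_relab Baseline floor for predators (default 0.02).
#' @param spike_alpha Incorporation level of the prey-spike taxa (default 1:
#'   the added cells are the labeled biomass; set 0 for a fully unlabeled
#'   global-null scenario).
#' @param t0 Simulate the moment of prey amendment? (default `FALSE`)
#' @param prey_residual_relab Prey-spike baseline when `t0 = FALSE`.
#' @param sdlog Log-normal shape of baseline abundances.
#' @return A `community_truth` object: data frame `taxa` with columns
#'   `taxon`, `genus`, `family`, `baseline_relab`, `alpha`, `role`, `prey`.
#' @export
simulate_community <- function(cfg,
                               roles = c(predator = 0.1, cross_feeder = 0.1,
                                         inactive = 0.8),
                               predator_alpha = c(0.5, 1),
                               cross_alpha = c(0.1, 0.3),
                               min_predator_relab = 0.02, spike_alpha = 1,
                               t0 = FALSE, prey_residual_relab = 0.005,
                               sdlog = 1.2) {
  stopifnot(inherits(cfg, "sim_config"))
  roles <- roles[c("predator", "cross_feeder", "inactive")]
  if (anyNA(roles)) stop("roles must name predator, cross_feeder and inactive")
  set.seed(derive_seed(cfg$seed, "community"))
  n <- cfg$n_taxa
  cnt <- role_counts(roles, n)
  role <- rep(c("predator", "cross_feeder", "inactive"), cnt)
  role <- sample(role)  # shuffle roles over abundance ranks

  w <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
  relab <- w / sum(w)
  is_pred <- role == "predator"
  relab[is_pred] <- pmax(relab[is_pred], min_predator_relab)
  relab <- relab / sum(relab)

  rng <- function(r, k) if (length(r) == 1L) rep(r, k) else stats::runif(k, r[1], r[2])
  alpha <- numeric(n)
  alpha[is_pred] <- rng(predator_alpha, sum(is_pred))
  alpha[role == "cross_feeder"] <- rng(cross_alpha, sum(role == "cross_feeder"))

  taxa <- data.frame(
    taxon = sprintf("ASV%03d", seq_len(n)),
    genus = sprintf("genus%03d", ceiling(seq_len(n) / 2)),
    family = sprintf("family%03d", ceiling(seq_len(n) / 6)),
    baseline_relab = relab, alpha = alpha, role = role,
    prey = NA_character_)

  spike_relab <- if (t0) stats::runif(2, 0.40, 0.50) else
    rep(prey_residual_relab, 2)
  spikes <- data.frame(
    taxon = c("ASV_prey_Ec", "ASV_prey_Pp"),
    genus = c("Escherichia-Shigella", "Pseudomonas"),
    family = c("Enterobacteriaceae", "Pseudomonadaceae"),
    baseline_relab = spike_relab, alpha = spike_alpha,
    role = "prey_spike", prey = c("E_coli", "P_putida"))
  taxa <- rbind(taxa, spikes)
  taxa$baseline_relab <- taxa$baseline_relab / sum(taxa$baseline_relab)
  structure(list(taxa = taxa, cfg_seed = cfg$seed), class = "community_truth")
}

#' Taxonomy map of a simulated community
#'
#' @param truth A `community_truth`.
#' @return Data frame `taxon`, `genus`, `family` usable with
#'   [aggregate_to_genus()] and [ef_table()].
#' @export
taxonomy_of <- function(truth) {
  stopifnot(inherits(truth, "community_truth"))
  truth$taxa[, c("taxon", "genus", "family")]
}

# Per-bin probability mass of Normal(mu, sigma) over the fraction bins,
# computed from upper-tail differences for accuracy far from mu.
bin_mass <- function(edges, mu, sigma) {
  up <- stats::pnorm(edges, mean = mu, sd = sigma, lower.tail = FALSE)
  pmax(up[-length(up)] - up[-1L], 0)
}

#' Simulate one isopycnic gradient
#'
#' Each taxon's rRNA mass distributes over the density grid as a
#' two-component Gaussian mixture: a fraction `1 - alpha_eff` bands at the
#' unlabeled density `mu0` and a fraction `alpha_eff` at
#' `mu0 + atom_pct * delta_max`, where `alpha_eff` is the taxon's
#' incorporation level in 13C treatments and 0 in 12C/control gradients.
#' Reads are drawn multinomially per fraction (fixed sequencing depth,
#' probabilities proportional to baseline relative abundance times in-bin
#' mass, renormalized within the fraction), and RT-qPCR copy numbers are the
#' total in-fraction mass under multiplicative log-normal noise. Fraction
#' densities are the midpoints of an equal-width partition of the grid
#' (half-open bins, last bin closed). Prey-spike taxa not matching the
#' gradient's prey are absent.
#'
#' @param truth A [simulate_community()] result.
#' @param meta List or one-row data frame: `gradient_id`, `treatment`
#'   (`"C13"`, `"C12"` or `"control"`), `prey` (`"E_coli"`, `"P_putida"` or
#'   `"none"`), `timepoint` (hours).
#' @param cfg The [sim_config()] used for `truth`.
#' @return List with `fractions` (data frame: `gradient_id`,
#'   `fraction_index`, `density`, `copies`) and `counts` (taxa x fractions
#'   integer matrix, columns keyed `"gradient_id:fraction_index"`).
#' @export
simulate_gradient <- function(truth, meta, cfg) {
  stopifnot(inherits(truth, "community_truth"), inherits(cfg, "sim_config"))
  meta <- as.list(as.data.frame(meta, stringsAsFactors = FALSE)[1L, ])
  if (!meta$treatment %in% c("C13", "C12", "control")) {
    stop("treatment must be one of C13, C12, control")
  }
  if ((meta$treatment == "control") != (meta$prey == "none")) {
    stop("prey must be 'none' if and only if treatment is 'control'")
  }
  set.seed(derive_seed(cfg$seed, paste0("gradient:", meta$gradient_id)))

  nf <- cfg$n_fractions
  edges <- seq(cfg$grid_lo, cfg$grid_hi, length.out = nf + 1L)
  mids <- (edges[-1L] + edges[-(nf + 1L)]) / 2
  muH <- cfg$mu0 + cfg$atom_pct * cfg$delta_max
  massL <- bin_mass(edges, cfg$mu0, cfg$sigma_bd)
  massH <- bin_mass(edges, muH, cfg$sigma_bd)

  taxa <- truth$taxa
  relab <- taxa$baseline_relab
  drop <- taxa$role == "prey_spike" & taxa$prey != meta$prey
  drop[is.na(taxa$prey) | taxa$prey == ""] <- FALSE
  relab[drop & taxa$role == "prey_spike"] <- 0
  relab[taxa$role == "prey_spike" & meta$prey == "none"] <- 0
  if (sum(relab) <= 0) stop("degenerate community: no taxa present")
  relab <- relab / sum(relab)

  alpha_eff <- if (meta$treatment == "C13") taxa$alpha else rep(0, nrow(taxa))
  M <- outer(relab * (1 - alpha_eff), massL) + outer(relab * alpha_eff, massH)
  rownames(M) <- taxa$taxon

  counts <- matrix(0L, nrow = nrow(taxa), ncol = nf,
                   dimnames = list(taxa$taxon,
                                   paste0(meta$gradient_id, ":", seq_len(nf))))
  for (j in seq_len(nf)) {
    tot <- sum(M[, j])
    pr <- if (tot > 0) M[, j] / tot else rep(1 / nrow(taxa), nrow(taxa))
    counts[, j] <- stats::rmultinom(1L, size = cfg$reads_per_fraction, prob = pr)
  }
  sdlog <- sqrt(log(1 + cfg$qpcr_noise_cv^2))
  copies <- colSums(M) * 1e8 *
    stats::rlnorm(nf, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  fractions <- data.frame(gradient_id = meta$gradient_id,
                          fraction_index = seq_len(nf),
                          density = mids, copies = copies)
  list(fractions = fractions, counts = counts)
}

#' Simulate a full paired 13C/12C SIP experiment
#'
#' Builds one 13C and one 12C gradient per prey x timepoint group (the
#' default design: *E. coli* at 1, 2 and 4 days, *P. putida* at 1 and 4
#' days) from a shared community truth, mirroring a microcosm experiment in
#' which parallel incubations receive labeled and unlabeled prey cells.
#'
#' @param cfg A [sim_config()].
#' @param truth Optional pre-built [simulate_community()]; generated from
#'   `cfg` with `...` passed through when absent.
#' @param groups Data frame with columns `prey`, `timepoint` (hours).
#' @param treatments Character subset of `c("C13", "C12")`.
#' @param ... Passed to [simulate_community()] when `truth` is `NULL`.
#' @return A `sip_experiment`: list with `counts` (taxa x all fraction
#'   keys), `fractions`, `meta` (one row per gradient), `truth`,
#'   `taxonomy` and `cfg`.
#' @export
simulate_experiment <- function(cfg, truth = NULL,
                                groups = data.frame(
                                  prey = c("E_coli", "E_coli", "E_coli",
                                           "P_putida", "P_putida"),
                                  timepoint = c(24, 48, 96, 24, 96)),
                                treatments = c("C13", "C12"), ...) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(truth)) truth <- simulate_community(cfg, ...)
  meta <- do.call(rbind, lapply(treatments, function(tr) {
    data.frame(gradient_id = sprintf("%s_%s_%dh", tr, groups$prey,
                                     groups$timepoint),
               treatment = tr, prey = groups$prey,
               timepoint = groups$timepoint)
  }))
  sims <- lapply(seq_len(nrow(meta)), function(i) {
    simulate_gradient(truth, meta[i, ], cfg)
  })
  structure(list(
    counts = do.call(cbind, lapply(sims, `[[`, "counts")),
    fractions = do.call(rbind, lapply(sims, `[[`, "fractions")),
    meta = meta, truth = truth, taxonomy = taxonomy_of(truth), cfg = cfg),
    class = "sip_experiment")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_sequence <- function(seq, rate, exact = FALSE) {
  ch <- strsplit(seq, "")[[1L]]
  len <- length(ch)
  pos <- if (exact) {
    k <- round(rate * len)
    if (k > len - 2L) stop("too many exact mutations for sequence length")
    sample(2:(len - 1L), k)  # interior sites keep the planted identity exact
  } else {
    which(stats::runif(len) < rate)
  }
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  list(seq = paste(ch, collapse = ""), n_mut = length(pos))
}

#' Simulate 16S-like reference and query sequence sets
#'
#' Generates random reference sequences and queries derived from them by
#' per-site point substitution, with a ground-truth table of source and
#' expected identity. With `exact = TRUE` each query carries exactly
#' `round(rate * length)` substitutions at interior sites, so its true
#' identity to the source is exactly `100 * (1 - n_mut/length)` — useful for
#' pinning behavior at the 94.5% genus boundary.
#'
#' @param n_refs,n_queries Numbers of reference and query sequences.
#' @param length Sequence length (use >= 100 for 16S-scale tests).
#' @param mutation_rates Per-query per-site substitution probability,
#'   recycled to `n_queries`.
#' @param seed Integer seed.
#' @param exact Plant exact substitution counts at interior sites?
#' @param ref_path,query_path Optional FASTA output paths.
#' @return List: `refs`, `queries` (named character vectors), `truth`
#'   (data frame: `query`, `source`, `rate`, `n_mut`, `expected_identity`).
#' @export
simulate_sequences <- function(n_refs, n_queries, length = 1500,
                               mutation_rates = 0.02, seed, exact = FALSE,
                               ref_path = NULL, query_path = NULL) {
  if (missing(seed)) stop("simulate_sequences requires a seed")
  if (any(mutation_rates < 0 | mutation_rates > 1)) {
    stop("mutation rates must lie in [0, 1]")
  }
  set.seed(derive_seed(seed, "sequences"))
  refs <- stats::setNames(random_dna(n_refs, length),
                          sprintf("ref%03d", seq_len(n_refs)))
  rates <- rep_len(mutation_rates, n_queries)
  src <- ((seq_len(n_queries) - 1L) %% n_refs) + 1L
  qs <- character(n_queries); nmut <- integer(n_queries)
  for (i in seq_len(n_queries)) {
    m <- mutate_sequence(refs[[src[i]]], rates[i], exact = exact)
    qs[i] <- m$seq; nmut[i] <- m$n_mut
  }
  queries <- stats::setNames(qs, sprintf("query%03d", seq_len(n_queries)))
  truth <- data.frame(query = names(queries), source = names(refs)[src],
                      rate = rates, n_mut = nmut,
                      expected_identity = 100 * (1 - nmut / length))
  if (!is.null(ref_path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs), ref_path)
  }
  if (!is.null(query_path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(queries), query_path)
  }
  list(refs = refs, queries = queries, truth = truth)
}

#' Simulate sample metadata with planted monotone taxon-variable links
#'
#' Unlinked taxa and variables are mutually independent; each planted link
#' ties a taxon's (log-scale) abundance and a variable to a shared latent
#' factor with noise calibrated so that the expected Spearman correlation
#' approximates the requested strength, with the requested sign.
#'
#' @param n_samples Number of samples.
#' @param n_taxa,n_variables Table dimensions.
#' @param planted_links Data frame with columns `taxon`, `variable`,
#'   `sign` (+1/-1), `strength` in `[0, 1]`.
#' @param seed Integer seed.
#' @return List: `abundance` (taxa x samples matrix), `metadata` (samples x
#'   variables data frame), `truth` (the planted links).
#' @export
simulate_metadata <- function(n_samples, n_taxa = 50, n_variables = 5,
                              planted_links = NULL, seed) {
  if (missing(seed)) stop("simulate_metadata requires a seed")
  set.seed(derive_seed(seed, "metadata"))
  taxa <- sprintf("taxon%03d", seq_len(n_taxa))
  vars <- sprintf("var%d", seq_len(n_variables))
  samples <- sprintf("sample%03d", seq_len(n_samples))

  abundance <- matrix(stats::rlnorm(n_taxa * n_samples, 0, 1),
                      nrow = n_taxa, dimnames = list(taxa, samples))
  metadata <- matrix(stats::rnorm(n_samples * n_variables),
                     nrow = n_samples, dimnames = list(samples, vars))

  if (!is.null(planted_links) && nrow(planted_links)) {
    if (anyDuplicated(planted_links[, c("taxon", "variable")])) {
      stop("duplicate planted taxon-variable pair")
    }
    if (any(planted_links$strength < 0 | planted_links$strength > 1)) {
      stop("link strength must lie in [0, 1]")
    }
    for (i in seq_len(nrow(planted_links))) {
      lk <- planted_links[i, ]
      if (!lk$taxon %in% taxa || !lk$variable %in% vars) {
        stop("planted link names unknown taxon or variable")
      }
      if (lk$strength == 0) next
      z <- stats::rnorm(n_samples)
      tau <- sqrt(1 / lk$strength - 1)
      abundance[lk$taxon, ] <- exp(z + stats::rnorm(n_samples, sd = tau))
      metadata[, lk$variable] <- sign(lk$sign) *
        (z + stats::rnorm(n_samples, sd = tau))
    }
  }
  list(abundance = abundance, metadata = as.data.frame(metadata),
       truth = planted_links)
}
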