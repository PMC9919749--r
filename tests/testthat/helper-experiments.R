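# Construct a minimal paired 13C/12C experiment whose representative
# fractions are forced by construction: the default 13-fraction grid puts
# fraction 4 inside the light window and fractions 9-10 inside the heavy
# window; copies are rigged so selection always picks fraction 9 (heavy)
# and fraction 4 (light). Count vectors for the four selected fractions are
# supplied; all other fractions carry zero reads.
grid_mids <- function(nf = 13, lo = 1.780, hi = 1.900) {
  edges <- seq(lo, hi, length.out = nf + 1)
  (edges[-1] + edges[-(nf + 1)]) / 2
}

make_experiment <- function(c13H, c13L, c12H = NULL, c12L = NULL,
                            prey = "E_coli", timepoint = 24) {
  taxa <- names(c13H)
  stopifnot(!is.null(taxa))
  mids <- grid_mids()
  gradient <- function(gid, h, l) {
    counts <- matrix(0L, nrow = length(taxa), ncol = 13,
                     dimnames = list(taxa, paste0(gid, ":", 1:13)))
    counts[, 9] <- as.integer(h)
    counts[, 4] <- as.integer(l)
    copies <- rep(1, 13)
    copies[9] <- 100; copies[4] <- 100
    list(fractions = data.frame(gradient_id = gid, fraction_index = 1:13,
                                density = mids, copies = copies),
         counts = counts)
  }
  g13 <- gradient(paste0("C13_", prey), c13H, c13L)
  grads <- list(g13)
  meta <- data.frame(gradient_id = paste0("C13_", prey), treatment = "C13",
                     prey = prey, timepoint = timepoint)
  if (!is.null(c12H)) {
    g12 <- gradient(paste0("C12_", prey), c12H, c12L)
    grads <- c(grads, list(g12))
    meta <- rbind(meta, data.frame(gradient_id = paste0("C12_", prey),
                                   treatment = "C12", prey = prey,
                                   timepoint = timepoint))
  }
  list(counts = do.call(cbind, lapply(grads, `[[`, "counts")),
       fractions = do.call(rbind, lapply(grads, `[[`, "fractions")),
       meta = meta)
}

# A small all-unlabeled (global null) experiment for calibration checks.
null_experiment <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  simulate_experiment(cfg, spike_alpha = 0,
                      roles = c(predator = 0, cross_feeder = 0, inactive = 1))
}
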