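#' Define a buoyant-density window
#'
#' A density window delimits the buoyant-density (BD) range, in g/ml, within
#' which gradient fractions are treated as "heavy" (13C-enriched rRNA
#' migrates here) or "light" (unlabeled rRNA). Membership is tested on the
#' closed interval `[lo, hi]`.
#'
#' @param lo,hi Window bounds in g/ml, `lo < hi`.
#' @param label Either `"heavy"` or `"light"`.
#' @return An object of class `density_window` (a named list).
#' @examples
#' heavy_window()
#' density_window(1.84, 1.88, "heavy")
#' @export
density_window <- function(lo, hi, label = c("heavy", "light")) {
  label <- match.arg(label)
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo < hi)) {
    stop("density window requires lo < hi (got lo = ", lo, ", hi = ", hi, ")")
  }
  structure(list(lo = lo, hi = hi, label = label), class = "density_window")
}

#' @rdname density_window
#' @export
heavy_window <- function() density_window(1.851, 1.872, "heavy")

#' @rdname density_window
#' @export
light_window <- function() density_window(1.805, 1.819, "light")

window_midpoint <- function(w) (w$lo + w$hi) / 2

check_windows <- function(heavy, light) {
  stopifnot(inherits(heavy, "density_window"), inherits(light, "density_window"))
  if (heavy$label != "heavy" || light$label != "light") {
    stop("window labels must be 'heavy' and 'light' respectively")
  }
  # closed intervals must not touch or overlap
  if (heavy$lo <= light$hi && light$lo <= heavy$hi) {
    stop("heavy and light density windows overlap: [", light$lo, ", ", light$hi,
         "] vs [", heavy$lo, ", ", heavy$hi, "]")
  }
  invisible(TRUE)
}

#' Classify gradient fractions into heavy/light density windows
#'
#' @param density Numeric vector of fraction buoyant densities (g/ml).
#' @param heavy,light `density_window` objects; defaults are the heavy
#'   (1.851-1.872 g/ml) and light (1.805-1.819 g/ml) windows used for
#'   representative-fraction selection.
#' @return Character vector, one of `"heavy"`, `"light"`, `"neither"` per
#'   input density. Window membership is inclusive of both endpoints.
#' @examples
#' classify_fraction(c(1.860, 1.810, 1.835))
#' @export
classify_fraction <- function(density, heavy = heavy_window(), light = light_window()) {
  check_windows(heavy, light)
  stopifnot(is.numeric(density))
  out <- rep("neither", length(density))
  out[density >= heavy$lo & density <= heavy$hi] <- "heavy"
  out[density >= light$lo & density <= light$hi] <- "light"
  out
}

check_fractions_df <- function(fractions) {
  need <- c("gradient_id", "fraction_index", "density", "copies")
  miss <- setdiff(need, names(fractions))
  if (length(miss)) {
    stop("fraction table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(paste(fractions$gradient_id, fractions$fraction_index))) {
    stop("fraction_index values must be unique within a gradient")
  }
  if (any(fractions$copies < 0)) stop("copies must be non-negative")
  if (any(fractions$density <= 1.70 | fractions$density >= 2.00)) {
    stop("fraction densities outside the plausible range (1.70, 2.00) g/ml")
  }
  invisible(TRUE)
}

#' Select the representative fraction inside a density window
#'
#' One fraction per gradient and window is carried into sequencing-based
#' analysis. The default policy keeps the in-window fraction carrying the
#' most rRNA copies (most informative for sequencing); `mid_density` keeps
#' the fraction closest to the window midpoint, for sensitivity analysis.
#' Ties are broken by density closest to the window midpoint, then by lowest
#' `fraction_index`, so selection is deterministic and permutation-invariant.
#'
#' @param fractions Data frame with columns `gradient_id`, `fraction_index`,
#'   `density`, `copies` (one gradient).
#' @param window A `density_window`.
#' @param policy `"max_copies"` (default) or `"mid_density"`.
#' @return The selected row of `fractions` (a one-row data frame).
#' @export
select_representative <- function(fractions, window,
                                  policy = c("max_copies", "mid_density")) {
  policy <- match.arg(policy)
  check_fractions_df(fractions)
  stopifnot(inherits(window, "density_window"))
  inw <- fractions$density >= window$lo & fractions$density <= window$hi
  if (!any(inw)) {
    stop("window-empty: no fraction of gradient '",
         unique(fractions$gradient_id)[1], "' falls in the ", window$label,
         " window [", window$lo, ", ", window$hi, "] g/ml")
  }
  cand <- fractions[inw, , drop = FALSE]
  dmid <- abs(cand$density - window_midpoint(window))
  ord <- if (policy == "max_copies") {
    order(-cand$copies, dmid, cand$fraction_index)
  } else {
    order(dmid, -cand$copies, cand$fraction_index)
  }
  cand[ord[1L], , drop = FALSE]
}

#' Quantitative distribution of rRNA copies across a gradient
#'
#' Normalizes RT-qPCR 16S copy numbers of the fractions of one gradient to
#' proportions, ordered by `fraction_index`.
#'
#' @param fractions Data frame as in [select_representative()].
#' @return Named numeric vector of proportions (names = fraction_index),
#'   summing to 1.
#' @export
copy_distribution <- function(fractions) {
  check_fractions_df(fractions)
  ord <- order(fractions$fraction_index)
  copies <- fractions$copies[ord]
  tot <- sum(copies)
  if (tot <= 0) {
    stop("degenerate gradient: all fractions have zero 16S copies")
  }
  stats::setNames(copies / tot, fractions$fraction_index[ord])
}
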