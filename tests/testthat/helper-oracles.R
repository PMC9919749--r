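# Independent reference implementations used as test oracles. These are
# deliberately written in a different style from the package code (memoized
# recursion, explicit enumeration) and must never call into it.

# --- Reference ends-free aligner -------------------------------------------
# Best (score, matches, columns) over all ends-free alignments, maximizing
# score, then matches, then minimizing columns. Leading overhangs are free
# (alignment may start at any (i, 0) or (0, j)); the aligned region runs
# until one sequence is exhausted, the rest is a free trailing overhang.
ref_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  acgt <- c("A", "C", "G", "T")
  memo <- new.env(parent = emptyenv())
  better <- function(x, y) {
    # TRUE if x beats y under (score desc, matches desc, columns asc)
    if (x[1] != y[1]) return(x[1] > y[1])
    if (x[2] != y[2]) return(x[2] > y[2])
    x[3] < y[3]
  }
  F <- function(i, j) {
    if (i == n || j == m) return(c(0, 0, 0))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    eq <- A[i + 1] == B[j + 1] && A[i + 1] %in% acgt
    d <- F(i + 1, j + 1) + c(if (eq) match else mismatch, as.integer(eq), 1)
    u <- F(i + 1, j) + c(gap, 0, 1)
    l <- F(i, j + 1) + c(gap, 0, 1)
    best <- d
    if (better(u, best)) best <- u
    if (better(l, best)) best <- l
    memo[[key]] <- best
    best
  }
  best <- c(-Inf, 0, 0)
  for (i in 0:n) {
    v <- F(i, 0)
    if (better(v, best)) best <- v
  }
  for (j in 0:m) {
    v <- F(0, j)
    if (better(v, best)) best <- v
  }
  pid <- if (best[3] > 0) 100 * best[2] / best[3] else 0
  list(score = best[1], matches = best[2], columns = best[3],
       percent_identity = pid)
}

# --- Exact rank-test enumeration -------------------------------------------
# Two-sided Mann-Whitney p by full enumeration of all group assignments,
# following the convention p = min(1, 2 * one-sided tail chosen by the
# observed statistic's side of its null mean).
enum_mann_whitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  U_of <- function(ix) {
    x <- pool[ix]; y <- pool[-ix]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- U_of(seq_len(na))
  combos <- utils::combn(na + nb, na)
  Us <- apply(combos, 2, U_of)
  mu <- na * nb / 2
  p1 <- if (obs > mu) mean(Us >= obs) else mean(Us <= obs)
  min(1, 2 * p1)
}

# Two-sided Wilcoxon signed-rank p by enumeration of all sign assignments.
enum_wilcoxon_signed <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p1 <- if (obs > mu) mean(Vs >= obs) else mean(Vs <= obs)
  min(1, 2 * p1)
}

# --- Hand-rolled BH step-up -------------------------------------------------
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  # enforce monotonicity from the largest p downwards
  if (m > 1) {
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- One-line enrichment-factor oracle -------------------------------------
# Eq.-style EF straight from raw counts of the four selected fractions.
ref_ef <- function(c13H, c13L, c12H, c12L, pc = 0.5) {
  r <- function(x) (x + pc) / sum(x + pc)
  r(c13H) / r(c13L) - r(c12H) / r(c12L)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
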