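---
title: "Methods: enrichment-factor SIP analysis, predator screening and the gradient simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment-factor SIP analysis, predator screening and the gradient simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predsip)
```

# The analysis in one paragraph

rRNA stable-isotope probing (rRNA-SIP) identifies microorganisms that
assimilate a ¹³C-labeled substrate — here, labeled prey bacteria added to
activated-sludge microcosms — by separating rRNA on an isopycnic
buoyant-density gradient and sequencing selected fractions. Taxa that
incorporated ¹³C carry denser rRNA and shift toward the "heavy" end of the
gradient. `predsip` implements the downstream inference: selecting one
representative heavy and one light fraction per gradient, computing a
per-taxon **enrichment factor**

$$\mathrm{EF} \;=\; \frac{{}^{13}\mathrm{C}_\mathrm{Heavy}}{{}^{13}\mathrm{C}_\mathrm{Light}}
\;-\; \frac{{}^{12}\mathrm{C}_\mathrm{Heavy}}{{}^{12}\mathrm{C}_\mathrm{Light}},$$

where each term is the taxon's relative sequence abundance in the selected
fraction of the ¹³C-treatment gradient or its paired unlabeled ¹²C control,
calling taxa with EF strictly greater than 0.1 ¹³C-labeled, screening 16S
sequences for genus-level relatedness (≥94.5% identity) to verified
predatory isolates, and correlating taxon abundances with process
variables under Benjamini–Hochberg false-discovery control. A forward
simulator of gradients, sequences and metadata with planted ground truth
makes every stage testable without any external data.

# Gradient model

A gradient is a set of 13 fractions, each with a buoyant density (g
ml⁻¹), an RT-qPCR 16S copy number, and per-taxon read counts. Fractions
are classified into a **heavy** window (default 1.851–1.872 g ml⁻¹) and a
**light** window (default 1.805–1.819 g ml⁻¹) on closed intervals: printed
ranges are conventionally read as inclusive, and the windows are
configurable per run. Gradients whose densities never enter a window fail
with an explicit `window-empty` error naming the gradient, rather than
silently widening windows.

The criterion by which a *representative* fraction is chosen within each
window is genuinely open; we default to `max_copies` — the in-window
fraction carrying the most rRNA is the one a sequencing study would
plausibly have library-prepped, and it is the statistically most
informative — with `mid_density` available for sensitivity analysis. Ties
break by density closest to the window midpoint, then by lowest fraction
index, so selection is deterministic and permutation-invariant.

# Enrichment factors, filters and labeling calls

Relative abundances for the EF are computed per selected fraction as
$(c_i + \varepsilon)/\sum_j (c_j + \varepsilon)$ with a pseudocount
$\varepsilon = 0.5$ reads. The pseudocount is our resolution of an issue
the EF definition leaves open: a taxon absent from a light fraction makes
the heavy:light ratio undefined. With $\varepsilon = 0.5$ the ratio stays
finite without inventing meaningful signal for absent taxa; with
$\varepsilon = 0$ the record is flagged `undefined_ratio` and excluded
from labeling calls rather than guessed.

The abundance filter admits genera exceeding 1% and ASVs exceeding 0.1%
relative read abundance in the heavy fraction of at least one ¹³C
treatment × timepoint. All three printed thresholds (">1%", ">0.1%",
"EF > 0.1") are implemented as strict inequalities, matching the printed
`>`; the predator-identity rule ("at least … ≥94.5%") is inclusive. The
filter is evaluated on plain (pseudocount-free) read proportions of ¹³C
heavy fractions only, since incorporators are identified in ¹³C-heavy
material; EF terms then use the pseudocounted abundances.

Prey × timepoint groups whose ¹²C counterpart is absent — or whose ¹²C
heavy fraction yields no usable reads, the situation that forced several
groups out of the original experiment — are retained with status
`missing_12C` and no EF, and are listed in the run manifest. Per-group EFs
are never averaged automatically; `summarize_ef()` reports the arithmetic
mean and maximum over status-`ok` groups only, because the averaging set
behind published "average EF across time and treatments" figures is not
fully specified, and imputing missing groups would be a stronger
assumption than excluding them.

Negative or near-zero EFs can be clipped at $10^{-1.5}$ by
`display_floor()` for log-scale visualization exports; the floor is never
consulted by labeling calls.

# Predator screening by percent identity

Queries are compared to a database of 16S sequences from experimentally
verified predatory isolates by pairwise alignment. The alignment method
behind published identity figures is typically unstated; we use a
Needleman–Wunsch-style global alignment with **free terminal gaps**
(ends-free), match +1, mismatch −1, linear gap −2, appropriate for
near-full-length 16S sequences of unequal trimming. Percent identity is
identical aligned bases over alignment columns, terminal overhangs
excluded; the denominator convention is configurable in spirit by
supplying pre-trimmed sequences. Because co-optimal alignments can differ
in identity, the reported value is made canonical: among score-optimal
alignments the one with the most matches, then the fewest columns,
defines the identity. This makes the implementation exactly checkable
against an independently coded dynamic-programming oracle, which the test
suite does on hundreds of random pairs, alongside a score cross-check
against `Biostrings::pairwiseAlignment(type = "overlap")`.

Two consequences of the ends-free design are worth knowing. First, a
perfect substring scores 100% identity despite unequal lengths — the
overhang is not evidence of divergence. Second, a terminal mismatch can be
trimmed into two overhangs when that raises the score. Both are standard
behavior for overlap-style alignment and are pinned in the tests.

Ambiguity codes (IUPAC) are accepted, normalized (case, U→T) and never
counted as matches. Classification uses the inclusive ≥94.5% genus-level
boundary by default; the best hit breaks ties to the lexicographically
first reference id.

# Ecology screen

`activity_ratio()` is the rRNA:rRNA-gene relative-abundance quotient, a
per-capita activity proxy (undefined at zero gene abundance).
`correlation_screen()` computes Spearman coefficients per taxon ×
variable with pairwise-complete cases, records the per-pair $n$ (sample
coverage differs per variable in survey data), applies Benjamini–Hochberg
within a family, and flags `p_adj < alpha`. The BH family defaults to
**per-variable** — each performance metric corrected across taxa — which
matches how such screens are displayed per metric with metric-specific
$n$; a `global` family is available. Small-sample Spearman p-values use
R's exact algorithm for $n \le 10$ without ties, otherwise the
t-approximation; ties switch to the approximation with a note.
`group_compare()` is a two-sided Mann–Whitney U (unpaired) or Wilcoxon
signed-rank (paired) test, exact for $n \le 12$ without ties, with
continuity correction otherwise; identical paired vectors return $p = 1$.

# The simulator: what it emulates, and what it does not

`simulate_experiment()` forward-simulates everything the pipeline
consumes. Each taxon's rRNA mass is a two-component Gaussian mixture over
buoyant density: weight $1-\alpha$ at $\mu_0 = 1.812$ g ml⁻¹ and weight
$\alpha$ at $\mu_0 + a\,\delta_{\max}$, where $\alpha \in [0,1]$ is the
taxon's ¹³C incorporation, $a = 0.97$ is the label purity (atom% ¹³C of
the prey biomass, matching the ~97 atom% of labeled prey cells) and
$\delta_{\max} = 0.045$ g ml⁻¹ the shift at full labeling. These are
calibration parameters, not claims about gradient-medium chemistry: they
are chosen once so that unlabeled mass bands inside the printed light
window and ~97%-labeled mass inside the printed heavy window, on a
13-fraction grid spanning 1.780–1.900 g ml⁻¹ (equal-width bins, fraction
density = bin midpoint; half-open bins, last closed). Within-taxon spread
is $\sigma = 0.008$ g ml⁻¹.

Reads are multinomial at fixed depth (default $10^5$ per fraction,
NovaSeq-scale) with probabilities ∝ baseline relative abundance × in-bin
mass, renormalized within the fraction — as in real amplicon work, every
fraction library is sequenced to comparable depth, so read totals carry no
density information; the rRNA mass profile is carried by the simulated
qPCR copies (total in-fraction mass × log-normal noise, CV 0.15). Baseline
abundances are log-normal (shape 1.2) over 60 taxa by default. Roles:
predators (default $\alpha \sim U[0.5, 1]$, baselines floored at 2% so
planted incorporators sit above the genus filter), cross-feeders
($\alpha \sim U[0.1, 0.3]$, modeling indirect label acquisition — flagged
in truth so tests can distinguish them from direct incorporators),
inactive ($\alpha = 0$), and two prey-spike taxa representing the added
*E. coli* / *P. putida* biomass ($\alpha = 1$; 40–50% of the community at
amendment time, a small residual at later timepoints). The default design
is the usable group set of a paired experiment: ¹³C and ¹²C gradients for
*E. coli* at 1, 2, 4 d and *P. putida* at 1, 4 d. All outputs are
bit-reproducible given the seed; per-gradient RNG streams are derived by
hashing the gradient id.

Not emulated: raw-read artifacts (chimeras, primer bias, denoising),
compositional correlations among taxa, gradient-formation physics, and
diffusion/smile effects on fraction densities. Passing tests therefore
demonstrate correctness of the inference given the model, not robustness
to every artifact of real gradients.

## Calibration facts the test suite establishes

The test suite and `scripts/acceptance.R` compute (not assert from
memory): exact agreement of pipeline EFs with a one-line formula oracle;
a genus-level false-labeling proportion under the simulator's global null
(all $\alpha = 0$, including the spikes) below 5% across 20 seeds;
recovery of planted predators ($\alpha \ge 0.5$, baseline > 1%) as
labeled in ≥95% of cases with mean EF strictly increasing over
$\alpha \in \{0, 0.25, 0.5, 0.75, 1\}$; exact score/identity agreement
with the alignment oracle; and calibration of the correlation screen on
independent tables. A caveat the simulator makes quantitative: at the
ASV-level filter of 0.1%, multinomial counting noise at $10^5$
reads/fraction gives the EF a null standard deviation of roughly
$2\sqrt{(1-p)/(Rp)} \approx 0.2$ at the filter boundary, so the strict
EF > 0.1 rule miscalls an appreciable fraction of borderline-abundance
ASVs under the null. The genus-level filter (1%) keeps this below the 5%
calibration bound; ASV-level calls near the abundance floor should be
read as candidates, not detections — a property of the printed rule at
finite sequencing depth.

## Study-scale choices

Test and acceptance runs use 60-taxon communities, $10^5$ reads per
fraction, 5 paired groups and 20-seed replication; the dose-response grid
re-simulates 100 experiments. These sizes give stable calibration
estimates (thousands of null records) while keeping the full suite in
tens of seconds. The genus-boundary identity fixtures use 2000-nt
sequences with exactly 110 and 114 interior substitutions, because 94.5%
and 94.3% are representable exactly at that length (they are not at 1500
columns) and interior placement keeps ends-free trimming from altering
the planted identity.

# Numerical and degenerate-input choices

* Window membership on closed intervals; overlapping windows are a
  configuration error caught before any computation.
* `copy_distribution()` errors on all-zero copies; proportions sum to 1
  within 1e-12.
* EF with a zero light-fraction abundance (pseudocount 0) → status
  `undefined_ratio`, no labeling call; never an exception mid-pipeline.
* Unmapped ASVs aggregate under `unclassified:<highest resolved rank>`;
  genus aggregation conserves column totals exactly.
* Gaussian bin masses use upper-tail differences, stable 10σ from the
  mean; an all-zero mass column (impossible under valid configs) falls
  back to uniform.
* Exact rank tests switch to the corrected normal approximation in the
  presence of ties, with a note; identical paired samples give p = 1.
* TSV outputs format numerics at 12 significant digits and carry a
  config-hash + seed header; reruns are byte-identical.

# Known limitations

* EF is a ratio-difference statistic without an error model; no
  uncertainty is attached to individual EFs (quantitative SIP-style
  density-shift modeling is out of scope).
* Labeling cannot distinguish direct predation from cross-feeding; the
  simulator's flagged cross-feeders exist precisely to exercise this
  ambiguity.
* Identity-based predator classification inherits the usual caveat that
  16S relatedness to a predatory isolate is evidence of potential, not
  proof of behavior.
* The correlation screen is observational: significant abundance ×
  performance associations are not causal claims.
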