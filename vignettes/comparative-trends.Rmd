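---
title: "Detecting adaptive trends in protein alignments: models and design choices"
author: "protrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting adaptive trends in protein alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protrend)
```

# The problem and the model

Organisms adapted to extreme habitats — cold, heat, salt, pressure — may
favour particular amino acids in their proteins. Given multiple
alignments of orthologous proteins whose sequences are labelled with an
*ordered* phenotype of the host organism (mesophile = 1, intermediate = 2,
psychrophile = 3, say), `protrend` tests whether composition, substitution
patterns, or mean physicochemical properties trend monotonically with that
ordinal code.

The phenotype code X is treated as an ordinal predictor, never as a
metric quantity: the primary inference tool is therefore rank-based. Each
protein family contributes one *block* of (X, Y) observations, where Y is
a per-sequence summary (frequency of an amino acid, mean property value).
Within a block the Mann-Kendall statistic

$$S = \sum_{i<j} \mathrm{sgn}(x_j - x_i)\,\mathrm{sgn}(y_j - y_i)$$

is computed with the standard tie-corrected variance. Ties in x are the
rule, not the exception — a block of 6 sequences in 3 groups has massive
x-ties — so the variance uses the full Kendall correction, including the
two cross-product terms that matter only when *both* vectors are tied:

$$\mathrm{var}\,S = \frac{n(n-1)(2n+5) - \sum_t t(t-1)(2t+5) - \sum_u u(u-1)(2u+5)}{18}
 + \frac{\sum_t t(t-1)(t-2)\sum_u u(u-1)(u-2)}{9n(n-1)(n-2)}
 + \frac{\sum_t t(t-1)\sum_u u(u-1)}{2n(n-1)}$$

where t and u run over tie-group sizes of x and y. When y is continuous
(the typical case) the last two terms vanish and the formula reduces to
the familiar one-sided correction.

Blocks are combined in seasonal-Kendall style: S and var S are summed over
families, and the total is tested with the continuity-corrected deviate
Z = (S − sgn S)/√(var S). This *cumulative* Mann-Kendall test is the
package's default instrument for "is there a common trend across many
families?". Degenerate blocks (constant x or y, or fewer than 3
observations) are skipped with a warning rather than aborting a
proteome-wide scan.

## Assumptions

- Sequences are statistically independent within each group at each
  stratum. Phylogenetic dependence (shared ancestry, horizontal transfer)
  violates this; the `collapseDependent` option averages observations
  within each group × stratum cell first and tests the cell means, trading
  power for validity.
- The alignment is taken as given and correct; alignment construction and
  structure prediction are upstream of this package (their outputs — the
  annotated FASTA dialect — are parsed, not produced).

# Substitution analysis

A substitution pair (SP) is an aligned position where residue x in a
sequence of the source group faces residue y ≠ x in a sequence of the
target group. Counts are accumulated in a 21 × 21 matrix (20 amino acids
plus the gap state `~`; both-gap columns are skipped, single-gap columns
count as exchanges with the gap state).

**Pairing.** To avoid oversampling, sequences are paired disjointly by the
Jones method: repeatedly take the cross-group pair with the highest
pairwise identity (identity = matches over both-aligned columns), remove
both sequences, and repeat. This greedy procedure is deliberately the
documented contract — it mirrors the pair-the-most-identical description
of the method — and is *not* guaranteed to maximize total identity; an
exhaustive optimal matching is exposed as a non-default option
(`method = "optimal"`, small groups). Ties are broken lexicographically
by sequence id so results are deterministic.

**Background.** The within-group background matrix N(M,M) uses the same
greedy pairing inside the baseline group, giving ⌊n/2⌋ disjoint pairs and
a symmetric count matrix. The choice of Jones-within (rather than all
within-group pairs) keeps the adaptation and background rows of the 2 × 2
table on comparable footing; the all-ordered-pairs alternative exists as
the *representative* matrix n̄ = Σ n / G_MP, which divides by the number
of ordered cross-group pairs and is the dependence-robust descriptive
summary. Representative counts are fractional by construction; the exact
tests require integers, so they are rounded half-to-even with a warning —
the default testing path always uses the Jones cumulative counts.

**Testing.** For each ordered pair (x, y) the table
[a, b; c, d] = [N_{x,y}(M→P), N_{x,¬y}(M→P); N_{x,y}(M,M),
N_{x,¬y}(M,M)] is tested with the mid-p Fisher exact test: the
hypergeometric null with fixed margins, where the observed table
contributes only *half* its probability. Two-sided p-values use
probability ordering — the sum over strictly-less-probable tables plus
half the probability of tables tied with the observed — with ties detected
at relative tolerance 1e-7. This makes the identity

$$p_\text{mid} = p_\text{exact} - \tfrac12 P(\text{tied tables})$$

hold exactly, and mid-p ≤ exact p on every table. Doubling of the
one-sided p is *not* used. A pair with zero forward counts out of x is
reported as not-testable rather than p = 1: absence of data is not
absence of effect. Pearson chi-square (1 df, no Yates correction — the
mid-p already handles discreteness where it matters) is the large-count
alternative, and Mantel-Haenszel combines per-stratum tables when
taxonomic strata are available.

# Composition and property analyses

Per-sequence amino-acid frequencies are computed over non-gap residues
only (a gap is the absence of a residue, not a 21st composition state).
The classical four-way charge partition — negative {D, E}, positive
{K, R}, uncharged polar {C, S, T, Y, N, Q, W, H}, hydrophobic
{G, A, V, L, I, F, P, M} — is built in; arbitrary disjoint category
schemes are accepted.

The test design follows the group count: exactly 2 groups may use one-way
ANOVA (two-way additive with a stratum, group effect by its Type II sum
of squares — no interaction term is in the model, so SS(group | stratum)
is the appropriate adjusted quantity) or the paired Wilcoxon over
per-family group-mean deltas; 2 or more ordered groups use regression or
the cumulative Mann-Kendall test. Requesting a 2-group design with more
groups is a hard error, not a silent subset.

Property analysis reduces each sequence to the arithmetic mean of a
property scale over its non-gap residues (optionally restricted to
filtered sites). Five scales are bundled with literature citations in
their metadata — Kyte-Doolittle hydropathy, Zamyatnin residue volume, net
side-chain charge at pH 7, Grantham polarity, Vihinen flexibility — and
user scales are read from a 20-line `AA<TAB>value` file or AAindex1
records. Per-family OLS slopes β₁ of Y on X provide the ranked-slope
figure; significance always comes from the cumulative Mann-Kendall test,
because the slope is a descriptive (metric) summary of an ordinal
relationship. Replacing a scale by an affine image a·v + b rescales every
slope by a and leaves the Mann-Kendall p unchanged.

In stratified single-family regression the parallelism model
Y = β0 + β1·X + Σ_s β_s I_s + e assigns the baseline intercept to the
lexicographically first stratum label — a deterministic, documented
choice. A stratum confounded with X makes the design rank-deficient and
is reported by name.

# Structural site filters

Per-site secondary structure (H/E/C) and relative accessible surface area
(RSA ∈ [0,1]) arrive as extra FASTA records (`>id|2D`, `>id|3D`). A 3D
body that is a bare digit string is decile-encoded; digit d maps to the
bin midpoint (d + 0.5)/10, an unbiased representative of the bin.
Surface means RSA ≥ 0.25, core means RSA < 0.25 — the conventional
25% relative-accessibility cut; the threshold is a parameter.

Annotations may disagree across the sequences of a column, and the
sources say nothing about how to resolve this; the package uses a
consensus rule: a column passes when the fraction of annotated, non-gap
sequences satisfying the constraint is ≥ `consensus` (default 0.5, with
the boundary case counted as passing). Kept columns retain their
original 1-based coordinates, so every report cites positions in the
input alignment.

# The synthetic-data generator

`fixtureSpec()`/`simulateAlignments()` generate annotated alignments with
known ground truth. Per family an ancestral sequence is drawn i.i.d. from
base frequencies (average database composition by default); each sequence
of group g resamples every site independently with probability
`divergence` (default 0.3, a moderately diverged orthologous family) from
a group-specific distribution. Because only a `divergence` fraction of
sites is resampled, the resampling distribution is inflated by
1/divergence so that the *expected composition* of group g is exactly
base + (g − 1)·shift; amino acids not named in the shift absorb the
compensating mass in proportion to their base frequency. Infeasible
combinations (negative frequencies) are rejected up front.

Property slopes are injected by shifting the composition along the
property direction w = f·(v − v̄) (f = base frequencies, v = scale
values), scaled so the expected per-sequence mean property rises by
exactly β₁ per group step. A directional substitution bias x → y is
injected as additional directed conversions in the adapted groups, with
the conversion probability calibrated analytically so the forward x → y
substitution rate is `multiplier` times the undirected background
coincidence rate (both the ancestor-x and the reverse ancestor-y paths
contribute to the background; the calibration accounts for both).

Gaps are injected independently per site at rate 0.02 by default —
unbiased thinning that leaves composition expectations unchanged.
Secondary structure is a sticky 3-state Markov chain (runs of helix and
sheet, as in real structure); RSA digits are i.i.d. Generation is
byte-for-byte deterministic given the spec, and the caller's RNG state is
left untouched.

**What the generator does *not* emulate:** phylogenetic correlation
within groups (sites and sequences are exchangeable), alignment error,
indel structure (gaps are point events, not tracts), site-specific
conservation, or correlated annotation. Passing the validation suite
therefore demonstrates correctness of the statistical machinery under the
models' own assumptions — not robustness to tree-structured dependence,
which real data exhibit and which the collapse-to-group-means path only
partially addresses.

# Validation design and problem sizes

The test suite validates every discrete test against independent
enumeration (full hypergeometric enumeration for the mid-p; all 2^n sign
assignments for the signed-rank test; all n! permutations for the
Mann-Kendall p at n ≤ 8) and the counting machinery against brute-force
recounts. Calibration and recovery use simulation at sizes chosen to
mirror a modest comparative study while keeping the suite fast on one
CPU:

- type-I error: 1000 null data sets of 50 families × 6 sequences
  (3 groups × 2), nominal α = 0.05, acceptance band ±3 binomial SE;
- composition power: 200 data sets of 30 families with a +0.05 per-step
  lysine shift, detection at α = 0.05 required in ≥ 80%;
- slope recovery: 5 × 65 families with an injected β₁ = 0.05
  hydrophobicity slope, mean recovered within 2 SE;
- substitution recovery: 100 data sets of 15 families (3 + 3 sequences,
  400 sites) with a 3× K→R bias, (K, R) required in the top 3 scan
  p-values in ≥ 90%. The 15 × 400 size was fixed by an a-priori power
  calculation on the calibrated generator before the acceptance run.

# Numerical choices and edge cases

- Gap symbols `-`, `.`, `~` are accepted on input and normalized; `~` is
  rendered in substitution outputs.
- Mid-p probability ties: relative tolerance 1e-7.
- Mann-Kendall continuity correction: Z = (S − sgn S)/√var S; S = 0 or
  var S = 0 reports p = 1 with a degenerate flag.
- Wilcoxon: zeros dropped; exact signed-rank distribution for n ≤ 25
  without ties; full 2^n enumeration with midranks for tied samples with
  n ≤ 12; tie-corrected normal approximation above.
- Degenerate 2 × 2 tables (empty margin) report p = 1 with a
  `not_testable` flag instead of raising — they occur routinely in sparse
  SP-matrices and must not abort a scan.
- Every multi-feature scan reports Benjamini-Yekutieli q-values (harmonic
  inflation c(m), valid under arbitrary dependence) alongside raw p.

# Known limitations

- The normal approximation to the Mann-Kendall p degrades for *heavily
  tied responses* in blocks of 4-5 observations (deviations up to ~0.25
  from the exact permutation p are possible); with continuous responses —
  the package's use case — the approximation stays within 0.09 of exact
  at all block sizes we enumerate. Very small studies with discretized
  responses should rely on the exact tests.
- Greedy Jones pairing can be globally suboptimal; the optimal assignment
  is available but exponential-time and limited to small groups.
- No evolutionary-model-based rate estimation (no PAM/LG fitting), no
  tree inference, no DNA-level analysis.
- The within-group background pairing is a documented convention (Jones
  pairs within the baseline group); other background models would change
  the 2 × 2 tables.
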