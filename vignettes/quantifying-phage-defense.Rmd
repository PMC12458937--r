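---
title: "Quantifying anti-phage defense and its mobile genetic context"
author: "DefenseKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anti-phage defense and its mobile genetic context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DefenseKit)
```

# Scope

Bacterial anti-phage defense systems are usually characterized with two
complementary assays: plaque assays on solid media, which measure how many
orders of magnitude a defense reduces the number of successful infections,
and liquid infection assays, which measure how well a defended culture keeps
growing under phage pressure. Defense systems also travel: many sit inside
integrated mobile genetic elements (MGEs) anchored at tRNA genes and bounded
by short direct repeats, and co-encoded systems can protect synergistically.
DefenseKit implements the quantitative machinery for all of these analyses,
together with seeded synthetic-data generators that carry machine-readable
ground truth, so every stage of the pipeline can be scored end to end.

# Plaque quantification

## The titer estimator and its censoring rules

A spot assay plates ten-fold serial dilutions of a phage stock (volume
$v$ ml, dilution factor $d \le 1$) on a bacterial lawn. If the most dilute
spot with a countable number of plaques shows $c$ plaques, the titer is

$$\hat T = \frac{c}{v \, d} \quad \text{[PFU/ml]}.$$

`estimateTiter()` uses a countable window of 3–100 plaques by default:
below 3 the spot is dominated by Poisson noise, above 100 plaques merge.
Three special cases are handled explicitly rather than silently:

* **Lysis halos.** Some lytic phages clear the lawn without forming
  discrete plaques. The most dilute halo-positive spot is quantified with
  the count treated as at least one, and the estimate is flagged
  (`lysisHalo`), since it is a bound rather than a count.
* **No plaques anywhere.** The titer is *censored*: all we know is that it
  lies below $1/(v \, d_{\max})$, the titer that would have produced about
  one plaque in the least-diluted spot. `TiterEstimate` carries this limit
  of detection instead of a made-up value.
* **No countable spot but nonzero counts.** The most dilute nonzero spot is
  used (overgrown assays where every count exceeds the window).

A statistical caveat that matters for recovery studies: because the
estimator prefers the *most dilute* countable spot, a dilution whose
expected count is near the lower window edge ($\lambda \approx 3$) enters
the estimate only when its Poisson draw happens to reach 3, which inflates
the mean estimate by roughly 20%. With the expected count at the counted
dilution at or above 20 the conditioning is negligible and the estimator's
relative bias is well under 5%. Recovery tests therefore use dilution
series (or a countable window of 20–200) whose counted spot has expected
count 30.

## EOP, log-protection, SFC and the classifiers

The efficiency of plating is the titer ratio
$\mathrm{EOP} = T_\text{test}/T_\text{ref}$ against a fully susceptible
reference strain; $-\log_{10}(\mathrm{EOP})$ is the *log-protection*, the
orders of magnitude of titer reduction. A censored test titer propagates
as an upper bound on the EOP and a lower bound on log-protection — the
qualitative call "protected" can still be made when the bound clears the
threshold. Two classifiers are provided:

* `classifyProtection()`: protected iff the titer reduction strictly
  exceeds ten-fold (log-protection > 1). We read the ">10^1 PFU/ml
  reduction" convention as a fold change, not an absolute difference; an
  absolute reading is dimensionally inconsistent with a serial-dilution
  assay, and the corresponding figure axis is log-scaled titer reduction.
  A censored lower bound at or below 1 returns `FALSE` (not demonstrated).
* `classifyModestProtection()`: EOP < 0.01 **or** plaque size fold change
  (SFC) < 0.5 — a disjunction, so a system that only shrinks plaques still
  counts.

SFC is the ratio of mean plaque radii (three plaques per condition is
typical); an area-ratio option exists (`use_area = TRUE`) because the
choice is not standardized. Replicate aggregation computes metrics per
replicate first and then averages — geometric mean for EOP (respecting its
log scale), arithmetic mean for SFC.

# Synergy statistics

## The epistatic coefficient

For two systems A and B co-encoded in one strain,

$$\varepsilon \;=\; |\log_{10} \mathrm{EOP}_{A+B}| \;-\;
  |\log_{10} \mathrm{EOP}_{A}| \;-\; |\log_{10} \mathrm{EOP}_{B}|.$$

For EOPs at most 1 this is $\log_{10}(\mathrm{EOP}_A \mathrm{EOP}_B /
\mathrm{EOP}_{A+B})$: zero when protection is exactly multiplicative,
positive when the combination protects more than the product of its parts.
The coefficient is set to zero whenever the mean EOP of the wild-type
(double-system) strain for that phage is $\ge 10^{-2}$ — if the phage
plates essentially normally on the defended strain there is no protection
to decompose, and the formula would amplify noise. The boundary is
inclusive (`zeroed` at exactly $10^{-2}$), and the would-be value is kept
in `rawEpsilon` for diagnostics. Censored EOP inputs are substituted by
their bounds and the result records the direction in which the true
coefficient lies; no value is invented.

Inputs are per-phage mean EOPs (replicates averaged before the formula),
matching how the zeroing rule is phrased; a per-replicate route is simply a
matter of calling the function per replicate.

## Growth curves and the AUC synergy call

Liquid assays sample OD600 every 10 minutes. Processing follows a fixed
order: subtract the initial OD from every point (`baselineSubtract()`,
idempotent), then integrate with the composite trapezoid rule
(`areaUnderCurve()`, reported in OD600·hour). At 10-minute sampling the
trapezoid discretization error for smooth curves is of order
$h^2/12\,f''$ — about 1.4% for a pure quadratic over one hour — which is
far below the biological replicate variation the statistic feeds into.

The synergy definition is deliberately stringent: systems A and B
synergize at a given MOI iff

$$\mathrm{AUC}_{A+B} \;>\; \mathrm{AUC}_A + \mathrm{AUC}_B,$$

a strict inequality; ties are not synergy (`callAucSynergy()`). Because the
single-system AUCs each contain the shared growth baseline, this additive
expectation is hard to beat — it only flags combinations whose joint
protection rescues growth that neither system could buy alone.

Replicate bands (`replicateBand()`) are pointwise Student-t intervals with
$n-1$ degrees of freedom; with triplicates the 95% half-width is
$4.30\,s/\sqrt{3}$. t-based bands were chosen over normal or bootstrap
bands because $n = 3$ is the norm and the t quantile is the honest small-n
choice; empirical coverage is verified at 95% ± 2% in the test suite.

## Reporter normalization and hypothesis tests

Propidium-iodide and resazurin fluorescence are reported per unit culture
density (RLU/OD600). `normalizeReporter()` floors the denominator at 0.01
OD (configurable) so that lysis-driven densities near zero do not blow the
ratio up; floored points are flagged rather than dropped.

Group comparisons use a Welch (unequal-variance) unpaired t-test with the
one-sided alternative "greater" (`oneSidedGreaterTest()`); normality is
pre-checked per sample with Shapiro–Wilk and reported alongside with a
warning — the test is never silently switched. Many-versus-control
comparisons use one-way ANOVA followed by Dunnett's all-versus-control
procedure (`anovaMultcomp()`); Dunnett was chosen because the design
compares each mutant to a single control, which is exactly Dunnett's
contrast family, with Holm-adjusted per-comparison Welch tests as a
configurable fallback. Significance is declared at adjusted p < 0.05.

# Island catalogue

## Protein-family clustering

Flanking ORFs are deduplicated into families by greedy incremental
clustering (`clusterProteinFamilies()`), the strategy of CD-HIT-class
tools: process sequences longest first (ties by id), join the
earliest-founded family whose representative aligns at ≥ 90% identity with
≥ 80% coverage of **both** sequences, else found a new family. Identity
and coverage are defined over a single global alignment (BLOSUM62, gap
open 11 / extend 1): terminal-gap columns are trimmed, identity is
matches over the remaining columns (internal gaps count as columns), and
coverage of each partner is its aligned residues over its full length. So
a perfect 70-residue prefix of a 100-residue protein has identity 1.0 but
coverage 0.7 of the longer partner, and the two stay separate. This is an
exact, reproducible definition — deliberately not an emulation of any
word-based screening heuristic — and it is verified against an all-pairs
brute-force oracle in the tests.

## Filtering, neighborhoods and grouping

Islands within 10 ORFs of a contig end are excluded
(`filterContigEdgeIslands()`, "at least 10" — the boundary island is
kept): truncated neighborhoods would fake unique context. Gene
neighborhoods (`extractNeighborhood()`) take up to 50 genes on each side
of an anchor, with signed offsets; a minus-strand anchor reverses order
and offset signs so the anchor always reads 5'→3' left to right; flanks
truncated by a contig end are simply shorter.

Islands are grouped by shared gene content (`groupIslandFamilies()`): the
distance between two islands is the size of the symmetric difference of
their content sets (defense genes plus adjacent ORF families; presence/
absence, copy number ignored — a multiset reading is a configuration
choice, not the default). Islands at distance ≤ 3 are linked and families
are connected components — single linkage, because the operation described
is grouping, not complete-linkage clustering; chains therefore merge
(distance 3 + 3 links islands 6 apart). Family ids are deterministic (the
smallest member island id).

# The MGE scanner

Integrated elements delivered by site-specific recombination are bounded
by a direct repeat pair: one copy overlapping the 3' end of the target
tRNA/tmRNA gene (the attachment site) and one at the distal element
boundary. `findTrnaAnchoredRepeats()` searches, for each tRNA, every
k-mer (k = 16–20) starting in an anchor window — the last 25 nt of the
gene plus 5 nt past its 3' end, a window that covers where attB sites
overlap tRNA 3' ends — against the region up to 200 kb downstream in the
tRNA's reading direction, accepting at most one mismatch. Choices worth
stating:

* **Mismatch model is Hamming** (substitutions only): the repeat lengths
  are fixed, so "may have one mismatch" cannot mean an indel. `N` never
  matches anything, including another `N`.
* **Both repeat copies are treated symmetrically**; the mismatch may sit in
  either copy.
* **Search is one-directional** (downstream of the 3' end in tRNA
  orientation), matching the integration geometry; minus-strand tRNAs are
  handled by scanning the reverse complement and mapping coordinates back,
  which makes the scan exactly strand-symmetric (a tested invariant).
* **Collapse precedence is fewest mismatches, then longest, then nearest.**
  Two candidate hits conflict when both their anchor and their distal
  spans overlap. Mismatch count must outrank length: otherwise an exact
  k-mer repeat would always be absorbed into a (k+1)-mer spending the
  mismatch budget on the extension base, and the true repeat could never
  be reported.
* **max_span defaults to 200 kb**: the elements of interest span tens of
  kb; the bound is a guard against quadratic blowup, not a biological
  claim, and is configurable.

`callElements()` places the element span strictly between (excluding) the
repeat copies, collects the genes fully contained in it as cargo, and,
when several hits share a tRNA, keeps a non-overlapping set greedily by
longest span. `classifyMobility()` is a deliberately transparent keyword
classifier over cargo product annotations (not an HMM/profile search): an
element is predicted active when it retains an intact (non-pseudo)
integrase/recombinase *and* either an excisionase or a rolling-circle
replication initiator; it is immobilized when its only integrase matches
are pseudogenes or it has none — the vestige signature of a stranded
element; an intact integrase alone stays unclassified. The "rep" keywords
are word-bounded so "repressor" never matches. The vocabulary is a
user-extensible configuration object.

# The synthetic-data generators

Each generator is a pure function of its configuration: one pseudorandom
sub-stream per generator, derived from the master seed by a fixed label,
so adding one generator never changes another's output.

**Plaque assays** draw spot counts from
$\mathrm{Poisson}(T \cdot \mathrm{EOP} \cdot d \cdot v)$ — the exact
sampling model of plating a well-mixed lysate. The defaults mirror the
assay design the package analyzes: ten-fold series, 3 µl spots,
triplicates.

**Growth curves** come from a deterministic susceptible–infected–phage
(SIP) ODE per condition,

$$S' = rS\left(1 - \tfrac{S+I}{K}\right) - a_\text{eff} P S, \qquad
  I' = a_\text{eff} P S - \delta I, \qquad
  P' = \beta \delta I - a_\text{eff} P S,$$

integrated with a fixed-step 4th-order scheme at 0.5-minute steps and
sampled every 10 minutes for 540 minutes, plus i.i.d. Gaussian noise
(sd 0.02 OD) per sample; replicates differ only in their noise draw.
Defense acts on adsorption: $a(1-e_A)$, $a(1-e_B)$ for single systems and
$a(1-e_A)(1-e_B)/\gamma$ for the double strain, so $\gamma = 1$ encodes
exactly multiplicative protection (the additive-expectation null) and
$\gamma > 1$ super-multiplicative protection — a single scalar that *is*
the synergy ground truth. The default parameters (r = 1.5/h, K = 1.0
OD600, a = 8×10⁻⁹ ml/(PFU·h), β = 5, δ = 0.7/h, e_A = 0.75, e_B = 0.35,
initial OD 0.05 at 8×10⁸ cells/ml per OD unit, synergy evaluated at
MOI 1) were chosen by forward design to place all strains in the partially
protective regime where the strict additive-AUC criterion is informative:
each single system delays but does not prevent culture collapse, the
multiplicative combination still falls short of the single-system AUC sum
(margin ≈ 0.70 OD·h), and γ = 2 clears it (margin ≈ 0.84 OD·h) — margins
two orders of magnitude above the AUC noise, so classification accuracy is
limited by the model, not the draw. The burst size of 5 is an *effective*
per-lysis yield folding in unproductive adsorption and reversible binding;
with textbook burst sizes the race between phage amplification and
logistic growth becomes so switch-like that the additive criterion
degenerates (every AUC saturates or collapses). This generator emulates
the decision geometry of the assay, not HK022 biology: no latent-period
delay distribution, no resistance evolution, no spatial structure — so
passing the recovery suite validates the *statistics*, not any claim
about real infection kinetics.

**Genomes with planted elements** are uniform-random backgrounds with
planted tRNAs whose 3' tails carry the anchor repeat copy, a distal copy
with the configured number of substitutions, cargo genes whose product
strings exercise every mobility class, and decoys that each violate
exactly one detection constraint (14 nt repeat; beyond the scan span; two
mismatches; not tRNA-anchored). Two constructive guarantees make "recover
the planted truth exactly" well-posed: substitutions are planted in the
repeat interior (inside every 16-nt sub-window, ≥ 3 nt from the ends), and
the two bases flanking each distal copy are forced to mismatch their
anchor-side counterparts — so the planted repeat is *maximal* and no
shorter or longer variant can outrank it. After assembly the generator
scans its own output and regenerates (bounded retries) if any unplanned
repeat is detectable, implementing the "unique elsewhere" precondition.

**Island tables** plant families sharing a core content set; each island
applies `perturbations_per_island` single-element add-or-remove edits
(an add/remove changes the symmetric difference by 1, so two 1-perturbation
islands stay within distance 2 and single linkage keeps the family
connected; a substitution would change it by 2 and could split planted
families at the distance-3 threshold). ORF proteins are reference
sequences mutated by at most 2% per member — same-family pairs stay ≥ 95%
identical, cross-family pairs are unrelated random sequences (~5%
identity), exactly the separation the 90/80 clustering thresholds assume.

# Numerical choices and degenerate inputs

* Coordinates are `GRanges` (1-based closed) internally — the Bioconductor
  convention — with 0-based half-open spans exposed at the BED boundary
  and via `coords0()`. Compound (join) gene locations collapse to their
  envelope with a warning: only gene order and span matter downstream.
* Ties everywhere break deterministically (length then id in clustering;
  mismatches/length/position in the scanner; smallest member id for family
  names), so runs are reproducible bit for bit.
* Empty inputs error early with messages naming the offending rows,
  columns or sequence ids; zero plaque counts are data, never dropped.
* Every threshold application can emit a structured log line
  (`options(DefenseKit.verbose = TRUE)`): operation, threshold, rows in,
  rows out.

# Problem sizes used in verification

The test suite runs the recovery studies at desk scale: 1000 random EOP
triples for the ε identity; 1000 Poisson dilution series for titer/EOP
recovery; 200 seeded growth datasets (half γ = 2, half γ = 1) for the AUC
synergy caller; 20 genomes of ≤ 50 kb for scanner-versus-oracle
equivalence plus 50 planted-element genomes for recall; island recovery at
5 families × 4 islands; 1000 Gaussian replicate sets for band coverage.
`scripts/acceptance.R` re-runs the same computations at comparable sizes
from a single command-line seed.

# Known limitations

* The protection classifiers implement fixed published-style thresholds;
  they are not calibrated decision rules.
* Identity/coverage clustering is quadratic in the number of sequences per
  family representative set; it is intended for the hundreds-of-ORFs scale
  of island deduplication, not proteome-wide clustering.
* The mobility classifier is only as good as the product annotations it
  reads; unannotated integrases are invisible to it by design.
* The scanner assumes a single replicon sequence per call and does not
  search across contig boundaries.
* Censored-EOP propagation into ε records bound directions but does not
  implement interval arithmetic across multiple simultaneous censorings
  (`bound = "unknown"` in that case).
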