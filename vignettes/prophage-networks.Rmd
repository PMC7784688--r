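---
title: "Methods: prophage interaction networks, defense targeting and capsule-loss dynamics"
author: "prophagenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prophage interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prophagenet)
```

# Scope and data model

`prophagenet` analyses panels of lysogenic *Klebsiella* strains in which
every strain's induced lysate is spotted on lawns of every strain, over
independent replicate lysates. The package starts from annotated inputs —
protein and nucleotide FASTA, BLAST-tabular homology hits, prophage
coordinate tables, R-M and CRISPR annotation tables, infection-matrix CSVs
and trajectory CSVs — and is deliberately agnostic about how those
annotations were produced. De-novo prophage detection, serotyping,
defense-system detection and motif inference from reference databases are
out of scope: their outputs are modelled as inputs.

Two S4 containers anchor the analyses. `InfectionMatrix` holds the
producer × target grid of replicate-positive counts with its replicate
number, and validates that every cell lies in `[0, nReplicates]`.
`ContingencyResult` holds a 2×2 table together with its sample odds ratio
and exact p value. Everything else (hits, BBH pairs, targeting calls,
trajectories) travels as plain data frames in documented column dialects.

# Prophage similarity: wGRR

For prophages $A$ and $B$ with $\#A$ and $\#B$ proteins and $p$
bidirectional best-hit (BBH) pairs,

$$\mathrm{wGRR}(A,B) = \frac{\sum_i^p \mathrm{id}(A_i, B_i)}{\min(\#A, \#B)}$$

with identities as fractions. The score weighs both how many genes are
shared and how similar they are: three homolog pairs at 100% identity
against a smaller proteome of 100 proteins give 0.03, as do six pairs at
50%.

Conventions, and why:

- **Hit filtering.** E-value strictly below $10^{-4}$ (the stated bound is
  "lower than"), identity at least 35% and coverage at least 50%
  (inclusive, "at least"). The coverage requirement applies to both query
  and subject by default — the stricter, standard BBH reading of an
  ambiguous one-sided phrasing — with `coverageMode = "query"` available
  as a switch.
- **Best-hit ranking.** Higher bitscore, then lower e-value, then higher
  identity, then lexicographically smaller subject identifier. The last
  tie-break is arbitrary but total, which keeps results independent of
  input row order.
- **Pair identity.** The two directions of a BBH may report different
  identities (their alignments differ); the pair identity is their
  arithmetic mean, the symmetric choice.
- **Diagonal.** wGRR of a prophage with itself is defined as 1; the
  analyses never compare a phage to itself, but a defined diagonal keeps
  the matrix usable as a distance complement.
- **Network threshold.** Edges require wGRR strictly above the threshold
  (default 0.5), matching a "higher than 50%" rule.

# Superinfection immunity

Repressor candidates are profile hits with viral quotient strictly above
0.8, best-domain e-value at most $10^{-4}$, profile coverage at least 60%,
and a description mentioning immunity, superinfection, repressor or
exclusion. Similarity between candidate repressors is the number of matched
positions under a global alignment with zero mismatch and gap costs —
equivalently the longest-common-subsequence length — divided by the length
of the shorter sequence (`repressorSimilarity()`). This matched-positions
statistic is used wherever repressor identity thresholds appear (e.g. the
\>80% rule in `repressorPairFraction()`). A column-identity statistic
would be a defensible alternative; the matched-positions reading is
implemented uniformly so thresholds mean the same thing everywhere.

# Defense-system targeting

**CRISPR.** Arrays with fewer than three spacers are discarded as
unreliable calls. Spacer matching (`matchSpacer()`) is an ungapped scan of
both strands allowing contiguous prefix/suffix truncations of the spacer
down to 90% coverage, reporting windows at ≥ 90% identity; overlapping
same-strand reports collapse to the best (fewest mismatches, then longest,
then leftmost). Short (25–40 nt) spacer alignments essentially never gap,
so ungapped matching loses nothing at this scale. The e-value criterion
used alongside identity/coverage in database searches is deliberately not
reproduced: e-values depend on database size and add nothing over the
identity and coverage thresholds on a fixed panel. A floating-point epsilon
(`1e-9`) guards threshold arithmetic such as $\lceil 0.9 \times 30 \rceil$
against representation error.

**Restriction–modification.** Each R-M system is a set of typed components
(MTase/REase) with an optional IUPAC recognition motif. Two proteins of the
same role and type are *equivalent* — assumed to target similar sites —
when their global-alignment identity (identical columns over aligned
columns, terminal gaps excluded) reaches the per-type threshold: 50% for
type II and IV REases, 55% for IIG, 60% for type II MTases, 80% for type I
and III MTases and REases. For an ordered pair (producer A, target B),
systems of B count as *absent from A* when none of their components has an
equivalent of the same role and type in A; this component-level rule is
the conservative choice where a system-level matching criterion is
underdetermined. Motif occurrences are then counted in each
intact prophage of A (`findMotifSites()`): the forward strand always, the
complementary strand only when the motif is not its own reverse
complement, so palindromic sites are not double-counted. A prophage is
targeted at one site by default, or two in `twoSiteMode` (for enzymes
requiring two recognition sites); two-site positives are necessarily a
subset of one-site positives, which the tests assert. Systems without
motifs are skipped with a message rather than silently dropped.

# Infection-matrix statistics

A producer–target combination is *infected* when at least one replicate
shows clearing (configurable to all replicates). The per-producer
*infection score* is the mean over all targets, self included, of the
fraction of positive replicates. Replicate reproducibility is the fraction
of infected combinations positive in every replicate, optionally
stratified by capsule locus type (CLT).

Serotype modularity cross-tabulates ordered strain pairs (same-CLT vs
cross-CLT against infected vs not). Self-pairs are counted by default
(`includeSelf = TRUE`): with 35 strains this yields 1225 ordered
combinations splitting 105/1120 under the default serotype multiplicities,
the arithmetic of the study regime; the flag exposes the alternative since
"cross-strain" phrasing could exclude them.

`fisherExact2x2()` is implemented in-package rather than delegated:

- the two-sided p value sums hypergeometric point probabilities of all
  tables with the observed margins that are at most as probable as the
  observed table, with a relative tolerance of $10^{-7}$ against
  floating-point ties — the convention of standard exact-test
  implementations, and the tests verify equality with full `choose()`-based
  enumeration on every table with $N \le 30$ and with `stats::fisher.test`
  on random tables;
- the odds ratio is the *sample* odds ratio $ad/bc$ ($\infty$ when
  $bc = 0 < ad$, `NA` when both products vanish; no Haldane correction),
  because printed odds ratios in this literature are sample odds ratios,
  while `fisher.test` reports the conditional MLE (e.g. 13.5 vs 14.5 on
  the table `[[35, 70], [40, 1080]]`).
- degenerate margins (an empty row or column) give p = 1, the only table
  consistent with the margins.

Rank association (`spearmanRho()`) uses mid-ranks and a seeded two-sided
permutation test with add-one correction — at panel scale ($n \approx 35$)
the t approximation is not trustworthy. GC comparison uses the paired
Wilcoxon signed-rank test, exact for $n \le 25$ and normal-approximated
with continuity correction beyond, reporting the median paired difference
in percentage points; all-zero differences return p = 1 directly, where
the signed-rank statistic is undefined.

# Capsule-loss trajectories

`capsuleAuc()` integrates the capsulated fraction by the trapezoid rule
over days 0–5 (the window is a parameter; the early window is where most
capsule loss occurs, and the estimator is the natural one for daily
samples). A missing day 0 defaults to a fully capsulated founder; missing
interior days are linearly interpolated with a message; days beyond the
window are ignored. The AUC has units of days: a constant fraction $f$
gives exactly $f \times \mathrm{window}$, and pointwise-lower trajectories
never score higher. Treatment comparisons use the two-sided Mann–Whitney
U test (a rank test is the safe default at $n = 6$ populations, where
normality is unverifiable),
exact for combined $n \le 20$, with a Welch t test behind
`parametric = TRUE`.

# Synthetic data: what it emulates, and what it does not

All generators derive independent substreams from one root seed (fixed
per-component offsets), so adding a generator never perturbs another's
output, and identical seed plus configuration reproduce byte-identical
files.

- `generateProteomePair()` plants homologs by copying a protein and
  substituting exactly `round((1 - identity) * L)` positions, so realized
  identity is the target up to rounding to whole substitutions.
  `exactHitsFromTruth()` emits the corresponding lossless hits table (one
  hit per direction, full coverage), bypassing external aligners so BBH
  recovery can be checked exactly.
- `generateInfectionPanel()` draws each replicate as Bernoulli with
  probability `pSame` (0.33) within a CLT and `pDiff` (0.036) across,
  the same-/cross-CLT infection frequencies of the regime it emulates.
  The default 35-strain serotype multiplicities (6, 5, 3, 3, four pairs,
  ten singletons) are chosen so ordered same-CLT combinations number 105
  of 1225 — the published per-strain serotype table is not reproduced,
  only its pair arithmetic. Note the probabilities are *per replicate*:
  the generator's parameter-recovery tests therefore check the
  per-replicate infection frequency, not the ≥ 1-replicate rate (which is
  $1 - (1 - p)^3$ under this model).
- `generateDefenseScenario()` builds one intact prophage genome per
  strain, assigns type II R-M systems with the supplied motifs, plants one
  concretized site each (random strand) in another strain's prophage, and
  plants protospacers with exact mismatch counts placed in the window core
  (so coverage-allowed truncations cannot shed them and planted mismatch
  counts are exact). The truth record includes chance background motif
  occurrences found by post-scan.
- `generateTrajectories()` iterates
  $f' = f(1-\mu) \big/ \{f(1-\mu) + (1 - f(1-\mu))(1+s)\}$ per generation
  (7 generations/day, the 1:100 daily-dilution regime; 10 days) with
  binomial sampling of 100 phenotyped clones per day. Default selection
  coefficients per environment (MMC 0.30 > LB 0.10 > MMC+citrate 0.05 >
  LB+citrate 0.02) order predation intensity as the experimental design
  implies. This is a fixture — selection against the capsule with
  unidirectional loss mutation — not a mechanistic claim: there is no
  explicit phage population, no reacquisition of the capsule, no
  demography.

Because the generators are simplified, passing tests demonstrate the
correctness and calibration of the *computations* (BBH recovery, exact
tests, threshold logic, AUC arithmetic, type-I error control and power in
the emulated regime), not properties of real genomes: real proteomes have
paralogs and domain shuffling that strain BBH assumptions, real infection
outcomes are correlated across replicates and strains, and real capsule
loss involves mutational spectra and frequency dependence that the
recursion ignores.

# Test and verification scale

The oracle suites run brute-force enumerations at sizes chosen to finish
within a normal test run while covering the combinatorics: exact-test
equality on all 2×2 tables with $N \le 30$; LCS equality exhaustively for
all 4-letter strings to length 3 plus sampled pairs to length 8; spacer
and motif scans against exhaustive window enumeration on 200 random
planted cases; BBH against exhaustive best-hit search on 5-proteome ×
8-protein panels. Calibration runs use 200 study-regime panels (power and
parameter recovery) and 1000 null panels (size), and trajectory
monotonicity is checked across a selection-coefficient grid with fixed
seeds. Each suite states its expectations at the tolerance the statistic
supports — exact equality for deterministic arithmetic, confidence-bound
checks for stochastic rates.

# Known limitations

- BBH-based wGRR treats proteomes as bags of single-copy genes; paralogs
  compete for one best hit per proteome pair.
- R-M targeting depends entirely on supplied recognition motifs; systems
  without motifs are skipped, which can only under-call targeting.
- The repressor statistic is gap-cost-free and therefore insensitive to
  rearrangement; it is a similarity floor, not an alignment identity.
- `spearmanRho()` and the permutation machinery assume exchangeability;
  phylogenetic structure in a real panel violates it.
- The CLI wrapper is a thin convenience; the R functions are the
  supported interface.
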