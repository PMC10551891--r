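---
title: "Methods: from raw quantification tables to integrated ppm datasets and ortholog amino-acid usage"
author: "ppmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw quantification tables to integrated ppm datasets and ortholog amino-acid usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppmkit)
```

# The problem

Quantitative proteomics experiments report protein amounts in
instrument-specific, run-specific units: summed precursor intensities for
MaxQuant-style protein groups, peak intensities or spectral counts for
peptide-level tables. Before datasets can be compared, ranked by quality, or
merged into a per-organism consensus, they must be placed on one common
relative scale. `ppmkit` implements that whole chain: normalization to parts
per million (ppm), network-based quality scoring, greedy weighted
integration, and a downstream comparative analysis of amino-acid usage in
orthologous protein domains as a function of protein abundance.

# Quantification models

## The ppm scale

A dataset maps each quantified protein to its share of all quantified
protein molecules, scaled to one million:

$$\mathrm{ppm}_i = 10^6 \cdot \frac{r_i}{\sum_j r_j}$$

where $r_i$ is the protein's raw (pipeline-specific) abundance. Every
dataset the package produces sums to $10^6$ within $10^{-6}$ relative
tolerance — this conservation holds after filtering, after pairwise
combination and after integration, and the test suite asserts it across all
pipelines. Proteins quantified at zero are kept at 0 ppm: "measured but not
detected" is informative and distinct from "not measured". Whether to drop
such rows before normalization is genuinely open; keeping them changes no
nonzero ppm value (the normalizing sum is unaffected) and preserves
missingness semantics for integration.

## Protein-centric (iBAQ-style)

For protein-group tables, contaminant (`CON_`) and reversed-decoy (`REV_`)
entries are removed first, then

$$r_i = \frac{\text{summed precursor intensity of the group}}
            {\#\{\text{theoretically observable tryptic peptides of } i\}}.$$

"Theoretically observable" means: peptides from a complete (zero missed
cleavages) trypsin digest — cleaving C-terminal to K/R except before proline
(the Keil rule) — whose length falls in a detectability window. The window
defaults to 6–30 residues, the usual iBAQ convention; it is a tunable
parameter (`min_len`, `max_len`, in residues) because instruments differ.
Multi-member protein groups resolve to the first member found in the
proteome (the MaxQuant "majority leader" convention); the remaining members
are discarded. This is a design choice — group-to-protein assignment is
underdetermined by the input format — and the run report counts every
unresolvable group.

## Peptide-centric (length-normalized)

For peptide tables (intensities or spectral counts), peptides are first
filtered at an FDR score threshold of 0.01 where scores are present
(unscored tables are assumed pre-filtered), then

$$r_i = \frac{\sum_{p \in i} q_p \cdot |p|}
            {\text{total length of observable tryptic peptides of } i}$$

with $q_p$ the peptide quantity and $|p|$ its length. The denominator —
the "corrected" length — is interpreted here as the summed length of the
*observable* peptides only, i.e. the correction excludes stretches of the
protein that complete digestion renders undetectable. This interpretation
is a documented decision, exposed through the same window parameters, since
the upstream literature does not restate the exact definition. With a
single observable peptide covering the whole observable length and quantity
equal to intensity, the two pipelines coincide (a consistency check in the
test suite).

# Quality: the interaction z-score

Interacting proteins tend to be expressed at broadly similar levels, so a
protein-interaction network gives an internal consistency probe that needs
no ground truth. For a dataset $D$ and network $N$:

1. Over all edges with both endpoints quantified above zero, compute the
   median of $|\log_{10}(\mathrm{ppm}_a/\mathrm{ppm}_b)|$ — the observed
   median.
2. Shuffle the abundance values across the quantified protein labels
   (network fixed), recompute the median; repeat 500 times (configurable).
3. $z = (\overline{m}_{\mathrm{null}} - m_{\mathrm{obs}})/
   \mathrm{sd}(m_{\mathrm{null}})$.

The orientation is fixed so that *larger z means better quality*:
better-than-random consistency gives a small observed median, hence a
positive z. Numerical properties the tests assert: z is invariant to
rescaling all ppm by a constant and to the logarithm base (both cancel in
the ratio–median–z chain), and it is bit-reproducible given the seed, which
is a required argument — there is no silent nondeterminism in scoring.
Zero-ppm proteins are excluded (their log-ratio is undefined); shuffling
permutes values over the dataset's own quantified proteins, not the whole
proteome, because the null should hold the dataset's value distribution
fixed. The median of an even number of values is the mean of the two
central ones. Degenerate cases fail loudly: no overlapping edge, or a null
with zero spread (e.g. all abundances equal), are errors rather than NaNs.

On null networks (edges drawn uniformly at random) the z-score is
calibrated: across 100 synthetic studies about 95% of scores fall within
±3. On networks built to connect similar-abundance proteins, z rises well
above 5. Both behaviours are acceptance-tested.

# Integration by greedy weighted averaging

Given several datasets for one organism or tissue:

1. Score each dataset; sort descending (ties broken lexicographically by
   dataset name, so input order never matters).
2. The best dataset seeds the merge with weight 100%.
3. Each subsequent dataset is combined with the running merge at a grid of
   weights over $[0,1]$ and the candidate with the highest interaction
   z-score is kept.

The weight grid has 11 points $\{0, 0.1, \dots, 1\}$. The governing
description — ten equally spaced weights from 0 to 100% — is ambiguous
between 10 and 11 points; 11 was chosen so both endpoints are reachable,
and the count is configurable. Because $w = 0$ is always on the grid, the
integrated score can never fall below the best single dataset's score under
the same seed; the same shuffle seed is reused for every candidate within
one integration so that weight selection compares like with like, and a tie
prefers the smaller weight (the established merge).

The combination arithmetic itself is not specified by the integration
description, so it is a package design choice: proteins present in both
sides combine as a weighted *geometric* mean
($10^{(1-w)\log_{10} a + w\log_{10} b}$), because protein abundances are
log-distributed; proteins on one side only are carried over scaled by that
side's weight mass, giving the union of coverages. An arithmetic-mean mode
(`space = "linear"`) is provided for sensitivity analysis. A shared protein
with a zero value on one side is treated as absent from that side. The
endpoints are exact: $w=0$ returns the first dataset unchanged, $w=1$ the
second.

For three datasets and this grid, the greedy search and an exhaustive
search over all weight combinations agree on the synthetic trios used in
the tests (one clean, one medium, one noisy replicate of a common truth).
This is a property of such graded inputs, not a theorem: with datasets
whose errors interact pathologically, greedy and exhaustive optima could
differ, which is why the trace of every merge step (weights tried, scores)
is part of the result.

# Identifier mapping and reciprocal best hits

External identifiers are resolved against an alias table (exact,
case-sensitive string match across all namespaces); an alias that points to
more than one internal id is reported as unmapped rather than guessed.
Records that cannot be mapped by name can be mapped by sequence: reciprocal
best hit (RBH) under global alignment, requiring the pair to be mutual best
scorers with at least 90% identity (default) in the alignment. Ties for
best hit exclude the protein — a one-to-one claim is not made when the
evidence is ambiguous.

# Alignment conventions

Global Needleman–Wunsch alignment with affine gaps (Gotoh three-state
dynamic program) is implemented in C++ so that whole tables of domain pairs
align in one call; the test suite checks it against exhaustive enumeration
of all gapped alignments (sequences up to length 8) and against an
independent aligner on longer random pairs. Conventions:

* substitution matrix BLOSUM62, gap open 10, gap extend 0.5 — mirroring
  EMBOSS needle/needleall defaults, since the exact penalties used with
  such tools are rarely printed; all three are parameters;
* a gap of length $L$ costs $\mathrm{open} + (L-1)\cdot\mathrm{extend}$;
* end gaps are penalized (true global alignment);
* identity = identical columns / alignment length, gap columns counted in
  the denominator (the EMBOSS convention);
* `X` is accepted as an unknown residue and scores via the matrix's X
  column (mismatch-level); any other non-standard letter is an error, not a
  silent skip.

# Ortholog-domain amino-acid usage

The comparative analysis asks whether particular residues — by default the
sulfur-containing amino acids C and M — are depleted in the abundant
proteins of a query species relative to a reference species. Restricting
the comparison to *aligned domains within strict one-to-one orthologs*
cancels differences in overall proteome composition; complex orthology
groups (paralogs on either side) are excluded outright.

Per ortholog pair: for each domain type annotated on both proteins, all
cross-products of same-named domain instances are aligned (domains are
extracted as 1-based inclusive subsequences; whole-protein alignment is out
of scope) and only the highest-scoring instance pair is kept; pairs below
40% identity are dropped. Residues of interest are counted in the ungapped
residues of each aligned string — gap columns contribute nothing — and the
usage ratio is $\mathrm{count}_a/\mathrm{count}_b$. Pairs where either side
has zero residues of interest are excluded: a ratio is only meaningful when
both proteins register the amino acid, and this also keeps ratios finite
and positive. The reference protein's abundance (an explicit
`abundance_dataset` argument — typically the reference species'
whole-organism integrated data) is attached to each row.

When several domain types qualify for one ortholog pair, each contributes
a row by default; whether to aggregate per pair is genuinely open, so an
`aggregate` flag (mean of ratios per pair) is provided. The headline
statistic is Spearman's rank correlation between usage ratio and abundance
(average ranks for ties, two-sided p by the t approximation); for
visualization, rows are sorted by abundance and split into six
equal-size bins summarized by median and quartiles, and per-species-pair
results assemble into rho/p/star matrices with stars at p < 0.01, < 0.001
and < 0.00001.

# The synthetic-data generator

Every stage is testable without downloads because the `make_*()` generators
emulate each input format with controlled statistical structure:

* **Proteomes** — i.i.d. sequences from a configurable residue frequency
  vector (default uniform 0.05, the simplest null for composition tests),
  lengths normal (mean 300, sd 80, minimum 30 residues).
* **Abundances** — $\log_{10}$ ppm normal with sd 1.3 by default, spanning
  roughly five orders of magnitude as real proteomes do.
* **Networks** — edges sampled from all pairs with weight
  $e^{-c\,|\Delta\log_{10}\mathrm{ppm}|}$; $c = 0$ is the calibration null,
  $c = 5$ a strong consistency signal.
* **Peptide tables** — each protein's observable tryptic peptides with
  quantities equal to ppm times $10^{N(0,\,0.2)}$ multiplicative noise
  (zero noise recovers input ppm exactly; at sd 0.2 rank recovery stays
  above Spearman 0.95). Optional planted FDR failures exercise the filter.
* **Ortholog sets** — domain pairs derived from a common master sequence
  (at least three sulfur residues each); the reference copy retains each
  sulfur residue with probability 0.9, the query copy with probability
  $0.9\,e^{-\beta\,\mathrm{rank}/n}$, so the expected log usage ratio falls
  linearly with abundance rank at slope $-\beta$ and both counts carry
  binomial noise. $\beta = 0.5$ at $n = 500$ pairs is reliably detected
  (negative rho, p < 0.01); $\beta = 0$ yields non-significant results in
  the vast majority of runs. Low-identity and complex-orthology pairs can
  be planted to test the filters.

Each generator draws from its own RNG stream derived from the config seed,
so regenerating one input does not shift the others, and every generator is
a pure function of its config.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: mass-spectrometer noise physics (only
multiplicative lognormal noise), peptide detectability bias (flyability,
charge, modifications), shared/razor peptides across homologous proteins,
real domain architectures and indel patterns, phylogenetic correlation
between ortholog pairs, and real interaction-network topology (hubs,
modules). Conclusions about real datasets still require the usual caution;
the tests establish that the machinery computes what it claims.

# Numerical choices and degenerate inputs

* Tissue-specificity z-scores standardize $\log_{10}(\mathrm{ppm} + 1)$ per
  gene across tissues with the $n-1$ denominator; the 1-ppm pseudocount
  keeps zeros finite on the ppm scale. Genes constant across tissues get a
  zero row (sd floor) and are flagged, not dropped silently.
* All medians use the mean-of-central-pair convention for even counts.
* Seeds are required wherever randomness enters (scoring, integration) and
  are recorded in results (`consistency_score$seed`, integration trace,
  run manifests) for provenance.
* Problem sizes in the test suite — proteomes of 100–150 proteins, networks
  of a few hundred edges, 500 ortholog pairs, 100 calibration seeds — were
  chosen as the smallest sizes at which the statistical properties under
  test (calibration bands, detection rates) are stable.

# Known limitations

* Group-to-protein resolution uses the leader convention; quantities of
  ambiguous multi-member groups are not redistributed.
* The interaction network is binary; confidence-weighted edges are not
  supported (a score cutoff is the user's responsibility at input time).
* Integration does not model covariance between datasets that share raw
  data; it assumes components are independent estimates.
* The greedy weight search is exact only per step; the full trace is
  emitted so alternative weightings can be audited.
* No alternative proteases, missed-cleavage enumeration or peptide mass
  computation in the digest module.
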