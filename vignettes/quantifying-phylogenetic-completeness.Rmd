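---
title: "Quantifying phylogenetic completeness and the lagerstätten effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phylogenetic completeness and the lagerstätten effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fossilccm)
```

## The metric

A morphological phylogenetic matrix can only place a fossil species if its
characters can be scored, and characters can only be scored from anatomy
that fossilized. The Character Completeness Metric 2 (CCM2) makes this
operational at the species level:

$$\mathrm{CCM2}_i \;=\; 100 \times \frac{|\,\text{characters scorable from the
element union of all specimens of } i\,|}{|\,\text{characters applicable to } i\,|}$$

Three modelling commitments deserve spelling out.

**A character is scorable iff *all* of its required elements are
preserved.** Most characters reference a single bone, but ratio and
articulation characters reference several; a character cannot be scored
from a subset of the elements it compares. Where a scoring convention
would count a partially exposed multi-element character as scorable, our
rule is (weakly) conservative; for the common single-element case the two
readings coincide. The required-element-set representation subsumes both.

**Scoring uses the species-wide element union.** CCM2 asks what the
species as a whole can contribute to a matrix, so elements are pooled
across all referred specimens (`unionPreservation()`). Per-specimen scores
remain available for diagnostics, and pooling can only raise the score —
a property the test suite checks.

**Limbless lineages get a reduced denominator ("true completeness").**
A snake is not "incomplete" for lacking a femur. Every character that
requires *any* element from the four limb/girdle partitions
(pectoral girdle, forelimb, pelvic girdle, hindlimb) is removed from a
limbless species' denominator — including characters spanning a limb and
a non-limb element, which such a species can never fully exhibit. With
the packaged squamate map this yields 860 applicable characters for
limbed and 710 for limbless taxa.

### The packaged squamate map

The combined squamate scoring set this package ships
(`squamateCharacterMap()`) is a **synthetic reconstruction**: the real
combined set's character-by-character element assignments were never
published. The reconstruction is constrained to the published structural
totals — 860 characters in all, 150 on limbs and girdles, and over
two-thirds (here 590) on the skull and mandibles — and is deterministic,
with single-element characters cycling through each partition's elements.
Totals-level conclusions (denominators, partition densities) are exact by
construction; per-character identities are not meaningful and nothing in
the package depends on them.

### Converting skeletal to character completeness

Published completeness assessments for some clades exist only as the
Skeletal Completeness Metric (SCM2): the proportion of the skeleton
preserved. Given per-partition proportions $p_r$ and the number of
characters $c_r$ each partition carries, the conversion is the
character-density-weighted mean

$$\mathrm{CCM2} = 100 \times \frac{\sum_r p_r c_r}{\sum_r c_r}.$$

No finer-grained procedure is possible without per-bone data, and this is
the only form consistent with using a character matrix as the conversion
key; when only a scalar SCM2 is available it is broadcast to all
partitions with an explicit warning. When $p_r \in \{0,1\}$ and no
character spans partitions, the conversion agrees exactly with direct
scoring of the corresponding element sets (a tested invariant).

## Statistical comparisons

Distribution comparisons are deliberately nonparametric — CCM2
distributions are bounded, skewed and often bimodal:

* **Mann-Whitney U** for location: exact enumeration of the null when
  $n_x n_y \le 400$ and the samples are tie-free, otherwise the normal
  approximation with tie and continuity corrections. The method actually
  used is tagged on every result, and both p-values are emitted when both
  are cheap to compute, so small discrepancies against other software's
  tie policies are auditable.
* **Kolmogorov-Smirnov** for shape: $D = \sup |F_x - F_y|$ with the
  asymptotic p-value at effective size $n_x n_y/(n_x+n_y)$. CCM2 samples
  routinely contain ties (many species share a score), which the
  asymptotic path tolerates; exact small-sample KS p-values are undefined
  under ties and are not attempted.
* **Bonferroni correction within one panel.** A family is one results
  panel — e.g. all pairwise landmass comparisons for one taxon group —
  with $m = \binom{k}{2}$ and adjusted level $\alpha/m$, $\alpha = 0.05$.
  Families are never pooled across panels: pooling would make one panel's
  size depend on unrelated analyses.
* **Violin summaries.** The reported interval is the central 95% *data*
  interval (2.5th–97.5th percentiles), not a standard-error band; common
  violin implementations are ambiguous on this point, so the choice is
  recorded in the output (`interval_type`). Quantiles use linear
  interpolation between order statistics (type 7, R's default).

Under the null, the family-wise false-flag rate of the combined
MW + KS battery at $\alpha/m$ stays below $\alpha$ (the exact tests are
discrete and conservative, and the two tests are strongly dependent);
the acceptance suite measures this over 2,000 simulated families.

## Quantifying the lagerstätten effect

Two complementary measurements:

**Leave-unit-out** (`leaveUnitOut()`): compare a scope's full CCM2 sample
against the same sample minus one unit's species. The default contrasts
full vs reduced — mirroring "with and without" panels — rather than
unit-vs-rest; the two answer different questions (does the unit move the
aggregate picture? vs is the unit different?), and the alternative is
available via `compare = "unit_vs_rest"`. The full and reduced samples
overlap by construction, which makes the test conservative for the
question asked. The Jehol (Yixian + Jiufotang) and Campanian Gobi
(Djadokhta + Baruungoyot) formation pairs ship as named unit-set aliases
since each pair is analysed as one assemblage.

**Matrix representation** (`matrixRepresentation()`): the share of a
phylogenetic matrix's terminals derived from one unit, with the number of
distinct families among them. The denominator is fossil (extinct)
terminals, since extant terminals are not supplied by any deposit; the
percentage over all terminals is emitted alongside because published
panels differ on this, and family assignments come from an input table
rather than being parsed out of taxon names.

## Occurrence vetting

`loadAndVet()` applies three rules, each logged per species: keep
species-level rows only (matrices use species as terminals); drop
material assigned to extant species (their morphology is fully observable
regardless of fossils); collapse duplicate rows, summing specimen and
locality counts. Conflicting categorical labels on duplicates keep the
first-seen value with a logged conflict — a species occurring in several
units is thus assigned to its first-listed occurrence. Landmass,
environment, lagerstätte-class and taxon-group labels are controlled
vocabularies and unknown labels are hard errors: a silently novel label
would quietly fork group denominators. The environment vocabulary is a
superset of any one study's usage and is user-editable, as is the
element→partition table.

Minimum sample sizes default to 6 species per landmass and 17 per
depositional environment — below these, median and distribution-shape
comparisons are uninformative.

## The synthetic generator

`generateFossilRecord()` draws a fossil record with the structure the
analysis assumes, so every downstream stage can be validated against
known truth:

* species are allocated to geologic units; unit $u$ has preservation
  quality $q_u \in (0,1]$ and specimen rate $\lambda_u \ge 0$;
* a species has $s = 1 + \mathrm{Poisson}(\lambda_u)$ specimens (every
  described species has at least one);
* each specimen preserves each element of partition $r$ independently
  with probability $q_u w_r$, where $w_r \in (0,1]$ is the partition's
  fragility weight; the species record is the union over specimens;
* a per-group limbless fraction generates limbless species with limb
  partitions forced absent and the flag set;
* every species has its own substream seeded deterministically from the
  config seed, so extending the allocation never perturbs earlier draws.

Element preservation is conditionally independent given $(q_u, w_r, s)$,
which gives a closed-form expected CCM2 (`expectedCCM2()`): an element
with per-specimen probability $p$ survives the $s$-specimen union with
probability $1-(1-p)^s$, and with $s = 1+\mathrm{Poisson}(\lambda)$,
$E[x^s] = x\,e^{\lambda(x-1)}$, so multi-element characters are handled
exactly by inclusion-exclusion over their required sets. The generated
mean converges to this expectation (tested at $n = 10{,}000$ within
3 standard errors) and the expectation is monotone in $q$, $w$ and
$\lambda$.

**Default configuration.** `defaultSimulationConfig()` encodes the study
conditions the package is built around: 797 squamates, 402 non-avian
theropods and 128 Mesozoic birds allocated over 25 units on ten
landmasses, with the published assemblage sizes for the exceptional units
(50 Gobi squamates across the two aeolian formations, 7 Jehol squamates,
62 Jehol + Gobi theropods, 60 Jehol birds, 44 Quercy-style karst
squamates, 35 lacustrine-lagerstätten squamates). Where the underlying
quantities were never published — unit preservation qualities, fragility
weights, the 30% limbless fraction — values were chosen once for realism:
$q$ high (0.75–0.85) for the Gobi and Jehol style units, very low
(0.05–0.08) for the microsite-style units that dominate the squamate
background, intermediate (0.2–0.45) for ordinary fluvial and marine
units; fragility makes mandibles and vertebrae hardier than skulls and
distal limbs and integument rare. These defaults reproduce the
qualitative structure of the empirical record (a fragmentary squamate
background with a high-completeness aeolian assemblage; a strongly
preserving Jehol; a more complete theropod background), not any printed
statistic.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: anatomical articulation
correlation (real specimens preserve co-articulated element blocks, not
i.i.d. elements), collection and description effort varying by taxon
charisma, taxonomic error, time-dependent sampling, and any correlation
between preservation quality and diversity. Conclusions about those
features need real occurrence data ingested through the same interfaces.

## Numerical and degenerate-input choices

* Percentages are stored at full precision; two-decimal formatting is
  applied only when printing.
* Empty element sets are valid preservation records (scoring 0);
  an empty sample or group is an error, not a silent skip.
* Removing a unit that would empty a sample is an error; removing a unit
  with no members in scope is a no-op with no test run.
* Character ids are 1-based, following NEXUS conventions; merged maps
  carry a provenance table to the parent matrices, and the overlap list
  driving a merge is an explicit input file — overlap judgements are
  expert decisions the software should record, not re-derive.
* NEXUS ingestion enforces the file's own declarations (NTAX/NCHAR,
  MISSING/GAP symbols) and fails with the offending line where it can.

## Validation problem sizes

The test and acceptance suites use: 1,000 random map/record pairs
($C \le 50$) against a brute-force scoring oracle; exhaustive
Mann-Whitney enumeration for all tie-free samples up to $6+6$; 1,000
random KS pairs against direct ECDF evaluation; 2,000 null comparison
families of three groups of 12; 200 seeds of the two-unit
($q = 0.9$ vs $0.3$, $n = 50$ each) recovery design; and a 10,000-species
Monte-Carlo check of the closed form. These sizes give binomial standard
errors small enough for the stated bounds while keeping a full run in a
few minutes.

## Known limitations

* The packaged squamate map is a totals-constrained reconstruction (see
  above); analyses needing real per-character assignments must supply
  their own map via `readRegionMap()`.
* Only exact-name de-duplication is performed; synonymy resolution is out
  of scope.
* Ages are carried through but unused: no time-series analyses.
* The KS p-value is asymptotic; for very small groups the minimum-sample
  thresholds, not the test, are the real guard.
* Drawing violin plots is left to the caller; the package exports the
  numeric summaries.
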