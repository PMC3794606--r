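---
title: "The RE-transactivation code: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The RE-transactivation code: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53REcode)
```

## The biological problem

p53, p63 and p73 bind DNA through nearly identical DNA-binding-domain
residues, yet regulate only partially overlapping gene sets. A useful probe
of this selectivity is a class of *change-of-spectrum* mutants (p73 S139F
and its p53/p63 counterparts) that gain activity on some response elements
(REs) while losing it on others. The sequence features that decide which way
a given RE goes form a compact *RE-transactivation code*, and this package
implements that code together with everything needed to apply and test it:
consensus scanning, signature scoring, transactivation classification and
association statistics, paired-dinucleotide logos, and cooperative
binding-curve fitting.

## The consensus model and site architectures

A canonical RE is two decameric half-sites matching the degenerate IUPAC
pattern `RRRCWWGYYY`, separated by a spacer of 0–13 nt. `consensusModel()`
captures the pattern, the spacer range and a per-half-site mismatch
tolerance. `scanHalfSites()` slides a 10-nt window over both strands of the
input (naive window scanning; the intended scale is promoters and reporter
constructs, not genomes), and `assembleSites()` pairs same-strand half-sites
into full sites, promotes half-sites with an adjacent consensus-conforming
pentamer (`RRRCW` 3' or `WGYYY` 5', spacer 0) to three-quarter sites, and
reports the rest as half-sites.

Conventions where the underlying definitions are open:

* Coordinates are 0-based half-open internally and 1-based inclusive in
  reports (`GRanges`); BED output is 0-based half-open per the BED standard.
* Both strands are always scanned. Palindromic sites therefore appear twice;
  `dedupe = TRUE` collapses them to the plus strand.
* `N` in a scanned sequence counts as a mismatch at that position.
* All overlapping assemblies are reported — there is no greedy selection;
  full sites are ordered smallest-spacer-first, then leftmost.
* The three-quarter-site rule (half-site plus one adjacent, spacer-0,
  exactly conforming quarter) is an operational definition; published
  examples of three-quarter sites are described only at figure level, so
  this rule should be read as one defensible formalisation, not the only
  one.
* Scanning defaults to 0 mismatches per half-site, but scoring accepts any
  20-mer: most physiologically validated REs deviate from the consensus
  somewhere, and the code below is defined positionally, not conditionally
  on consensus conformance.

## The signature code

On the spacer-removed 20-mer (positions 1–20), `ryProfile()` evaluates:

* four **RY slots** — `GG` at positions 2–3 and 12–13, `CC` at positions 8–9
  and 18–19 — giving an RY count of 0–4;
* the two **WW motifs** at positions 5–6 and 15–16 inside the `CWWG` cores
  (positions 4–7 and 14–17), labelled `AT`, `TA`, `AA`, `TT` or `other`;
* `innerOnly`, flagging single RY signatures that sit between the two cores
  (slots at 8–9 or 12–13), where a positional bias toward enhanced response
  has been observed.

`s139fPredict()` applies the code: RY count 0 predicts *reduced*
transactivation by the change-of-spectrum mutant; RY count ≥ 1 predicts
*enhanced*, scaling with the count. The numeric score,
`ryCount + 0.5 × [any core WW ∈ {AA, TT}]`, is a package convention — no
combined numeric score is defined in the source literature — and its only
contract is monotonicity consistent with the qualitative ordering: the RY
count dominates and the AA/TT core acts as a secondary bonus, never a veto
(the strongest-bound 4/4-RY RE has AT cores in both half-sites).
`wwRank()` orders the WW motifs by wild-type activity (AT highest, TA
lowest, AA/TT tied in between, non-consensus last). The `indeterminate`
class is reserved for future rules; the default rule never emits it, because
REs with *similar* mutant/WT activity are not separable from their sequence
by the published code.

## Transactivation classification and association statistics

`foldInduction()` is the reporter summary: mean of normaliser-corrected
replicate readings over the normaliser-corrected empty-vector background.
Replicates are aggregated by the mean; standard deviations are display-only
and are not propagated into classification. `classifyRatio()` classifies the
mutant/WT ratio with strict thresholds — enhanced above 1.5, reduced below
0.67, similar in the closed interval between them. (A published version of
the *similar* band is printed with inverted inequalities, an evident typo;
the closed interval is used.) `superTransRate()` is the corresponding tally
for uniformly hyperactive alleles such as p73 S260N, whose phenotype is
independent of the S139F code; such records are only annotated, never
predicted from sequence.

`fisherExactTwoSided()` implements the two-sided Fisher exact test by
point-probability summation (the most common two-sided convention, with a
relative tolerance of 1e-7 guarding floating-point ties on the hypergeometric
support). It is enumeration-exact at every table size and is checked in the
test suite against both a literal binomial-coefficient enumeration and
`stats::fisher.test`. `signatureAssociation()` builds the 2×2 table at
half-site resolution (two half-sites per RE, so a group of 22 REs
contributes 44 half-sites), contrasts the enhanced and reduced classes on
the core-WW AA/TT feature, and adds a Spearman rank trend of ratio against
RY count — the package's operationalisation of "enhanced activity
proportional to the number of RY signatures", which the source describes
without naming a statistic. All half-sites are counted in the denominators,
including those with non-W cores; whether the published denominators
excluded any half-sites is not stated. p-values are reported raw, without
multiple-testing correction, matching how single tests are reported in this
literature.

```{r assoc}
tab <- matrix(c(28, 16, 5, 13), 2, byrow = TRUE,
              dimnames = list(c("enhanced", "reduced"), c("AA/TT", "other")))
fisherExactTwoSided(tab)
```

## Dinucleotide logos

`dinucleotideFrequencies()` generalises the per-position sequence logo to
the six signature slots, recording exact empirical dinucleotide fractions
per slot plus the conventional 20×4 per-position frequency matrix as the
baseline (the marginal of each slot joint reproduces the corresponding
mononucleotide row exactly). There is no entropy scaling or small-sample
correction: glyph size in `renderLogo()` is strictly proportional to
frequency, which is what the paired-logo display is meant to show. The
default rendering draws every dinucleotide at or above `minFreq` (default
0.05), colouring consensus-compatible ones and greying the rest;
`consensusOnly = TRUE` is the strict mode that drops non-compatible
dinucleotides entirely. REs with spacers are included after spacer removal.
Rendering embeds no timestamps, so a given logo always produces a
byte-identical SVG.

## Cooperative binding curves

Fluorescence-polarization titrations are converted to fraction bound by
linear interpolation between the free and bound polarization endpoints
(`fractionBound()`, clipped to [0, 1] with a flag) and fitted with the
four-parameter Hill model

$$f(c) = f_0 + (f_{max} - f_0)\,\frac{c^h}{EC_{50}^h + c^h},$$

where the EC50 is reported as the dissociation constant under the assumed
stoichiometry (one dimer per 12-bp half-site, one tetramer per 20-bp full
site). The fit (`fitHill()`) is unweighted least squares on pooled
replicates via bounded Levenberg–Marquardt with five multi-starts (EC50
initialised at the interpolated half-max crossing and jittered ×0.2–×5;
h started at 1; asymptotes at the response extremes; bounds h ∈ [0.2, 5],
EC50 ∈ [min positive conc/10, 100 × max conc]; convergence tolerance 1e-10).
The zero-concentration anchor constrains only the lower asymptote. By
default no ligand-depletion correction is applied even though the 50 nM DNA
concentration is not always negligible against the Kd — this matches the
EC50 ≡ Kd treatment being emulated; `fitHill(..., depletion = TRUE)` fits
the quadratic exact-binding model instead (Hill coefficient fixed at 1,
since cooperativity is not identifiable there). Weighting, replicate
pooling and the
exact 18-point grid spacing are not documented for the original
measurements; the defaults here (unweighted, pooled, a zero anchor plus 17
log-spaced points from 1 to 20,000 nM) are this package's choices.

Censoring is a reporting convention for unsaturated curves, mirroring
published "Kd > top concentration" entries whose exact rule is unstated: a
fit is censored when the maximum observed response stays below 60% of the
fitted span above `f0`, or when the fitted EC50 exceeds the top tested
concentration; the Kd is then reported as a lower bound equal to the top
concentration, and `affinityRatio()` propagates the bound as a one-sided
qualifier.

```{r hill}
conc <- defaultTitrationGrid()
fit <- fitHill(conc, hillFraction(conc, ec50 = 230, hill = 1.9))
fit
```

## What the synthetic generators emulate

Raw per-RE activity tables and polarization titrations for the original
study are not redistributable, so `generateRESet()`,
`generateTransactivation()` and `generateBindingCurve()` produce data with
the same statistical structure, each a pure function of a seeded
`syntheticConfig()`:

* **RE sets** are consensus-conforming 20-mers with controlled composition.
  Defaults reflect the published panel: RY-count mix (0.24, 0.19, 0.19,
  0.19, 0.19) for counts 0–4 (about a quarter of full-site REs lack the
  signature), WW mix AT 0.35 / TA 0.12 / AA 0.265 / TT 0.265 (roughly half
  of half-site cores are AA or TT, AT otherwise most common), and a spacer
  point mass at 0 (almost none of the tested full sites had one). Consensus
  mismatches (rate 0.1) touch only the four positions outside the RY slots,
  WW motifs and invariant core C/G, so recorded truth labels are exact by
  construction.
* **Transactivation** follows a log-linear ratio model,
  `log ratio = log 0.5 + log 1.6 × ryCount + log 1.3 × [any WW ∈ {AA,TT}] +
  N(0, 0.2)`, with WT fold inductions lognormal (meanlog log 20, sdlog 0.8,
  a typical yeast reporter range). The betas are conventions that reproduce
  the qualitative structure — reduced at 0/4 RY, enhanced from about 3/4,
  similar in between — not estimates of real effect sizes.
* **Titrations** evaluate the Hill model on the 18-point grid with i.i.d.
  Gaussian noise per replicate.

What passing tests on these data do **not** show: the generators have no
chromatin context, no protein-level or isoform effects, no correlation
between neighbouring REs, replicate noise is lognormal/Gaussian rather than
instrument-specific, and the effect model is exactly the model the analysis
assumes — so recovery tests demonstrate correctness of the implementation,
not validity of the code on new biological data.

Two calibration properties deserve honesty notes, both visible in the
acceptance tests. First, the exact Fisher p-value is discrete and
conservative; across null simulations its distribution is correctly
calibrated at the 5% level (empirical rejection ≈ 0.04) but measurably
non-uniform (an atom at p = 1 and a conservative bulk), so a strict
Kolmogorov–Smirnov uniformity check fails — that is a property of exact
conditional tests, not a bug. Second, with the default effect sizes the
WW-feature Fisher test at 50 REs has low power (~12%): the log 1.3 WW bonus
induces a far weaker class contrast than the strongest published
contingency, whereas the Spearman RY trend detects the default effect
essentially always. Both facts are asserted at their stated bars in the
acceptance suite and left failing rather than re-tuned.

## Problem sizes used in the test suite

The suite runs entirely on generated or packaged data: scanner oracle
equivalence on 100 random 500-nt sequences at 0–2 mismatches; exhaustive
Fisher enumeration over all 46,375 2×2 tables with N ≤ 30; Hill recovery on
a 7×6 (EC50, h) grid noiselessly plus 200 noisy re-fits; association
simulations of 500 replicates at 50–200 REs. These sizes were chosen to
make the statistical assertions sharp while keeping the default test run
fast.

## Known limitations

* The code is categorical; there is no PWM or energy model, and no
  prediction is attempted for the *similar* band or for super-trans alleles.
* Three-quarter-site detection depends on the operational adjacency rule
  above.
* ConA/ConD/ConH in the packaged fixture table are reconstructions from a
  stated edit path and are labelled as such; they are used as worked
  examples of the code, not as ground-truth sequences.
* The default Hill fit assumes total protein ≈ free protein; affinities
  approaching the 50 nM labelled-DNA concentration should be read as
  apparent, or refitted with the depletion flag.
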