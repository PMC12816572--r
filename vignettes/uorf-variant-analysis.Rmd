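---
title: "Upstream ORF analysis of 5'UTR variants in a haploinsufficient disease gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upstream ORF analysis of 5'UTR variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfkit)
library(dplyr)
```

## The problem

In a dominant, haploinsufficient disease gene, anything that lowers the
translational output of the one intact allele can cause disease, and anything
that raises it is a candidate therapeutic lever. The 5' untranslated region
(5'UTR) is where much of that control lives: the scanning preinitiation
complex traverses it before reaching the main open reading frame (mORF), and
AUG-initiated upstream open reading frames (uORFs) along the way typically
repress mORF translation. Variants that *create* an upstream AUG, or that
*remove the stop codon* of an existing uORF so that it reads through the main
start codon out of frame (an overlapping ORF, oORF), are a recognised but
easily overlooked loss-of-function mechanism. Conversely, knocking out a
uORF start codon de-represses the main ORF.

`uorfkit` mechanises this analysis pathway for a single contiguous
5'UTR: uORF discovery and annotation, structural classification of variant
consequences, allele-frequency credibility filtering, and the statistics of
the dual-reporter assay used to validate candidate variants in vitro. The
package ships a constraint-driven synthetic fixture emulating the PKD1 5'UTR
architecture so that the whole pathway runs end to end with no external data.

## Coordinate model

A `transcript_model` ties genomic positions to transcript coordinates for
the UTR plus the first main-ORF codon. UTR bases are numbered `c.-L` (cap)
to `c.-1`; `c.1` is the A of the main AUG and `c.0` does not exist.
Internally all interval arithmetic uses 0-based cap offsets; HGVS-style
values appear only at the API boundary, which avoids a whole class of
off-by-one errors in interval math. Genomic intervals are 1-based inclusive
(the VCF convention), and the conversion helpers are the only place the two
conventions meet. On a minus-strand gene the cap is the *maximum* genomic
coordinate, so increasing genomic position maps to decreasing cap offset:

```{r}
fx <- generate_fixture(seed = 1)
genomic_to_tx(fx$model, c(2135898, 2135776, 2135758))
```

Multi-exon UTRs (intron-containing, splice-aware `c.` positions) are out of
scope: the region is modelled as one contiguous block.

## uORF scanning and annotation

`scan_uorfs()` reports every ATG in the UTR whose first in-frame stop codon
lies entirely within the UTR — a stop whose last base is at `c.-1` still
counts; one overlapping the main AUG does not. Only ATG starts are
considered; near-cognate starts (CUG and friends) are deliberately excluded.
Nested and overlapping ATGs each get their own record, because variant
diffing needs per-start identity.

```{r}
scan_uorfs(fx$utr)
```

Annotations per uORF:

* **Frame versus the mORF** — in frame exactly when the uAUG-to-mAUG
  distance is divisible by 3.
* **Kozak strength** — only the -3 and +4 positions of the core motif
  `A/GxxATGG` are scored: both matching is `strong`, one `moderate`, none
  `weak`. A truncated context is flagged, not fatal.
* **Conservation** — a codon is called conserved when all three bases exceed
  the basewise threshold (default 2.0, a PhyloP-like purifying-selection
  score) *or* the elementwise score (PhastCons-like, default 0.8) exceeds
  its threshold at all three bases. The two channels are independent and
  optional. The defaults follow the stricter of the two conventions in use
  for uORF work; a lower basewise cut-off (around 0.6) is sometimes quoted
  for observed uORF boundary conservation, and both thresholds are plain
  config values.
* **Peptide conservation** — mean pairwise percent identity over an aligned
  orthologue set, classified `high` (>= 80), `moderate` (50-80), `weak`
  (< 50), boundaries inclusive upward.

Evidence of uORF translation from ribosome-profiling catalogues is consumed
as a per-uORF boolean input when available; it is never computed here.

## Variant consequence classification

`classify_consequence()` applies the variant set (HGVS-like `c.` strings:
substitutions, single-base duplications, insertions, deletions; duplications
are normalised to their 3'-most equivalent transcript position), re-scans
the edited sequence, and matches ORFs across the edit by variant-adjusted
start coordinate. The structural diff is then summarised as one primary code
plus secondaries, with the primary chosen by a fixed severity ranking
(`CONSEQUENCE_SEVERITY`): stop disruption and AUG creation rank highest,
mirroring how such variants are tiered during curation.

```{r}
classify_consequence(fx$utr, "c.-69dupG")
classify_consequence(fx$utr, c("c.-69dupG", "c.-59C>A"))
```

Design choices worth knowing:

* A start whose ATG is destroyed is `uStart_lost`; a new ATG absent from the
  adjusted reference is `uAUG_created_*`, sub-classified by the extent of
  the frame it opens (contained uORF, overlapping oORF, or N-terminal
  extension when in frame with the CDS with no intervening stop).
* A lost stop is `uStop_lost_extension` when a new in-frame stop is reached
  within the UTR (the new stop-to-mAUG gap is reported, and a flag notes
  when that stop lands inside another uORF) and `uStop_lost_oORF` when
  reading continues past the main AUG. The rare case where a frameshift
  drops a uORF into the mORF frame with no stop is reported as
  `uStop_lost_oORF` with an `in_frame_readthrough` detail, since the
  biological consequence is read-through of the main start.
* A substitution that *gains* a premature stop inside a uORF has no code of
  its own in this taxonomy; it is reported as `uAA_substitution` with a
  `premature_stop` detail flag.
* Kozak changes are reported only when the strength *class* changes, not on
  any base change inside the context window.
* Degenerate bases are rejected at parse time so calls are deterministic.
* A supplied splice-prediction score at or above 0.05 (configurable) adds a
  possible-splice-effect flag; splice prediction itself is out of scope.

## Prioritisation

Rarity comes first: a variant is reviewable when its population allele
frequency is absent (unobserved) or below 0.001. A second, stricter screen
uses the maximum credible population allele frequency for a heterozygous
disease,

\[
\mathrm{AF}_{\max} \;=\; \frac{\text{prevalence} \times \text{genetic het.} \times \text{allelic het.}}{2 \times \text{penetrance}},
\]

where the factor 2 converts a heterozygote genotype frequency to an allele
frequency. With prevalence 1/1000, genetic heterogeneity 0.9, allelic
heterogeneity 0.1 and penetrance 0.75:

```{r}
max_credible_af(0.001, 0.1, 0.9, 0.75)
```

Penetrance stays a free parameter (default 0.75): even a disease considered
fully penetrant by adulthood is incompletely penetrant in an age-mixed
population database. Both thresholds are reported per variant because they
serve different screens. Tiering: AUG-creating and stop-disrupting codes are
`potentially_disease_causing`; N-terminal extensions, uORF missense, Kozak
class changes, uORF start losses, and any other rare 5'UTR variant
(catch-all) are `uncertain_significance`; common variants are
`not_prioritised`. No further ACMG-style evidence combining is attempted.

## Reporter-assay statistics

The emulated experiment expresses the UTR upstream of secreted Gaussia
luciferase (GLuc) with secreted alkaline phosphatase (SeAP) on the same
construct as a transfection-efficiency control; 12 transfections per
construct across 2 independent experiments, 2 technical duplicate wells
each. `normalize_assay()` averages duplicates, forms the GLuc/SeAP ratio
per transfection, and divides by the wildtype mean ratio *of the same
experiment*, so purely multiplicative batch effects cancel exactly and the
wildtype experiment-mean is 1 by construction. Averaging duplicates first
keeps n at 12 transfections and avoids pseudo-replicating wells.

`assay_anova()` fits a one-way ANOVA on the linear relative-activity scale
(differences are reported on that scale, so no log transform) and computes
Tukey HSD comparisons from the studentized-range distribution with the
pooled within-group variance. Differences are oriented wildtype-minus-
construct, so a knockdown is positive; `percent_change()` converts a
difference to a signed percent. Adjusted p-values below 1e-4 format as
`"<0.0001"`.

```{r}
tab <- simulate_assay(assay_sim_config("variant"), seed = 1)
fit <- assay_anova(normalize_assay(tab))
tidy(fit) |> filter(group1 == "wildtype")
```

## The synthetic fixture

`generate_fixture()` builds a 209-nt UTR (plus a 30-nt CDS prefix) that
reproduces the structural facts of the PKD1 5'UTR architecture it emulates:
uORF1 at cap offsets 122-145 encoding MPSAGPA in frame with the mORF and
stopping 63 nt upstream of the main AUG; uORF2 at 189-206 encoding MRALP
out of frame, stopping 2 nt upstream; both uAUGs in a moderate Kozak
context with G at -3 and C at +4; and the full behavioural panel —
`c.-69dupG` frameshifts uORF1 into a stop-less oORF, the in-phase rescues
`c.-59C>A` and `c.-8C>A` restore stops ending 58 and 7 nt upstream of the
main AUG, and `c.-52C>T` / `c.-209G>A` leave the architecture untouched.
The genomic anchoring reuses the real minus-strand coordinates
(chr16:2,135,690-2,135,898) so printed genomic/transcript coordinate pairs
are testable verbatim, while the sequence itself is synthetic.

Construction places the uORFs from randomly chosen synonymous codons, pins
the handful of bases the behavioural constraints force (reference alleles,
Kozak -3 positions, the two bases that let the rescue substitutions complete
stop codons), fills the rest randomly, and accepts a candidate only when an
independent validator — built purely from the scanner and classifier, never
trusting the generator — passes every constraint. The search is seeded and
bounded (default 10,000 attempts, typically succeeding within a few
hundred); on failure it errors rather than relaxing constraints. A
constraint-solver dependency would be overkill: the constraints are local
and sparse.

What the fixture does **not** emulate: the real PKD1 sequence, its extreme
GC content and six pseudogenes; RNA secondary structure; the true Kozak
context of the main AUG (not printed anywhere authoritative — the fixture
defaults to moderate, an explicit assumption); splicing; transcript
stability. Passing tests therefore demonstrate that the *analysis logic* is
correct on a sequence with the documented architecture, not that any
particular real-genome pipeline is correct.

The assay simulator draws a lognormal transfection-efficiency factor per
transfection (sdlog 0.25; cancelled by normalisation, its exact value is
uncritical) and independent lognormal measurement noise per well. The
default measurement sdlog of 0.075 was calibrated by inverting the reported
Tukey p-values of the emulated experiment (a borderline non-significant
comparison with mean difference 0.064 at p = 0.13, and a borderline
significant one at 0.09 with p = 0.04, both at n = 12 with 6 resp. 4
groups imply a pooled within-group standard deviation near 0.075). The
planted true means are the reported wildtype-minus-construct differences:
0.8678 (patient duplication), -0.097 (rescue 1), 0.4465 (rescue 2), 0.008
(benign control), 0.06369 (cap substitution), and -0.09 / -0.34 / -1.31 for
the uORF1 / uORF2 / double start-loss knockouts.

## Numerical and testing choices

* All randomness flows through explicit seeds (`withr::with_seed`); the same
  seed reproduces every table byte for byte.
* The uORF knock-out substitution defaults to T>C at the second AUG base
  (ATG -> ACG) and is configurable; any non-AUG-restoring substitution
  satisfies the design.
* Property checks in the test suite run the scanner against a brute-force
  enumeration oracle on 1,000 random UTRs (lengths 50-400), the consequence
  classifier against an independent architecture-diff oracle on 1,000 random
  single-base edits, the Tukey procedure against frozen published
  studentized-range quantiles, and the assay pipeline against 200 seeded
  simulation replicates — sizes chosen to exercise the combinatorics
  thoroughly while keeping the default test run fast.

## Limitations

* Two of the emulated assay comparisons are intrinsically borderline: a
  true difference of 0.064 at n = 12 sits essentially on the Tukey critical
  difference at the calibrated noise level, and a true difference of 0.09
  sits just above it. A single wet-lab realisation of such a comparison can
  land on either side of 0.05; simulation replicates reproduce the *large*
  effects' significance essentially always, but a specific pattern of
  borderline calls is not a stable property of the data-generating process,
  and the package makes no attempt to force it.
* Consequence codes describe structural changes to the ORF architecture;
  they are not quantitative predictions of translational output. The rescue
  construct whose new stop lands inside uORF2 is a case in point: the
  overlap is reported as a detail flag (plus the incidental uORF2 missense
  code), but no functional prediction is attached, because the mechanism is
  genuinely open.
* Allele frequencies, splice scores and uORF-catalogue evidence are inputs,
  not computations; live database queries are out of scope.
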