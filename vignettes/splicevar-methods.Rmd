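---
title: "Models and methods behind splicevar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splicevar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicevar)
library(dplyr)
```

# The scoring model

splicevar scores splice-site strength with an inhomogeneous Markov chain
of order 2 over a fixed window: 9 nt for donors (relative positions
-2..-1 exonic, +1..+7 intronic, with the canonical GT at +1,+2) and 27 nt
for acceptors (-24..-1 intronic, covering the polypyrimidine tract and
the canonical AG at -2,-1, plus +1..+3 exonic).  Relative coordinates
skip zero, so the donor interval \[-2, +7\] contains exactly 9 positions.
The splicing score of a window $w$ is the log-odds

$$S(w) = \sum_{i} \log \frac{P_\text{site}(w_i \mid w_{i-2} w_{i-1},\, i)}
{P_\text{bg}(w_i \mid w_{i-2} w_{i-1})},$$

where the site model is position-specific and the background chain is a
single position-independent order-2 model estimated from user-supplied
background sequence.  Window positions with fewer than two preceding
bases condition on the shorter available context (the standard
inhomogeneous-chain convention).  Scores are reported in natural-log
units; the base is configurable (`base = 2` for bits) and all thresholds
shipped with the package are calibrated in the natural-log scale, so the
choice is self-consistent.

The model is sometimes described in the gene-finding literature as an
"HMM", but no hidden states are involved; it is a Markov chain, and that
is how it is implemented here.

**Functionality.**  Beyond the score, the model records which (position,
context, base) triples occurred in the site training windows.  A window
touching a triple never observed among real sites is deemed
*non-functional*: such sequence was never seen as a working splice site,
and no score magnitude is read into it.  The default pseudocount is 0
precisely to keep this absent-from-training semantics exact; smoothing
(`pseudocount > 0`) is available for probability-estimation experiments.
With pseudocount 0, zero-probability terms are clamped at a configurable
floor (`log(1e-12)`) so the reported score stays finite.

**The PWM companion.**  A standard per-position log-odds position weight
matrix over the same windows serves as the independent second scoring
scheme.  Its score is strictly local — a substitution changes it only
through the affected position — whereas the Markov score can change
through up to order + 1 positions.  This locality difference is asserted
in the tests.

# Variant classification

For a variant overlapping a site window, the variant window is rebuilt
from the genome (SNPs substituted in place; indels applied to the
sequence and the fixed-length window re-extracted anchored at the intron
boundary; a deletion that removes the anchoring boundary base is
reported as disrupting with a distinct `boundary_lost` flag).  With
$\Delta = S(\text{variant}) - S(\text{reference})$ the decision table is:

| reference | variant | call |
|---|---|---|
| functional | non-functional | disrupting |
| non-functional | functional | activating |
| both functional | $\Delta > \tau$ | enhancing |
| both functional | $\Delta < -\tau$ | weakening |
| both functional | otherwise | neutral |
| neither functional | — | neutral_nonfunctional |

with $\tau = 1.5$ for donors and $1.0$ for acceptors.  The comparisons
are strict, so $\Delta$ exactly at $\tau$ is neutral.  When both windows are non-functional there is no meaningful score
comparison to interpret; rather than forcing that case into one of the
five classes, splicevar reports it as its own subcategory.  By default each variant is applied
alone to the reference window (matching per-SNP class proportions); a
haplotype mode applies all variants of a site jointly.

**Calibration.**  `calibrate_threshold()` sweeps $\tau$ over a grid
(default 0–2.5 in steps of 0.1), cross-tabulates the three-way Markov
classification against the fixed PWM classification (neutral band
$\pm 6$, the location of the minima separating the trimodal PWM
score-difference distribution), and measures agreement with the
chi-square statistic; enrichment of concordant calls is reported as
standardized residuals.  Ties in the argmax resolve to the smallest tau.
On the synthetic fixture the argmax typically sits at the top of the
grid rather than in its interior: synthetic PWM differences exceed the
$\pm 6$ band almost only at canonical-dinucleotide hits, so agreement
keeps improving as the Markov neutral band widens.  An interior optimum
is a property of the richer score distributions of real data, not of the
procedure.

# Derived summaries

**PSI.**  Percent-spliced-in of an alternatively included exon combines
the two flanking inclusion junction counts against the skipping
junction: $\text{PSI} = (i_1 + i_2) / (i_1 + i_2 + e)$, undefined below
a total junction coverage of 10.  The combined (summed) convention is
used so that balanced evidence — 15 reads per inclusion flank against 30
skipping reads — yields PSI 0.5.

**DAF by class.**  Derived-allele-frequency distributions are binned per
effect class and compared against the neutral class with two-sample
Kolmogorov–Smirnov tests (`stats::ks.test`).  Classes with fewer than
two observations are skipped with a warning.

# Rescue of unannotated elements

**Cleavage sites.**  Unmapped reads ending in `AAAA` or starting with
`TTTT` are tail-trimmed (longest terminal run with at most one
interrupting base, minimum run 5; the innermost trimmed base is always a
matching base), then filtered for informativeness (length strictly
greater than 25 nt and combined A+T content strictly below 80%).
T-head reads are minus-strand evidence: the read is the reverse
complement of a tailed mRNA end, so after trimming it anchors on the
plus strand and the cleavage site is recorded on the minus strand at the
alignment start.  Anchored reads vote for the last templated base;
identical (chrom, strand, position) collapse with summed support, sites
with support ≥ 2 form the conservative subset, and no positional merging
is applied by default (exact-position keying; an optional merge radius
exists for noisy data).  Cross-dataset confirmation accepts a partner
site within ±50 nt (inclusive).

**Poly-A signals.**  Thirteen CPSF-binding hexamers are scanned in rank
order (AATAAA most frequent … AATAGA least) over ±50 nt of the cleavage
site on the transcribed strand; the first present hexamer wins, the
occurrence closest to the site is recorded, and upstream occurrences win
distance ties.  Biologically the signal sits upstream of the cleavage site, but
scanning around the site is more forgiving of anchoring error; both
modes are implemented (`upstream_only`), with ± as the default.  A variant inside a motif is
*altered* when the variant hexamer is still in the list, *degraded*
when it is not.

**Novel introns.**  Split-read junctions are filtered (properly paired,
mapping quality ≥ 150 — a mapper-dependent scale, kept configurable —
edit distance ≤ 6, insert size ≤ 1e6), junctions equal to annotated
introns are removed, and the rest are grouped with read / individual /
population support.  Junction sides absent from the annotated site set
are novel; novel sides must lie within 30 nt of an annotated exon
boundary (for doubly novel junctions, either side suffices).  Events are
typed internal / extension (upstream-of-TSS or downstream-of-cleavage)
by their position relative to annotated transcript spans; a junction
farther than 1 kb from every transcript is intergenic and excluded from
event tables.  Individual-support thresholds count individuals with at
least one read.  Only GT/AG junctions are scored for variant effects;
non-canonical junctions are retained but flagged.

**RNA editing.**  RNA-side variant calls are reduced to ADAR-consistent
candidates: not present among genomic genotype variants, reading A>G on
the gene strand (plus-strand A>G or minus-strand T>C), median coverage
across samples ≥ 10, ≥ 10 samples showing the non-reference base, and
call quality ≥ 100 (all three lower bounds inclusive, so the boundary
values pass).  Editing efficiency is the fraction of non-reference
bases; *exhaustive* editing means strictly above 0.9.  The association
between editing completeness at disrupted sites and intron retention is
a two-group Mann–Whitney test on normalized intron coverage; the
normalization is deliberately pluggable (the fixture uses reads per
intronic base, and length/expression scalings are reasonable
alternatives).

# The synthetic fixture

All tests run against data generated in code.  `sim_fixture()` builds,
deterministically from a seed, a single ~60 kb contig with 60 four-exon
genes (alternating strands; half carry a second, exon-skipping
transcript so that alternative sites exist), exon lengths 90–140 nt,
intron lengths 90–160 nt.  Splice-site windows are drawn from fully
specified "true" models (`site_truth_probs()`): canonical dinucleotides
are deterministic, and the remaining positions mix a major, a secondary
and two minor bases so that substitutions with large, small and
negligible log-odds effects all exist.

Planted ground truth covers every stage:

* **Variants** per effect class, with substitutions selected under the
  true model at a log-odds margin of 0.7 beyond the class threshold.
  Activating variants are planted by breaking the genome's canonical
  dinucleotide at a site and letting the variant restore it — the
  reference genome carrying a derived, disrupted allele.  Per-class DAFs
  follow Beta distributions (low for disrupting/weakening, uniform for
  neutral, high for enhancing/activating), mirroring the direction of
  purifying selection.
* **Training catalogues** of 4,000 windows per site kind, drawn
  independently from the same true models.  The size is chosen so the
  order-2 functional sequence space is essentially fully covered, as the
  method presumes of its genome-wide training catalogue; the
  parameter-recovery property is tested separately at n = 1000.
* **Split reads** supporting annotated introns plus planted novel
  junctions of each design (novel donor, two novel sides,
  exon-skipping combinations of annotated sites, extensions beyond the
  TSS) and deliberately low-quality evidence the filters must drop.
* **Poly-A reads** at planted cleavage positions with 12-base tails,
  T-head reads for minus-strand sites, and junk reads for the filters.
  Each cleavage neighbourhood is re-written G/C-only before the signal
  hexamer is planted: no listed hexamer can occur spontaneously without
  A/T, so the planted motif is the unambiguous truth and templated read
  segments always pass the complexity filter.
* **Editing calls** at acceptor A positions with chosen efficiencies
  (exhaustive > 0.9 vs partial), evidence-threshold failures, and a
  genomic-contaminant call; intron coverage is drawn higher for the
  exhaustive group.
* **Junction count matrices** (`sim_psi_fixture()`): 100 individuals ×
  40 exons, net effect-allele dosage in {-2..2}, inclusion following a
  logistic response (logit shift 0.9 per dosage unit, individual noise
  SD 0.3) observed through binomial junction counts of coverage 60.

What passing these tests shows — and does not.  The fixture plants clean
signal at desk scale: uniform read quality, no mapping ambiguity, no
sequencing error, single-contig geometry, and effect sizes chosen to be
detectable.  Recovery rates near 100% therefore validate the logic and
the coordinate/strand bookkeeping, not performance on real population
data, where window diversity, repeat-driven mismapping and shallow
per-individual coverage dominate the error budget.

# Numerical choices

* Log floor `log(1e-12)` for zero-probability terms; scores stay finite
  and comparisons remain ordered.
* Strict inequalities at every threshold boundary: score deltas beyond
  $\tau$, editing efficiency > 0.9, trimmed length > 25 nt, A+T ≥ 80%
  rejected, confirmation distance ≤ 50 nt, support ≥ 2.
* Calibration grid 0–2.5 by 0.1; argmax ties resolve to the smallest
  tau; contingency rows/columns that are empty at a grid point are
  dropped from that chi-square evaluation.
* N or other ambiguity codes: error in strict mode; in lenient mode the
  window is returned unscorable (`scorable = FALSE`), which is distinct
  from non-functional.
* Introns shorter than the acceptor window cannot be scored without the
  windows overlapping the opposite site; such windows raise an error
  rather than silently truncating.
* All randomness flows through explicit seeds (`withr`); identical
  fixture specs produce byte-identical files.

# Problem sizes

The default fixture (60 genes, 360 sites, 190 planted variants, 4,000
training windows per site kind, 20 cleavage sites, 30 novel junctions,
20 editing calls, a 100 × 40 PSI grid) runs the whole suite in about a
minute and a half on one CPU; these sizes are the package's standard
study conditions and are what the reported recovery rates refer to.

# Known limitations

* The background model is a single position-independent chain;
  gene-finding tools differ in how they model background composition,
  and no attempt is made to reproduce any particular one.
* PWM scores re-implement standard log-odds scanning rather than calling
  an external motif scanner, so absolute PWM values are not comparable
  across tools (score *differences*, which drive classification, are).
* Junction evidence is consumed from a documented TSV (or pre-anchored
  alignments); alignment itself is out of scope.
* Genome-scale class proportions and element counts require full human
  annotation, genotype and population RNA-seq datasets; splicevar
  validates the machinery at desk scale and leaves those analyses to
  its users.
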