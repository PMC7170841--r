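---
title: "Methods: design and analysis of pooled base-editing fitness screens"
author: "baseEditScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design and analysis of pooled base-editing fitness screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baseEditScreen)
```

## The experimental design this package models

A nickase-Cas9/cytidine-deaminase base editor (Target-AID type) edits
cytosines in a narrow window roughly 14-20 nt 5' of the NGG PAM, producing
mainly C→G and C→T changes; C→A products are rare enough to neglect. When a
guide library is designed so that each guide has few editable cytosines in
that window, the identity of the induced mutation is largely predictable
from the protospacer sequence alone, and the guide itself can serve as a
barcode for the fitness of the cells carrying its mutation. A pooled screen
then reads out mutational fitness effects as changes in relative guide
abundance between the mutagenesis step and the end of a bulk competition.

`baseEditScreen` implements the full computational side of such a screen:
library design, outcome prediction, read-count processing with
synthesis-error handling, the statistical machinery that calls guides with
significant negative fitness effects (GNEs) against an empirical null, the
downstream enrichment analyses, and a generative simulator with known
ground truth that lets every stage be validated without external data.

## Window conventions and guide design

Positions are PAM-relative: position $-k$ lies $k$ bases 5' of the first
PAM base, so the 20-nt protospacer spans $-20..-1$. The extended editing
window is $-20..-14$ and the high-activity window is $-19..-17$. A guide
enters the library only if all of the following hold:

* at least one cytosine in the high-activity window;
* not all three of $-19/-18/-17$ are cytosines, and $-18/-17$ are not both
  cytosines (such sites produce too many co-edited outcomes to interpret);
* no BsaI site (GGTCTC or reverse complement) in the protospacer, which
  would break Golden Gate library cloning;
* the protospacer+PAM matches the genome exactly once, and (by default)
  the protospacer never also matches a site followed by an NAG PAM;
* for coding targets, the top-ranked editable cytosine falls between 0.5%
  and 75% of the spliced CDS. The edit site, not the guide body, anchors
  this fraction, because the edit determines where a truncation or
  substitution lands; whether the bound should be taken in nucleotide or
  codon coordinates is not determined by the screen design we follow, and
  we use nucleotide coordinates.

Each guide receives a co-editing risk category from the 7-nt window
sequence at $-20..-14$. A configurable pattern table is consulted first; it
ships with the single unambiguous anchor (`NCDDDNN`, a lone C at $-19$, is
`very_low`). All other windows fall through to an activity-weight rule: the
highest-weight C is the intended (primary) edit, and the category grows
with the weight of the remaining (secondary) Cs - `very_low` with none,
`high` with a secondary C in the high-activity window or a CC dinucleotide
(processive co-editing), `moderate` with a mid-weight secondary C,
`low` otherwise. We deliberately did not guess a full verbatim
pattern-to-category table because the published category patterns cannot be
assigned to columns unambiguously; the fallback reproduces their stated
semantics and the table can be overridden via `designConfig()`.

## The outcome model

The editor's positional activity enters only through ranks, never through
absolute rates. `activityProfile()` therefore carries editable weights
(default ordering $-18 > -17 > -19 > -16 > -15 = -20 > -14$, ties breaking
toward the PAM); any profile with the same ordering yields identical
predictions. The model set of a guide holds the C→G and C→T outcomes at
the top-ranked editable position, plus both outcomes at the second-ranked
position when one exists - at most four genotypes, never C→A. Edits on
guides targeting the template (non-coding) strand are complement-mapped to
the sense strand before codon consequences are computed, so a template
C→G appears as G→C and a template C→T as G→A.

Stop-codon-generating guides (SGGs) are guides whose model set includes a
nonsense change. Enumerating the standard code under single C→G/C→T edits
shows stops are reachable from exactly six codons: TCA and TAC via C→G,
CAA, CAG and CGA via C→T on the coding strand, and TGG via a
template-strand C→T (the protospacer then shows the CC dinucleotide
pairing the two guanines).

Guide physical features include the RNA:DNA duplex melting temperature of
the guide hybridized to its genomic target, computed with the published
nearest-neighbor parameter set for RNA/DNA hybrids (shipped as data,
overridable), 25 nM strand concentrations and an entropic monovalent-salt
correction at 50 mM by default. Only relative comparisons (bins,
correlations, group shifts) are used downstream, so the concentration
conventions matter little; they are exposed as arguments regardless.

## Count processing and the synthesis-error null

Reads trimmed to the 20-nt variable region are matched exactly, then at
Hamming distance 1 (a unique 1-mismatch hit becomes a mismatch record;
ambiguous or more distant reads stay unassigned). We use exact plus
unique-Hamming-1 matching rather than an external aligner: library guides
are mutually distant, the behavior is fully testable, and read conservation
(perfect + mismatch + unassigned = input) holds by construction.

Oligonucleotide synthesis errors create guide variants that cannot edit
(their sequence no longer matches the genome) but still amplify and
sequence. A mismatch variant is called a synthesis error (SE) when its
read total, aggregated over all samples, exceeds 0.075 of the parent's
perfect-match total - strictly greater, so 75/1000 is retained as a
recurring sequencing error while 80/1000 is flagged. SE reads are removed
from the parent; SE variants with more than 1000 total reads are kept as
abundant SE guides, the negative-control population for the null model.
Whether the ratio should be taken per library or on aggregate counts is
ambiguous in the design we follow; we aggregate, with the threshold
exposed as an argument.

Guides absent (zero reads) from strictly more than half of the samples are
dropped, and fitness analysis is restricted to guides with at least 54
reads (inclusive) at the mutagenesis time point in every replicate - the
default that trades analyzable guides against inter-replicate noise.

For each guide and replicate the abundance change is

$$\Delta\log_2 = \log_2\frac{N_{\mathrm{guide},t_1}}{N_{t_1}} -
  \log_2\frac{N_{\mathrm{guide},t_0}}{N_{t_0}}$$

with a single numerical concession: a zero count at $t_1$ (only) is
replaced by 0.5 before the ratio; nonzero counts are never perturbed.
$\Delta\log_2$ values are standardized within replicate over all eligible
guides (SE guides included, since the standardization describes the
distribution, not the discoveries), and z-scores are averaged across
replicates. A Gaussian is fit by maximum likelihood (population SD) to the
averaged z-scores of the abundant SE guides; the false positive rate at
threshold $t$ is $\Phi((t-\mu_{SE})/\sigma_{SE})$, the expected
false-positive count multiplies by the number of tested (non-SE) guides,
and the FDR divides by the number of observed hits at or below $t$. The
GNE threshold is the largest observed averaged z-score whose estimated FDR
is at or below the 10% default target; the threshold search runs over
observed z values only, matching the hit-counting definition, rather than
through continuous root finding. SE guides are controls and never receive
GNE calls.

## Enrichment analyses

Fisher's exact test is computed from the hypergeometric point
probabilities (two-sided p = sum of probabilities not exceeding the
observed table's), with the sample odds ratio $ad/bc$. Substitution
patterns use the paired C→G/C→T outcome notation at the top rank (for
example `G>R/S` for a glycine codon mutating to arginine or serine); each
guide contributes its rank-1 pattern once, a multiplicity convention the
screen design leaves open. Multiple testing across patterns uses Holm's
step-down procedure at $\alpha = 0.05$; the published description of this
step conflates familywise control with FDR, so the package implements what
is named (Holm) and labels it as such, with a Benjamini-Hochberg option.
Annotation enrichment classifies guides as on-site, near-site (within a
two-residue window by default, inclusive) or off-annotation, and tests the
on and near classes against the off class. Feature analyses provide Welch
t-tests, per-bin GNE enrichment relative to the overall GNE ratio, and
Spearman correlations.

## The simulator and what passing tests mean

`generateReference()` builds random start/stop-bounded CDSs at a requested
GC content on alternating strands. `simTruth()` fixes per-guide editing
rates (uniform on 0.5-0.9 by default, the regime an efficient editor
reaches), selection coefficients (a configurable fraction of lethal
outcomes, $s = 1$), an outcome spectrum (0.45/0.45/0.05 C→G/C→T/C→A plus
a 5% multi-edit share), a ~3% synthesis-error fraction, ~300 reads per
guide per sample, and 10 generations of competition - the generation count
between sampling points is not pinned down by the experimental design we
follow and is exposed as a parameter. `simulateScreen()` grows each
guide's subpopulation deterministically as a mixture of unedited cells
(fitness 1) and edited cells (fitness $1-s$) and draws reads multinomially
per sample for two time points and two replicates; the only noise is
sequencing sampling, the simplest model consistent with a bulk-competition
readout (an optional drift bottleneck was considered and rejected as
out of scope for the default).

Two modeling consequences deserve emphasis. First, because the only null
variation is multinomial, the variance of $\Delta\log_2$ scales inversely
with read count. The simulator therefore keeps post-cloning abundance
heterogeneity modest (lognormal, cv ~25%), so that the abundant-SE null is
representative of the tested population and the FDR machinery is
calibrated; real oligo pools can be considerably more skewed, in which
case the homoskedastic SE null underestimates the noise of low-count
guides and realized FDR exceeds the nominal target (in our simulations,
a nominal 10% typically realizes near 15%). Passing tests therefore
demonstrate correctness of the machinery under near-homogeneous noise,
not robustness to strong abundance skew - an abundance-matched or
variance-weighted null would be the extension for that regime. Second,
real screens add biological noise (growth-rate variation, transformation
bottlenecks, PCR jackpotting) that the generator intentionally omits;
sensitivity numbers from simulations are accordingly optimistic upper
bounds.

Problem sizes used by the test suite and the acceptance script - screens
of 10,000 guides with 5% planted lethal outcomes over five seeds, a
three-gene (~1.5 kb) genome for exhaustive design checks, and full
fixed-margin Fisher enumeration up to table totals of 40 - were chosen so
that exhaustive oracles stay exact while each suite runs in about a
minute.

## Reproducibility

Every stochastic function takes an explicit seed or derives one from the
pipeline configuration; `runPipeline()` threads a single seed through all
stages, stamps artifacts with a configuration hash, and produces
byte-identical TSV outputs on identical configurations. Degenerate inputs
fail loudly rather than silently: empty FASTA records, duplicate
identifiers, out-of-bounds gene intervals, CDS lengths off codon frame,
zero-variance z-score distributions, and null fits on fewer than ten SE
guides are all hard errors.
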