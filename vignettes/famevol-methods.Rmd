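---
title: "Methods behind famevol: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind famevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famevol)
```

famevol packages the desk-scale stages of a plant gene-family survey, built
around the heat shock transcription factor (Hsf) family of desert poplar:
protein physicochemical profiling, domain-geometry classification, Ka/Ks
estimation with sliding windows and divergence dating, microsynteny
duplication typing, promoter cis-element scanning with an enrichment
statistic, intron phases, and qRT-PCR induction calling. Every stage can be
exercised on synthetic inputs with known ground truth, because the original
genome and the web services used in such surveys are not desk-available.
This vignette explains the models, the tunable parameters, and the places
where the design was genuinely open.

## Physicochemical profile

`protein_profile()` computes, per protein, the columns of a family survey
table. The definitions are the canonical ExPASy/ProtParam ones, shipped as
inspectable package constants so they can be swapped:

* **Molecular weight**: sum of average-isotopic residue masses plus one
  water (18.0153 Da), reported in kDa.
* **GRAVY**: mean Kyte-Doolittle hydropathy per residue; bounded by the
  table range \[-4.5, 4.5\] and invariant under sequence shuffling.
* **Aliphatic index**: $AI = X_{Ala} + 2.9\,X_{Val} + 3.9\,(X_{Ile} +
  X_{Leu})$ with $X$ in mole percent (Ikai coefficients).
* **Instability index**: $II = (10/L)\sum_i \mathrm{DIWV}(aa_i, aa_{i+1})$
  over the $L-1$ overlapping dipeptides, using the Guruprasad DIWV weights.
  The stability call is *stable* strictly below 40; a value of exactly 40 is
  called *unstable*, matching the usual "above 40 may be unstable" wording.
* **Isoelectric point**: the root of the Henderson-Hasselbalch net-charge
  equation, found by bisection on pH \[0, 14\] to 1e-3, with a
  Bjellqvist-style pKa set (D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0,
  R 12.0, N-terminus 7.5, C-terminus 3.55). Published pI values cannot be
  matched bit-exactly without the original sequences and the exact pKa set
  behind them, so the package treats pI as a well-defined model quantity:
  tests assert the defining property (|net charge at pI| < 1e-2) and
  agreement with an independent grid-scan solver under the same pKa set.

Percentages (charged-residue fractions) are kept exact internally and
rounded to one decimal only in report output.

## Hsf motif scanning and class assignment

Upstream domain annotation (DBD and HR-A/B coordinates) is an input, not a
re-implementation: profile-HMM and coiled-coil detection are out of scope.
What the package adds:

* `find_rd_motif()`: exact tetrapeptide search (LFGV, with the IFGV variant
  enabled by default), non-overlapping, leftmost first — the class-B
  repressor-domain marker.
* `find_nls()`: windows of length 8 containing at least 4 K/R residues,
  merged when overlapping. This is a deliberately simple composition rule;
  published NLS entries are exemplar strings, not an algorithm, so the rule
  is configuration validated on planted synthetic signals and on the
  exemplars (e.g. NKKRRLKQ).
* `find_aha_motifs()`: windows of length 10 centred on an aromatic residue
  (W/F) with at least 2 acidic residues (D/E), merged. The same caveat
  applies; the defaults recover exemplars such as DVFWEQFLTE.
* `classify_hsf()`: class A when the HR-A/B span is at least 40 residues
  (reflecting the class-A insertion in the oligomerization region), else
  class B when the DBD-to-HR-A/B linker exceeds 44 residues, else class C.
  The thresholds are configuration and the applied rule is echoed per
  protein. Published domain tables do not separate classes under any single
  span threshold (the original assignment used a dedicated web tool), so
  family-wide class recovery from printed coordinates is deliberately not a
  test target; recovery is validated on synthetic proteins with planted
  class geometry.

## Ka/Ks: Nei-Gojobori counting with Jukes-Cantor correction

The estimator behind `kaks_pair()` is the transparent approximate method:

* Per codon, the synonymous site count $s$ is the sum over the three
  positions of the fraction of one-step changes that preserve the amino
  acid; changes to stop codons count as nonsynonymous and $n = 3 - s$.
  $S$ and $N$ are summed per sequence and averaged over the two sequences.
* Per differing codon pair, $S_d$ and $N_d$ average equally over all
  minimal substitution paths; paths through stop codons are excluded (with
  a fall-back to all paths in the degenerate case where every path is
  blocked).
* $K_s = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p_S)$ with $p_S = S_d / S$, and
  analogously for $K_a$. Proportions at or above 3/4 are reported as a
  saturation error. $K_s = 0$ yields an undefined ratio, serialised as NA,
  never 0 or infinity.

The original survey named only the alignment tooling, not the estimator, so
the printed Ka/Ks columns are not bit-exact anchors; the fully specified
divergence clock is. `divergence_time()` applies $T = K_s / (2\lambda)$
with the *Populus* synonymous rate $\lambda = 9.1\times10^{-9}$
substitutions/site/year. Of the ten published pair dates, five round-trip
exactly from the printed (3-decimal) Ks values; the other five differ in
the second decimal because they were evidently computed from unrounded Ks,
so tests assert the round-tripping subset.

`sliding_window_kaks()` re-runs the estimator in codon-aligned windows
(90 bp and 60 bp are the conventional sizes; the step defaults to 9 bp and
is recorded in the result's attributes since the original step size is
unpublished). Windows with saturation or zero-site denominators carry a
status flag instead of a value. With step equal to window, per-window
difference counts add up exactly to the whole-alignment counts.

## Microsynteny and duplication typing

A duplicated block is a chain of at least 3 homolog anchor pairs in which
consecutive anchors lie within 15 genes of one another on both scaffolds
(`find_duplicated_blocks()`, window and minimum both configurable). The
"within 15 genes" rule is read as a bound on the rank gap between
consecutive anchors, not on total block extent — the stricter and, in our
view, more natural reading of a window rule whose original tool parameters
are unpublished. Gene rank is computed from start coordinates,
strand-agnostic, ties broken by id; coordinates are GFF3-style 1-based
inclusive throughout.

`classify_duplication()` partitions pairs: *tandem* when both genes share a
scaffold with at most 5 intervening genes (the published tandem pair is
adjacent, so any threshold of 0 or more reproduces it; 5 is plumbing),
else *WGD* when the pair anchors, or is flanked within the window by, an
inter-scaffold block joining its scaffolds, else *dispersed*.

`intron_phases()` reports, per intron, the cumulative upstream CDS length
mod 3 (0/1/2), flagging UTR-only introns separately; a total CDS length not
divisible by 3 is a validation error.

## Promoter scanning and the enrichment level

Promoters are the 2 kb immediately 5' of the translation start
(`extract_promoter()`): plus-strand genes take genomic
$[tss-2000,\,tss-1]$ as-is, minus-strand genes the reverse complement of
$(tss,\,tss+2000]$; truncation at scaffold edges is flagged. Position 1 of
a promoter is most distal and position 2000 abuts the start codon.

`scan_elements()` matches IUPAC consensus patterns at every position on
both strands, reporting all overlapping occurrences deterministically; an N
in the sequence matches only an unconstrained pattern position. One design
point deserves emphasis: the heat stress element consensus AGAAnnTTCT is
its own reverse complement, so a forward match is always also a
reverse-strand match. Counting both would double every HSE site, which is
biologically meaningless (the element is strand-symmetric) and would make
planted-count bookkeeping impossible. Patterns whose consensus equals its
own reverse complement are therefore scanned on one strand — one site, one
occurrence — while non-palindromic patterns are reported per strand.

The packaged catalog carries the survey's element names with published
consensus IUPAC strings. It is a documented stand-in for the original
database's matrices — absolute per-genome counts are therefore not
reproducible here and are exercised only through planted synthetic
promoters — and it is fully user-replaceable via `read_element_catalog()`.

`enrichment_level()` is the survey's statistic: total occurrences divided
by the number of genes carrying at least one occurrence (e.g. 73 sites in
27 promoters gives 2.7; 37 in 12 gives 3.1). Elements with no hits are
absent from the summary rather than reported as 0/0.

## qRT-PCR induction calling

Relative expression follows $2^{-\Delta\Delta C_t}$ with amplification
efficiency fixed at 2.0 and the 0-h sample (or tissue median) as
calibrator; the normalization method is a stated package choice since the
original protocol names only the reference gene. Replicate log2 expression
($-(C_t^{target} - C_t^{ref})$) is compared against the 0-h control with a
Student's t test — pooled variance by default, Welch via `var_equal =
FALSE` — and a gene is called induced when $P < 0.05$ and $\log_2 FC \ge
1$: the fold-change boundary is inclusive, the significance boundary is
not. When both groups have zero variance the test degenerates to an exact
comparison ($p = 1$ if the means are equal, else 0). No multiple-testing
correction is applied by default, matching the original analysis;
Benjamini-Hochberg is available through `adjust_p = "BH"`. Induced genes
are counted once per condition regardless of how many timepoints fire.
Tissue profiles are $\log_2$ ratios to the per-gene median across tissues
(mean of the two central values for an even tissue count), making them
invariant to multiplicative rescaling.

## Synthetic-data generators

Each generator is seed-deterministic (same arguments + seed give identical
output) and returns a machine-readable truth record.

* `simulate_codon_pair()` draws a random sense-codon ancestor and applies
  Poisson numbers of synonymous (expectation $K_s^{target} \cdot S$) and
  nonsynonymous (expectation $\omega K_s^{target} \cdot N$) one-step
  substitutions in random interleaved order, rejecting stop codons. The
  process is substitution-count-targeted rather than continuous-time — a
  deliberate simplification that makes realized event counts exact. It does
  not model transition/transversion bias, codon-usage bias, or indels, so
  passing recovery tests demonstrates correctness of the counting engine
  under its own model, not robustness to those real-data features.
* `simulate_genome_layout()` plants inter-scaffold anchor chains whose rank
  gaps respect the detection window, adjacent tandem pairs, and 2-anchor
  decoy chains on otherwise unused scaffold pairs (below the anchor
  minimum, so they must never be reported).
* `simulate_promoters()` rejection-samples background sequence (default GC
  0.40) until it contains zero chance catalog matches, then inserts
  concrete pattern instances at non-overlapping positions and re-checks
  that a scan recovers exactly the planted set. This makes planted counts
  exact, at the cost of requiring long/rare patterns: with 5-nt catalog
  entries a match-free 2-kb background is essentially unattainable and the
  generator stops with an informative error.
* `simulate_qpcr()` generates $C_t = baseline - \log_2(fold) +
  \mathcal{N}(0, \sigma_{C_t})$ per replicate with a constant reference
  Ct; defaults (3 replicates, $\sigma_{C_t} = 0.3$, timepoints 0/1/6/12 h,
  the five standard treatments) mirror the study design.
* `simulate_proteins()` plants class-specific domain geometry (A: 48-aa
  HR-A/B span; B: 29-aa span with 51-aa linker; C: 27-aa span with 28-aa
  linker — comfortably inside the class regions) plus NLS/AHA/RD motifs on
  a background alphabet that excludes the scanned residue classes, so
  planted motifs are recovered exactly.

## Problem sizes and numerical choices

The test suite validates the Ka/Ks engine against a full path-enumeration
oracle on 500 random 50-codon pairs (tolerance 1e-9); recovers
$\omega \in \{0.1, 0.3, 1.0\}$ to within $\pm 0.05$ of the mean over 200
replicates of 900 codons; checks block detection against an exhaustive
chain scan on random layouts up to 200 genes per scaffold; requires exact
planted-promoter recovery; and checks the induction criterion's null rate
(at most 5% plus a three-sigma Monte-Carlo margin) and power (at least 95%
at $\log_2 FC = 2$, $\sigma_{C_t} = 0.3$, $n = 4$) over a 10,000-gene
simulation. These sizes keep the full suite under two minutes while leaving
the Monte-Carlo margins comfortably wider than the observed deviations.

Numerical conventions worth knowing: undefined ratios are NA, never 0 or
Inf; saturation is an error for whole-pair estimates and a flagged status
in sliding windows; all coordinates are 1-based inclusive; block and hit
orderings are fully deterministic so identical inputs give byte-identical
outputs.

## Known limitations

* Class assignment thresholds are heuristics over input domain
  coordinates; they are not a substitute for profile-HMM annotation.
* The cis-element catalog is consensus-based; position-weight-matrix
  scoring and the original database's matrices are out of scope, so
  absolute element counts on real genomes will differ.
* The codon simulator's count-targeted process is not a substitute for
  continuous-time codon models; likelihood-based estimators (codeml-style)
  are out of scope.
* NES scanning has no default rule (published entries are heterogeneous
  strings); only the configurable pattern list is provided.
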