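---
title: "Methods: divergence, transfer screening, and the simulator behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence, transfer screening, and the simulator behind them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baeocomp)
```

# The inference chain

`baeocomp` implements the comparative-genomics chain used when a newly
sequenced cyanobacterial genome from a non-axenic culture is compared
against a panel of related strains: contigs are binned to remove
contaminants, coding sequences are classified into orthologs, paralogs
and strain-specific genes by reciprocal best hits, codon-level
divergence is estimated for ortholog sets, and two signatures of
horizontal gene transfer (HGT) are tested — reduced synonymous
divergence of pair-restricted genes, and their enrichment on predicted
plasmid sequences. All stages are exercised end-to-end on a simulator
with known ground truth; this vignette records the models, the
defaults, and the choices made where the design was genuinely open.

# Contig binning

A contig's evidence is its (at most 20) best translated-search hits
against a mixed reference, each tagged with a coarse taxon group, plus
its fold coverage. The rules in `classify_contig()`:

* all hits cyanobacterial → retain;
* a **strict majority** of cyanobacterial hits *and* coverage above
  `coverage_min` (default 70, strict `>`) *and* best cyanobacterial
  identity at least `identity_margin` (default 10 percentage points)
  above the best non-cyanobacterial identity → retain as curated;
* otherwise discard (an empty hit list is a discard with reason
  "no hits").

"Majority" and the 10-point margin are formalizations: published
curations of this kind are partly manual, and no quantitative rule is
standard. Both knobs are exposed. `congruence_filter()` reconciles the
decisions with an independent binner's labels: hit-rule retentions
contradicted by the second binner are kept but flagged (the hit
evidence is primary), while second-binner retentions that the hit
rules discarded *with both top identities high (≥ 70) and within the
margin of each other* are excluded as ambiguous — mixed-signal contigs
must not seed spurious transfer calls downstream. The congruence
fraction is agreement counted over contigs retained by either method.

# Reciprocal-best-hit homology

The scorer emulates a translated (tblastx-like) search: both
nucleotide sequences are translated in all three forward frames
(ambiguous codons become `X`, which is scored 0 against everything;
internal stops are kept as `*`), and every frame pair is scored by
local alignment under BLOSUM62 with affine gaps (open 11, extend 1 —
`Biostrings::pairwiseAlignment` does the alignment). The hit score is
the maximum over the nine frame pairs. CDS inputs are assumed
stranded; `reverse_frames = TRUE` adds the reverse-complement frames
for unstranded input.

A raw-score threshold (default 50) stands in for a search E-value:
E-value calibration needs database-scale statistics that a pairwise
scorer does not have, so the package exposes the raw score and also
accepts precomputed tabular hits (`rbh_from_hits()`) for users who ran
a real search engine. Ties are broken by lexicographically smallest
gene id so runs are reproducible. Labels follow the classic
reciprocal rule: no forward hit → *no similarity*; forward best whose
reverse best is the original query → *ortholog*; otherwise →
*paralog*.

# Nei–Gojobori divergence

`ng86()` implements the 1986 counting method. Synonymous sites per
codon are the sum over the three positions of (synonymous changes) /
(changes not creating a stop), so S + N = 3 × comparable codons holds
exactly; the final S averages the two sequences. Codons containing a
gap, an ambiguous base, or a stop in either sequence are skipped.
Differences at codons that differ in 2–3 positions are averaged over
all minimal substitution pathways with equal weights, excluding
pathways that pass through a stop codon (if every pathway is blocked,
all are used rather than dropping the codon). Proportions are
corrected with Jukes–Cantor, `K = -(3/4) ln(1 - (4/3) p)`; when the
log argument is non-positive the estimate is flagged undefined rather
than clamped. All 64 × 64 codon-pair difference counts are
precomputed once per session; the test suite checks the fast path
against a brute-force enumeration oracle to 1e-9.

The estimator is deliberately the counting method, not a
maximum-likelihood codon model: it is the method behind the classic
DnaSP-style Ks/Ka values this chain consumes, and its counting
identities (site conservation, additivity under concatenation) are
what the downstream windowing relies on.

# Windowed Ks and the transfer screen

`windowed_ks()` scans a concatenated alignment codon by codon for one
taxon pair, accumulating pairwise synonymous sites, and closes a
window at the first codon that brings the cumulative count to the
target (default 500 synonymous sites; windows may overshoot by at most
one codon's worth). The trailing partial window is discarded. A
tolerance of 1e-9 on the closing comparison keeps fractional site
counts that sum to the target exactly in real arithmetic from missing
the boundary in floating point.

The screen compares the window-Ks distribution of the "All" ortholog
set against a "Pair" set (genes shared with one strain only) with
`mann_whitney()`: if pair-restricted genes arrived by transfer, their
divergence reflects the (recent) transfer time, not the species split,
and the Pair distribution sits below the All distribution. The test
uses exact enumeration (two-sided p by doubling the smaller tail) when
the combined sample is ≤ 20 without ties, and the normal approximation
with tie-corrected variance otherwise; a one-sided alternative
(`"less"`) is the natural choice for the screen.

# Tajima relative rate test

`tajima_rrt()` counts, over columns comparable in all three sequences,
the sites where lineage A carries the unique state (m1) and where B
does (m2), either on third codon positions or on translated amino
acids. Under equal rates, `(m1 - m2)^2 / (m1 + m2)` is chi-square with
1 df; m1 + m2 = 0 gives chi-square 0 and p 1 by convention. Third
positions give more power but saturate sooner; the amino-acid mode is
the conservative companion. The suite verifies the test's size
empirically: over 500 equal-rate simulated triples the rejection rate
at α = 0.05 stays within [0.02, 0.09].

# Presence/absence classes and plasmid enrichment

A focal gene is *present* in a subject strain when its label there is
ortholog **or** paralog — no-similarity is the complement of that
union, matching how per-strain summary tables partition. The absence
class is the number of absent strains; class 0 (present everywhere) is
kept for bookkeeping. Per-class annotation profiles exclude
unannotated genes with a warning. For the top informative class
(absent everywhere but one strain) the complementary presence view
identifies the single retaining partner — the natural reading when
those genes are transfer candidates.

Plasmid calls use a probability threshold in [0.5, 1] (default 0.7):
records that clear it for neither class are *unclassified* and folded
into *chromosome* for all downstream accounting, the conservative
assumption for draft genomes. `fisher_exact()` computes the two-sided
p by the minimum-likelihood rule (summing hypergeometric probabilities
of tables no more likely than the observed one); the published bounds
this package reproduces hold under either sidedness convention. The
odds ratio reported is the sample cross-product `ad/bc` with an
explicit infinity flag, not the conditional MLE — the flag, not the
magnitude, is what matters when a zero cell occurs.

# The simulator

`simulate_strain_set()` evolves gene families along a rooted guide
tree under a minimal codon model: candidate mutations are uniform per
nucleotide over the three alternatives; events that would create a
stop codon are rejected and redrawn; nonsynonymous events are accepted
with probability `omega` (default 0.1). Branch lengths are expected
substitution *attempts* per site, so realized synonymous divergence
per synonymous site tracks path length closely (synonymous changes are
always accepted); the suite checks recovery of a target Ks = 0.3 to
within 10% relative bias at 10^4 codons, and cross-checks realized
divergence against the simulator's own substitution event log.

Structural events layered on top:

* **Duplication** (`dup_fraction`, default 0.25): a recent duplicate
  of the focal strain's tip sequence, evolved a further
  `dup_divergence` (default 0.05) attempts/site. Making the duplicate
  strictly more diverged keeps the truth unambiguous: the reverse best
  hit of any subject ortholog is the original copy, so the duplicate
  is the paralog-confounded gene. The default duplicate share (25% of
  families, i.e. 20% of focal genes) sits in the 16–28% range typical
  of these genomes.
* **Loss** (`loss_fraction`, default 0.08 per non-focal strain):
  families dropped independently per strain.
* **Transfer** (`hgt_fraction`, default 0.08): a fraction of families
  is restricted to a donor/recipient pair (default Pleurocapsa →
  Hyella, the most-shared marine pair), and the recipient's copy is
  re-sourced from the donor tip with `hgt_divergence_scale` (default
  0.3) times the tree-path divergence — the signature the window
  screen must detect. Transferred genes can be plasmid-enriched
  (`hgt_plasmid_enrichment`) so the Fisher stage sees signal.
* **Compartments** (`plasmid_fraction`, default 0.12): i.i.d. per
  gene, with PlasFlow-style probabilities drawn high for plasmid
  genes, low for most chromosome genes, and mid-range for a 20%
  low-confidence slice that the 0.7 threshold leaves unclassified.
* **Frameshifts** (`frameshift_fraction`, default 0.05): one inserted
  nucleotide at a uniform position, applied after evolution so truth
  relationships are unaffected. Families containing a frameshifted
  member stack into non-multiple-of-three alignments and are exactly
  what `filter_multiple_of_three()` removes.

The default seven-strain guide tree is calibrated so realized pairwise
Ks spans roughly 0.28 (the two *Stanieria*) through 0.9 (Hyella vs
Chroococcidiopsis) to 1.8 (Myxosarcina vs Pleurocapsa), the divergence
range these strain panels actually show. A single integer seed drives
every draw; identical configurations reproduce byte-identical FASTA
and truth tables.

What the simulator does **not** emulate: GC content and codon-usage
bias, indels other than the single frameshift rule, rate variation
across sites, gene-length variation within a family, intergenic
sequence, and real search-score statistics. Green tests therefore show
that the chain's logic and estimators are correct under a clean codon
model — not that the thresholds (score 50, identity margin 10) are
optimal for any particular real dataset.

# Problem sizes and determinism

The test suite and the acceptance script run simulations at reduced
sizes chosen to keep the whole suite in the low minutes on one CPU:
two-strain calibration runs at 40 × 100 codons (10^4 codons for the
bias check), the transfer screen at 40 replicates of a three-strain,
40-family scenario with 100-synonymous-site windows, and the rate-test
size check at 500 replicates of 300-codon triples. The full
seven-strain default (120 families × 150 codons) runs in seconds and
is used where per-gene resolution is not needed. All replicate seeds
derive arithmetically from one base seed.

# Known limitations

* The RBH scorer scans forward frames only by default and assumes
  stranded CDS input.
* NG86 with equal pathway weights underweights transition/transversion
  asymmetry; Ks above ~1.5 is close to saturation and its window
  variance grows accordingly (visible in the widest pairs of the
  default tree).
* The congruence rule's ambiguity definition (both identities ≥ 70,
  margin < 10) is a formalization of a manual curation step; users
  reproducing a specific study should treat it as configurable.
* `plasmid_fraction()` weights by sequence length only; it does not
  model per-replicon copy number.
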