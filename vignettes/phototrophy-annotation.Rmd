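---
title: "Detecting photosynthesis gene clusters and proton-pumping rhodopsins in MAG collections"
author: "cyanophot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting photosynthesis gene clusters and proton-pumping rhodopsins in MAG collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`cyanophot` annotates two modes of bacterial phototrophy in collections of
metagenome-assembled genomes (MAGs) binned from non-axenic cyanobacterial
cultures: anoxygenic bacteriochlorophyll-based photosynthesis, encoded by a
photosynthesis gene cluster (PGC), and retinal-based light-driven proton
pumping by proteo-/xanthorhodopsins. It then aggregates the evidence into
one phototrophy call per MAG, flags dual phototrophs, and computes
community metrics calibrated to the cyanobacterial host.

The package assumes assembled nucleotide contigs per MAG (no reads), a
precomputed coverage table (mapped bases per MAG and metagenome), a
CheckM-style QC table, and an externally assigned taxonomy. Read QC,
assembly, binning, taxonomy and tree inference are deliberately out of
scope; their outputs are inputs here.

# The translated homology screen

Reference proteins are searched against MAG contigs the way a TBLASTN
screen would be used, but made exact and deterministic:

1. Every contig is decomposed into maximal stop-to-stop open reading
   frames in all six frames (bacterial translation table 11). Contig ends
   are treated as open, so a terminal ORF needs no closing stop. The
   default length floor is 60 aa — shorter ORFs carry too little alignment
   signal at remote-homology identities to clear the score threshold
   anyway.
2. Each panel protein is aligned against each ORF by optimal
   Smith–Waterman local alignment with affine gaps (BLOSUM62, gap open 11,
   extension 1 — the classic protein-search working point). A gap of
   length $L$ costs $11 + L$.
3. A hit requires identity $\ge 0.30$ over aligned columns, query
   (reference) coverage $\ge 0.50$, and score $\ge 60$. These three knobs
   are the conventional remote-homology working point; no E-value is
   computed because a MAG does not define a meaningful database size. All
   are configurable and echoed to the log.
4. Per ORF, only the best reference of each gene family is kept;
   overlapping same-family hits on a contig are dereplicated keeping the
   best score.

ORF-based exact DP was chosen over seeded heuristics because MAG-scale
inputs make full DP tractable, and determinism matters more than speed
here. A score-only DP pass over all ORFs selects candidates; the full
traceback runs only on those. Co-optimal alignments are resolved by the
alignment engine's deterministic backtrace, so outputs are identical
across runs and platforms; scores, identity and coverage — the quantities
all downstream logic consumes — are invariant to that choice.

# Rhodopsin classification

Rhodopsins are functionally ambiguous (proton pumps, ion pumps, sensors),
so a hit alone is not evidence of phototrophy. Three orthogonal signals
are combined:

**Subtree assignment.** Each hit is assigned to subtree I
(proteorhodopsin, Bacteroidota-type), II (proteorhodopsin including the
*Exiguobacterium sibiricum*-type branch) or III (xanthorhodopsin) by the
best global-alignment score against labeled references — a deterministic
nearest-reference stand-in for tree placement. The margin between the best
and the best differently-labeled reference is reported; a margin below 5%
of the best score flags the label low-confidence, which guards chimeric or
deeply ambiguous sequences.

**Diagnostic residues.** Positions are anchor-relative: the hit is
globally aligned to the assigned subtree's anchor and residues are read at
anchor positions 85, 89, 96 (proton-transfer triad D/T/E), 156 (antenna
glycine) and 292 (retinal-binding lysine). Because numbering schemes for
rhodopsin positions are a chronic source of confusion, the anchor sequence
*is* the definition of the numbering here — replace the anchor and the
positions follow it. An anchor alignment below 15% identity raises an
error rather than silently reading residues off a meaningless mapping;
positions aligned to gaps yield `NA` residues and `FALSE` flags.

**Operon context.** Functional proton pumping requires retinal, whose
biosynthesis needs the *brp*/*blh* β-carotene 15,15′-dioxygenase.
Neighbors are all predicted features within 5000 bp on the same contig
(strand-agnostic; operon plots show tight clustering but "adjacent" is
never formally defined, so a generous window was fixed). `brp_blh`
adjacency and genome-wide presence are tracked separately, as is the set
of carotenoid genes (*crtE/B/I/Y*) in the neighborhood.

The functional call applies, in order: the NDQ motif at 85/89/96 excludes
the protein as a Na⁺ pump; a missing K-292 marks it divergent/unknown;
otherwise a subtree-assigned rhodopsin with *brp*/*blh* anywhere in the
genome is a bona fide light-driven proton pump, else a candidate. E96
divergence alone does **not** disqualify — the *E. sibiricum*-type branch
pumps protons without E-96. A carotenoid antenna is predicted when G-156
is present and the subtree is I or III.

# PGC inventory and synteny

PGC genes found by the screen are numbered against an ordered reference
cluster. A MAG "has a PGC" when *pufL* and *pufM* (the diagnostic
reaction-center markers) are both present and completeness — distinct
reference genes found over reference size — reaches 0.5. "Complete PGC" is
nowhere given a numeric definition in the literature this package serves,
so the rule is an explicit, configurable operationalization, with
contiguity (one contig, span ≤ 80 kb, generous against the ~45 kb
canonical cluster) reported separately so split bins are not penalized.

Cluster rearrangement is quantified by signed adjacency breakpoints: both
clusters are restricted to shared genes, laid out as signed permutations
of reference indices (sign = strand), and an adjacency $(u, v)$ of one
order counts as conserved if $(u, v)$ or $(-v, -u)$ occurs in the other.
This is the minimal well-defined statistic for the inversion-style
differences seen between PGCs; heavier rearrangement distances
(block-interchange, DCJ) would over-specify what the comparison needs to
show. The statistic is symmetric, zero iff the shared genes are collinear
up to whole-cluster reflection, and is validated against exhaustive
adjacency enumeration over all signed permutations of up to six genes.

# Phototrophy calls and community metrics

Host MAGs are an explicit manifest flag, not a taxonomy inference. A
non-host MAG is `dual` when it has a PGC and a bona fide pump (or a
xanthorhodopsin operon, recorded separately because observed dual
phototrophs are xanthorhodopsin-bearing); `rhodopsin_only` counts bona
fide or candidate pumps. The Venn summary reports both the
pump-or-candidate tally and the bona-fide-only tally, since
"rhodopsin-positive" can be reasonably read either way.

QC thresholds are strict inequalities (completeness > 80, contamination
< 10), matching how the cut-offs are conventionally printed; the arguments
allow relaxation to ≥/≤. Relative abundance is
$100 \times \mathrm{cov}_\mathrm{MAG} / \mathrm{cov}_\mathrm{host}$ per
metagenome with coverage = mapped bases / genome size, so the host is 100%
by construction and the metric is invariant to sequencing depth.
Commonality counts each taxon once per metagenome. Presence–absence
matrices at the six ranks are exported for external ordination; embedding
(e.g. t-SNE) is intentionally not computed because its parameters are not
reproducible choices of this package.

# The synthetic generator: what it emulates and what it does not

`generateCollection()` emulates a per-culture MAG set: one host genome at
GC 0.69 (a realistic cyanobacterial value) plus associates at GC 0.5, with
log-normal coverages, a configurable host multiplier, one associate
planted at 17× host coverage and one associate species shared by 12 of 14
cultures — echoing the magnitudes real cyanosphere collections show.
Planted features reverse-translate panel proteins with uniform synonymous
codons (detection operates at protein level, so a codon-usage model would
add nothing testable), flank every gene with in-frame stops, and record
expected subtree/call/mode in a truth manifest derived from the spec of
the plant itself.

Desk-scale defaults keep an end-to-end run of the 14-metagenome design
under ~2 minutes: 3–6 associates per culture, 6 kb background contigs,
15 kb host contigs. The per-culture MAG count range is configurable up to
the 3–40 (median 21) seen in real culture collections; the problem size,
not the biology, is what is scaled down. What passing planted-truth tests
show is that every pipeline rule fires correctly on unambiguous inputs and
degrades monotonically with divergence; what they cannot show is
robustness to real-world mess — fragmented genes at contig edges, paralog
families, composition-biased backgrounds, chimeric bins, or reference
panels that only remotely match the community. The shipped panels are
synthetic stand-ins constructed to carry the canonical diagnostic
residues, labelled as such; analyses of real data should substitute real
reference proteins via the panel paths.

# Numerical and degenerate-input choices

- Internal coordinates are 0-based half-open everywhere; conversion
  happens only at the GFF3 boundary (1-based inclusive), which round-trips
  bit-exactly.
- GC content excludes ambiguous bases from the denominator; a sequence of
  only `N`s yields `NaN` rather than a fabricated value.
- A local alignment whose optimal score is not positive is reported empty
  (score 0) — chance-level local similarity carries no signal.
- Empty MAGs screen to an empty hit table with a warning; an empty hit
  table inventories to completeness 0; a synteny comparison with no shared
  genes reports `NA` breakpoints rather than 0.
- All generator outputs are pure functions of the seed; reruns are
  byte-identical.

# Known limitations

- Nearest-reference subtree assignment inherits the panel's coverage of
  rhodopsin diversity; a sequence outside all three subtrees is still
  assigned to the nearest one (with, at best, a low-confidence flag).
  Heliorhodopsins and sensory rhodopsins are not subtyped.
- Threshold-passing hits are final; no manual curation stage is modeled.
- The screen has no profile/HMM sensitivity: homologs below ~30% identity
  to every panel member are invisible by design.
- Coverage arrives as a table; mapping ambiguity between closely related
  MAGs is upstream of this package.
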