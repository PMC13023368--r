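---
title: "Methods: telomere motif inference and telomerase RNA discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: telomere motif inference and telomerase RNA discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloquest)
library(dplyr)
```

## The problem

Telomerase maintains chromosome ends by copying a short template carried by
its RNA subunit (TR) into tandem telomeric DNA repeats. The protein subunit
(TERT) is reasonably conserved; the RNA is not — it evolves quickly in
sequence, structure, and transcriptional context, which makes it hard to
find by sequence similarity alone. In insects the telomeric unit itself
varies across lineages (TTAGG, TCAGG, TTTGGG, and many variants), and the
TR template tracks those changes: whatever repeat a genome's telomeres are
made of, the TR of that species must carry its reverse complement.

teloquest implements that logic as a testable pipeline:

1. **Telomere motif inference** — what repeat do this species' telomeres
   use? (from assembly termini, or from raw reads)
2. **Template-guided TR search** — where in the genome does the reverse
   complement of that repeat occur in tandem, with flanking context?
3. **Evidence integration** — candidates must (i) carry a template
   concordant with the species motif, (ii) be detectably transcribed, and
   (iii) have homologs in related species. Structural anchors (a template
   boundary hairpin, a pseudoknot-like crossing pattern) and type-3 snRNA
   promoter architecture are annotated as corroboration.
4. **Telomerase-loss calling** — species in which motif, TR, and TERT are
   all undetectable are flagged as putative telomerase losses, and Dollo
   parsimony places the loss events on a species tree.

Because genuine multi-species beetle data cannot ship with a package, a
synthetic-genome generator with machine-readable planted truth is a
first-class module: every recovery claim the test suite makes is a claim
about planted ground truth.

## Motif canonicalization

A telomeric repeat is a circular object observed on either strand: one
telomere read from the opposite strand in a different rotation phase is
the same motif. `canonical_motif()` therefore maps a unit to the
lexicographically minimal string over all rotations of the unit and of its
reverse complement; `display` is the field convention (G-rich strand,
rotation with the longest leading T run; G-count ties broken toward the
lexicographically smaller strand, which keeps single-symbol units stable).
Units are not reduced to a primitive period here; `find_tandem_arrays()`
handles periodicity minimality itself by discarding consensus units that
are whole-number tandems of a shorter unit.

## Tandem detection and motif inference

`find_tandem_arrays()` uses period autocorrelation: positions where
`seq[i] == seq[i + p]` mark `p`-periodic structure; maximal high-identity
runs are extended greedily across short mismatch gaps, summarized by a
per-phase majority consensus, and compared against that consensus for the
reported identity. The greedy merge also keeps each longest pure run as a
candidate, so a merge that drags in leading noise can never delete a clean
array. The default period range 3–10 nt covers the known insect telomere
units; satellite-sized repeats (tens of nt) need `max_period` raised
explicitly and are out of the default search space by design.

`infer_motif()` ranks motifs by votes: in `termini` mode each terminal
window (default 2,000 nt) casts one vote for the motif with the largest
array in that window, and motifs are ranked by `(ends supporting, total
array length)`. Votes rather than lengths make the ranking robust to one
unusually long interstitial array. Terminal enrichment is reported as
covered-base density of the motif in terminal windows divided by its
genome-wide density; chance occurrences of short units in random sequence
make "enrichment ≈ 1" the null, not "enrichment = 0". In `reads` mode,
arrays are counted inside individual reads (with an exact-tandem regex
prefilter for speed) and ranked by supporting reads. Inference defaults
(`min_copies = 4`, `min_identity = 0.85`) are deliberately stricter than
the raw detector's, because a species-level motif call should rest on
unambiguous arrays; at these settings chance arrays still occur in random
windows, which is why the pipeline additionally requires a motif to win
the vote at half the chromosome ends before scoring it present.

## Local alignment

Cross-species filtering needs a homology search engine. The package
carries two authored implementations: `smith_waterman()`, a full
dynamic-programming local aligner with affine gaps (a k-long gap costs
`gap_open + k * gap_extend`), and `seed_extend_search()`, a word-seeded
banded-extension heuristic. Defaults follow the BLASTn-style
parameterization used for this kind of search — word size 11, E-value
cutoff 1e-3, gap penalties 5/2 — with +2/−3 as the conventional
match/mismatch companion to those gap costs (configurable). The exact
aligner is the oracle for the heuristic in the test suite, and an
independent third implementation (`Biostrings::pairwiseAlignment`) checks
the oracle itself.

E-values use the Karlin–Altschul form `K·m·n·exp(−λ·score)`. λ is solved
from the ungapped identity `Σ pᵢpⱼ exp(λ·sᵢⱼ) = 1` under a uniform
background; K is estimated once per scoring scheme by a seeded Monte-Carlo
fit of the mean optimal score of random sequence pairs to the Gumbel mean,
then cached. Neither constant is asserted from literature; both are
reproducible computations. These statistics are used for filtering and
ranking, not for publication-grade significance claims.

Translated mode searches all six subject reading frames with BLOSUM62
scores (gap 11/1), seed length `floor(word_size/3)` residues, and words
containing stop codons discarded.

## TR discovery

`scan_genome_for_templates()` looks for runs of ≥ 2.5 tandem copies of the
reverse complement of the species motif, any rotation phase, either
strand, tolerating one substitution per run. The 2.5-copy floor reflects
the ~3-copy (15-nt) templates seen in real TRs while tolerating rotation
phase at run edges; one mismatch is allowed because template/motif
correspondence in real paralogs is near- but not always perfect. Runs
longer than `max_copies = 8` copies are skipped: a telomere or satellite
array read from the opposite strand is itself a long run of the template
unit, and without this cap every telomere would be reported as a TR
candidate. Candidates carry 200-nt flanks oriented 5'→3' on the
template-carrying strand, so cross-species alignment, promoter scanning,
and structure checks share one coordinate convention.

Criterion (ii), "detectably transcribed", is operationalized on per-base
coverage tracks: transcript boundaries are the outermost positions of the
longest run with coverage ≥ 10% of the locus' 90th percentile, and
`expressed` requires the median coverage inside that interval to be ≥ 5×
the median outside. The 5× ratio is a package decision — the underlying
experimental notion has no numeric definition — and is configurable.

Criterion (iii) is reciprocal-best-hit single-linkage clustering of
concatenated flanks across species, with at most one member per species
per group (best summed RBH score wins) and groups below `min_support = 2`
species flagged unsupported.

Tiers: HIGH = (i)+(ii)+(iii); MEDIUM = (i) plus exactly one of (ii)/(iii);
LOW = (i) only; candidates failing (i) are dropped. Structural and
promoter flags annotate but never move tiers: they corroborate rather than
gate, since at permissive stem lengths (5 bp, G·U allowed) chance helices
are common in 200-nt windows, and the bundled PSE model is synthetic.

## Structural anchors and promoters

`structure_checks()` finds helices as runs in the base-pairing matrix
(A–T, C–G, and G·U wobble, since these are RNA helices written in DNA
alphabet): a template-boundary hairpin requires arms ≥ 5 bp, loop ≤ 30 nt,
with the 3' arm within 30 nt of the template; a pseudoknot-like signal
requires two helices downstream whose pairing intervals interleave. This
is a deliberate simplification — no covariance model, no free-energy
minimization — and the vignette's caveat above applies: treat these flags
as corroboration.

`scan_promoter()` implements type-3 snRNA promoter architecture as a PSE
position-weight-matrix hit in a window upstream of the transcript start
(default start offsets −80..−40) plus an exact IUPAC match of a TATA-like
element (default `TATAWAW`, window −40..−20). Both defaults follow
canonical insect snRNA promoter spacing (PSE ≈ −55/−60, TATA ≈ −30). The
bundled 12-column PSE matrix is synthetic (85% consensus weight per
column) and user-replaceable via a plain-text PWM file; the score
threshold defaults to 80% of the matrix's maximum attainable score. The
transcript start defaults to the template 5' end — a simplification that
matches how the synthetic data are planted; a coverage-derived start can
be passed via `tss_offset`.

## TERT screening and loss mapping

`screen_tert()` six-frame-translates each contig and searches one or more
protein queries. Presence requires either hits in ≥ 2 distinct
(non-overlapping, merged) query regions — the analogue of recovering
several separated reverse-transcriptase motifs — or hits jointly covering
≥ half the query; a single short spurious HSP satisfies neither. If the
strict pass (E ≤ 1e-3) fails, a relaxed pass at E ≤ 0.1 runs before
absence is declared, and both passes are reported. The bundled query
peptide is synthetic (labelled as such); real screens should pass real,
phylogenetically diverse TERT queries.

`dollo_losses()` assumes a single gain at the root and losses only: the
minimal loss set is one event on the stem edge of every maximal clade
whose informative tips are all absent. Unknown tips are uninformative for
clade maximality. If every informative tip is absent, the convention is a
single loss on the root edge. This minimality is not just asserted: the
test suite checks it against exhaustive enumeration over all edge subsets
on every rooted binary 6-leaf topology × every presence pattern.
`classify_status()` labels a species "putative telomerase loss" only on
concurrent absence of motif, TR, and TERT — the deliberately cautious
wording reflects that extreme sequence divergence is an alternative
explanation the computation cannot exclude.

In the pipeline, a species with no inferable motif is re-scanned with
every motif found elsewhere in the bundle (a cross-species template
search) before TR is scored absent rather than unknown.

## The synthetic data generator

`generate_dataset()` builds what the analysis assumes real data look like:

* **Telomeres**: each chromosome end carries a tandem array of the species
  motif, G-rich strand 5'→3' toward the 3' end at the right terminus and
  reverse-complemented at the left. Array lengths are geometric with mean
  `telomere_copies` (default 100), minimum 10 copies — real telomere
  lengths are heterogeneous, and a fixed length would make enrichment
  statistics degenerate. Arrays are mutated at 2% per base by default.
* **TR loci**: template = exactly 3 tandem copies of the reverse
  complement of the motif (the rotation starting with T where one exists,
  matching the printed-template convention; the 5'-most copy is recorded
  as the annealing portion), flanked by one bundle-wide ancestral 500-nt
  flank pair independently diverged per species at `flank_divergence`
  (default 0.1, Jukes–Cantor-like substitutions, no indels). The planted
  transcript runs from the template 5' end to 185 nt past it (200 nt
  total for a 5-nt motif). PSE and TATA elements are planted exactly at
  −60/−30 upstream of that start.
* **Decoys**: interstitial motif arrays at ~1 per 50 kb (15–30 copies)
  exercise terminal-enrichment discrimination; 10 template-bearing decoy
  loci per species with random flanks exercise the orthology and
  expression filters.
* **TERT**: the bundled query peptide is codon-encoded in frame
  (deterministic codon choice) as two exon-like fragments on a random
  strand.
* **Loss clades**: a monophyletic tip set where telomeres, TR loci, and
  TERT fragments are jointly omitted.

Reads are sampled uniformly from both strands with constant quality and
substitution errors only; coverage tracks are `depth` plus truncated
Gaussian noise inside the planted transcript and truncated noise around
zero outside. The generator is deterministic in `(spec, seed)` down to
bytes.

What the generator does **not** emulate: indels, GC bias, repeat families
beyond the planted decoys, assembly gaps/fragmentation, transcriptome
complexity, or read-quality structure. Passing the recovery tests
therefore demonstrates internal consistency of the method under its own
assumptions, not performance on real assemblies.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 20 single-species bundles
(4 × 20-kb chromosomes) for motif recovery, 20 five-species bundles
(2 × 20-kb chromosomes per species, flank divergence 0.1, 10 decoys per
species, depth-10 coverage with SD 2) for end-to-end TR recovery, 200
random pairs (≤ 60 nt, planted ≥ 15-nt exact core) for oracle
equivalence, all 945 rooted binary 6-leaf topologies × 64 presence
patterns for Dollo verification, and 5 loss-clade bundles for loss
calling. These sizes were chosen so the whole validation runs comfortably
on a laptop while keeping every per-bundle quantity (telomere length
distributions, decoy counts, divergence) at the defaults described above.

Degenerate inputs are defined rather than accidental: empty sequences
give empty tables; an all-zero coverage track gives "no interval, not
expressed"; an empty assembly screens TERT absent with a warning; a tree
whose informative tips are all absent yields the root-edge loss. Ties are
deterministic throughout (lexicographic tie-breaks in canonicalization;
smallest `q_start`, then `s_start` among equal-scoring hits; smaller
period preferred among equal-length arrays).

## Known limitations

* Structural flags are sensitive but unspecific at default stem lengths;
  they are annotations, not filters.
* The E-value calibration is Monte-Carlo based and intended for
  filtering; tail accuracy at extreme scores is not guaranteed.
* The promoter model is a synthetic placeholder until a lineage-specific
  PSE matrix is supplied.
* Dollo loss mapping takes the tree as given and cannot distinguish true
  loss from extreme divergence or assembly incompleteness — hence
  "putative" in every loss label.
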