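---
title: "Methods and design notes for foxtail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for foxtail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxtail)
```

# Scope

`foxtail` implements the analytical layer that sits downstream of a plant
genome assembly project: the statistics and curation procedures that turn
an assembled, repeat-masked, annotated genome plus population resequencing
into the summary numbers a genome paper reports.  It deliberately does
*not* wrap the upstream tools (assemblers, polishers, RepeatMasker, MAKER,
aligners, SV callers); their output file formats are its inputs.  A
deterministic simulator generates all of those inputs with known ground
truth, so every procedure is testable without downloading any sequencing
archive accession.

# Coordinate conventions

All annotation arithmetic uses 0-based half-open intervals; the GFF3
reader/writer converts to and from the 1-based closed convention at the
boundary.  One deliberate exception: structural-variant records keep their
VCF 1-based `pos`/`end` fields, because the only derived quantity is the
length `end - pos` and converting would invite an off-by-one against the
caller dialect's own length convention.

# Genome size from a k-mer spectrum

`estimate_genome_size()` is a peak-based estimator: the error threshold is
the first local minimum of the count spectrum scanning up from
multiplicity 1 (`find_error_threshold()`), the homozygous peak is the
count-maximizing multiplicity at or above the threshold, and

$$\hat G = \frac{\sum_{m \ge t} m \, c_m}{m_\text{peak}}.$$

This is intentionally simpler than a full mixture fit (no heterozygous
peak, no repeat tail model): the returned object records that
simplification in its `model` field.  Peak detection runs on raw counts by
default — deterministic and easy to reason about — with an optional
moving-average `smooth` window for ragged empirical spectra.  The mode of
a Poisson(λ) multiplicity distribution can sit at λ−1 when λ is an
integer, so a relative error of about 1/λ is inherent to the peak
convention; at 25× coverage the estimator stays within the 5% recovery
band the tests assert.

# Assembly metrics

Contigs are maximal non-gap segments after splitting at N-runs of at least
`min_gap_len` bases (default 10, the census threshold for "large" gaps;
the 100-N convention for unspanned junctions is a property of the input,
not of the metric).  `nx()` is the descending-cumulative-sum definition.
The masked fraction counts lowercase bases over *all* bases, N included —
matching a "percent of assembly bases" reading — with `exclude_n = TRUE`
exposed for the alternative.  The per-assembly N50 in `summarize_assembly()`
is computed from gap-split segments and labelled as such, since whether a
published per-chromosome N50 came from pre-scaffolding contigs or
gap-split segments is generally not stated.

# Repeat context and strand bias

A repeat is *genic* when it overlaps a gene span (introns and UTRs
included) by at least one base; the text this mirrors says "intersect
genes" without qualification, and an exon-only mode is provided.  When a
repeat overlaps several genes, the leftmost by coordinate provides the
strand relation — a deterministic tie-break — and the `multi_gene` flag
reports how often it fired.  Composition shares are computed over element
counts (each element counts once), with a base-weighted mode available,
because the corresponding published shares are phrased as "% of all
repeats that intersect genes".

# Gap-flank permutation test

The observed statistic is the unweighted mean, over all flank windows, of
either repeat-covered fraction or GC fraction (Ns excluded from the GC
denominator).  Both flanks of every gap contribute as separate windows.
Gaps are then re-placed uniformly (chromosome chosen proportional to
length, offset uniform, mutual overlaps rejected) `n_perm` times, and

$$p = \frac{\#\{\text{permuted means} > \text{observed mean}\}}{n_\text{perm}}$$

with *strict* inequality — ties do not count against the observed value —
and no pseudo-count, so `p = 0` must be read as "less than 1/n_perm".  A
zero-variance permutation distribution is flagged.  Two unstated details
were resolved as follows:

* Windows that would overhang a chromosome end are **discarded, not
  truncated**, so observed and permuted statistics always average windows
  of identical width; truncation would confound the test with a
  window-length effect.
* Shuffled gaps may land on the original gap coordinates; no exclusion
  zone is imposed (an option exists).

The calibration suite checks empirical type-I error on a *null world* in
which repeat placement is strictly independent of gap placement
(`repeats_avoid_gaps = FALSE`).  This matters: in a real annotation,
repeats are never called across N-runs, which slightly depresses observed
flank coverage relative to shuffled placements and makes the test
conservative near gaps.  The default simulator keeps the realistic
convention (repeats avoid gaps, masking bookkeeping exact); the null
switch exists precisely so the statistical machinery can be validated
against an exactly exchangeable world.

# Structural-variant curation

The filter chain is: PRECISE (split-read-resolved) breakpoints, length
strictly below 5 Mb, FILTER `PASS`, median mapping quality strictly above
zero, and paired-end support of at least five reads.  "At least five
paired-reads" is read as the PE field alone (the paired-end evidence
class), with `pe_plus_sr = TRUE` switching to the combined count.
PRECISE and `sr > 0` are both checked and a disagreement warns.  Allele
frequencies are computed over called diploid genotypes under a biallelic
model, folded to the minor allele; the carrier-based alternative the
literature sometimes intends is left to the caller via the per-variant
table.  Medians use the midpoint convention for even-sized sets (hence
values like 6,630.5).  `deletion_te_length_overlap()` quantifies the
visual co-occurrence of deletion-length peaks with retrotransposon length
distributions as an overlap coefficient of shared-grid histograms
(500-bp bins over [0, 10 kb) by default).

# Gene-set filtration

AED filtration keeps a gene when its *best* isoform has AED ≤ 0.5
(strictly-greater models are removed, so 0.50 survives).  The primary
isoform is the minimum-AED transcript, ties broken by longer exonic
length, then lexicographic id.  Gene expression is the per-sample sum of
isoform TPMs.  The final filter removes primary models shorter than 50
bases (strict), and single-exon genes in focal-species-specific
single-copy orthogroups that are either unsupported (merged TPM < 1) or
mostly encompassed (> 90% of their span) by another candidate gene.
Decisions taken where the source procedure is silent:

* Genes absent from every orthogroup are treated as de-facto
  focal-specific singletons — they have no cross-species evidence either.
* Encompassment is evaluated against all genes surviving the AED and
  length rules, not against an order-dependent shrinking set; this makes
  the filter idempotent, which the tests assert.
* A gene with TPM exactly 1 is neither "supported" (support needs > 1)
  nor removed by the "< 1" clause; both thresholds are honored verbatim
  and the per-gene TPM is reported so the inconsistency is visible.
* "Shorter than 50 bp" is applied to the primary transcript's exonic
  length (`length_mode = "span"` switches to the gene span).

# Duplication enrichment

Duplication events are kept at clade support ≥ 0.90 (inclusive) and
grouped by species-tree node.  Enrichment of a functional term in the
duplicated set is the exact hypergeometric upper tail
$P(X \ge k)$ with Benjamini–Hochberg step-up correction across all terms
present in the study set; significance is `q < 0.05`.  The background is
supplied by the caller; the simulator-driven tests use all focal-species
genes, and restricting to annotated genes is a caller-side subset.  Terms
are tested independently (no ontology-graph propagation), on the
assumption that slim-style annotations are already propagated.

# The simulator as a stated world

Generator defaults are fixed once and are not tuned to test outcomes:

* Two 200-kb chromosomes — the scaled world used by the calibration and
  power criteria, chosen so 500 replicate analyses fit a desktop budget.
* Gaps: 20 runs of exactly 100 Ns (the unspanned-junction convention).
* Repeat families with log-normal length mixtures peaking near 3/13 kb
  (copia-like) and 3/8 kb (gypsy-like), plus LINE, MULE and helitron
  families; counts chosen to give a repeat fraction in the 30–45% range
  typical of a millet-clade genome.
* Genes: log-normal spans (median 2.4 kb), 1 + Poisson(3) exons, Beta(1,4)
  AEDs, an optional worse second isoform.
* SV panel: 235 samples; 150/186/85 clean DEL/DUP/INV records plus, per
  type, two records per curation rule violating exactly that rule;
  allele frequencies Beta(0.5, 5) — an explicit stand-in, since the real
  panel's frequency spectrum is not described; Hardy–Weinberg genotypes.
* Orthogroups: 400 groups over three species; 60 duplication events at
  the planted node, 20% drawn below the 0.90 support bar; a planted term
  at 5% baseline annotation frequency, enriched by a configurable factor
  among planted-node duplicates (`effect_size = 1` is the calibration
  null).

What the simulator does *not* emulate: read-level error profiles,
sequence homology between repeat copies, linkage between variants,
ontology structure among terms.  A green test therefore establishes that
the *procedures* are correct on data with the assumed statistical shape,
not that the shape matches any particular organism.

# Numerical and degenerate-input choices

Interval validation rejects zero-length spans; `pos == end` SV records
are legal but flagged as degenerate length 0.  The coverage index merges
features before prefix-summing, so overlapping annotations never double
count.  `p = 0` permutation results are reported with the `< 1/n_perm`
caveat.  Histogram multiplicities must be strictly increasing;
duplicates are parse errors rather than silently summed.  All writers
emit binary-mode files with `\n` separators so round-trips are
byte-stable across platforms.

# Known limitations

The genome-size estimator fits no heterozygous peak and will misread a
strongly heterozygous spectrum.  The permutation machinery assumes gaps
are rare relative to chromosome length; dense gap sets would make the
non-overlap rejection loop slow.  The enrichment module assumes a fixed,
caller-supplied background and pre-propagated annotations.  Published
headline numbers that depend on the real assembly, the full resequencing
panel, or external annotation pipelines are out of reach by construction;
the package reproduces their *arithmetic* on printed summary tables and
validates their *procedures* on simulated ground truth instead.
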