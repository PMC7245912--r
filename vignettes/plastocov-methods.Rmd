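---
title: "Methods: coverage depth and IR equality on quadripartite plastome maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage depth and IR equality on quadripartite plastome maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastocov)
```

## The model

A plastome assembly is treated as a single circular sequence of length
$L$ with a feature table, and — when both inverted repeats are annotated —
a quadripartite partition into four contiguous regions in genome order
LSC, IRb, SSC, IRa. The partition is derived purely from the annotations:
the IRs are taken verbatim from `repeat_region` features whose qualifier
values spell `IRa`/`IRb` (or the long forms `inverted repeat A/B`,
case-insensitively, whitespace-normalized), and the single-copy regions
are the gaps between them. No de novo repeat detection is attempted:
correcting IR boundaries is an assembly/annotation task, not a QC
visualization task, and silently "fixing" the annotation would hide
exactly the class of error this tool exists to expose.

Coverage depth at position $i$ is the number of retained aligned spans
covering $i$. It is computed by the start/end event sweep: a delta array
receives $+1$ at each span start and $-1$ just past each span end, and
its cumulative sum is $d(i)$. This is exactly equivalent to a per-position
pileup (the test suite asserts equality against a brute-force pileup on
100 randomized alignment sets) but linear in reads plus genome length.

Two quadripartite-specific adjustments matter:

* **Windows restart at region boundaries.** Each region is tiled from its
  own start with windows of exactly the window size, plus at most one
  shorter remainder window per region. A window therefore never spans a
  boundary, so no window's coverage is counted toward two regions, and
  the per-region window count is $\lceil n/w \rceil$ for a region of
  inclusive length $n$. The remainder window uses its true span as both
  its histogram bar width and its averaging denominator.
* **Boundary-spanning genes are split.** A gene crossing a region
  boundary is cut at every boundary it crosses; each part becomes an
  independent unit with its own region label and central-nucleotide
  anchor. This keeps labels, bars, and synteny ribbons in the correct
  region for genes such as *ycf1* (SSC/IRa boundary) or *rps19*
  (LSC/IRb). Parts of one source gene are drawn as independently labelled
  units, with adjacent same-origin labels within a configurable angular
  distance (default 1 % of the circle) collapsed to one — visually
  equivalent to re-merging the parts, but fully specified.

## IR equality

Healthy IRs are reverse complements of each other with mirrored gene
complements. The assessment is two-step:

1. **Direct.** Lengths are compared first; only when equal is sequence
   content compared, accepting either direct identity or
   reverse-complement identity (annotation conventions differ in recorded
   orientation). Comparing content across unequal lengths would
   necessarily also fail and produce a redundant second warning, so a
   length inequality yields exactly one `ir_length` warning;
   `sequences_equal` is still reported `FALSE`, preserving the invariant
   that sequence equality implies length equality.
2. **Indirect.** IR gene units are tabulated per side and paired by
   identical name. Duplicate names within one IR (e.g. two *trnI* copies)
   are paired by *mirrored rank*: the $k$-th occurrence along IRb
   ($5'\!\to\!3'$) pairs with the $k$-th occurrence along IRa counted
   $3'\!\to\!5'$, because gene order reverses between reverse-complementary
   repeats. The test suite verifies this against an exhaustive assignment
   oracle minimizing summed mirror-position asymmetry. Genes without a
   counterpart become unmatched entries with one `ir_gene_complement`
   warning each; paired genes of unequal inclusive length warn
   (`ir_gene_length`) but stay paired — only name absence unpairs.

When fewer than two IRs are annotated the genome is a single `WHOLE`
region, the comparison and the ribbon layer are skipped entirely, and an
informational notice (not a warning) is emitted: an IR-less plastome is a
natural state, not a QC failure.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `window_size` | 250 | bp | near one short-read length; fine enough to localize dropouts, coarse enough to smooth sampling noise |
| `threshold` | 0.5 | fraction of genome mean (or absolute depth) | half the genome-wide mean flags genuine under-coverage without flagging the natural SC/IR depth contrast |
| `threshold_is_relative` | `TRUE` | — | relative thresholds transfer across libraries of very different depth |
| `log_transform` | `FALSE` | — | display transform is $\log_{10}(x+1)$; the pseudo-count keeps zero-coverage windows at height 0, and flagging always uses untransformed depths |
| `ribbon_mode` | `proportional` | — | ribbon end widths proportional to gene length make long-gene synteny legible; `uniform` and `none` available |
| `text_scale` | 0.5 | fraction of maximum font size | legible on 50–250 kb genomes at the default canvas |
| `delete_temp` | `TRUE` | — | intermediate window tables are removed unless kept for debugging |

Numerical conventions: coordinates are 1-based inclusive throughout
(conversion to 0-based half-open happens only at the BAM boundary and on
BED/bedGraph export); the flagging inequality is strict (a window exactly
at the cutoff is displayed as normal); the central nucleotide of a span is
$\lfloor(start+end)/2\rfloor$; the genome-wide mean includes zero-coverage
positions. The region-size accessor `table_region_size()` reproduces the
$end-start$ convention used in published plastome region tables, which is
one less than the inclusive length; all internal arithmetic uses inclusive
lengths, whose four-region sum equals the genome length exactly.

Degenerate inputs: origin-wrapping features are rejected (the BAM is taken
as linear, so reads spanning the circular origin are not reconstructed);
overlapping IR annotations and conflicting duplicate IR annotations are
validation errors; IR annotations not flush with the sequence end leave a
trailing segment that is circularly contiguous with the LSC and is carried
as a second LSC-labelled partition row, with a warning; genomes outside
the 50–250 kb range only warn. IRa annotated before IRb is honored as
labelled, with a warning.

## Rendering

All layers share one angular mapping,
$\theta(p) = 2\pi\,(p-1)/L$ clockwise from 12 o'clock. The histogram's
radial scale is linear from zero to the maximum displayed depth, shared
across regions so the per-region mean arcs are comparable; mean arcs are
broken over maximal runs of zero-coverage windows. SVG output is generated
by the package's own serializer and is byte-deterministic for identical
inputs — this is the structural test surface (bars, ribbons, ticks, and
arcs are counted by parsing the file). PDF (the user-facing default) and
PNG are drawn from the same geometry primitives with base graphics.

## What the fixture generator emulates — and what it does not

`make_genome()`/`make_reads()` build a toy quadripartite plastome
(defaults: LSC 8,000, IRb 2,500, SSC 1,800, IRa 2,500 bp) with IRa the
exact reverse complement of IRb, a mirrored IR gene roster including a
duplicated *trnI* pair, a boundary-crossing *rps19* with its mirrored
fragment flush at the IRa end, and a matching coordinate-sorted, indexed
BAM. Single-copy regions target 20× and IRs 16× — the depth contrast
regularly observed in real quadripartite assemblies — with one dropout
interval (two windows of the LSC) receiving zero reads. Read starts are
stratified (evenly spaced with small seeded jitter) rather than i.i.d.
uniform so each region attains its target depth tightly, and reads may run
past region boundaries, as in a real mapping; anchor reads flush with the
genome ends and dropout edges guarantee that only the dropout is
uncovered. The generator records the exact pileup by naive per-position
counting while writing alignments, giving an oracle independent of the
sweep implementation.

The fixture genome is deliberately small (~14.8 kb, below the preferred
50 kb range; the size warning is expected and asserted) so the whole suite
runs in well under a minute. What passing tests therefore do **not** show:
behavior on realistic read error/quality models, paired-end insert-size
effects, duplicate-marking artifacts, or genuinely ambiguous multi-mapping
in the IRs — the simulated reads are single-end, ungapped, and fully
matching; complex CIGARs (deletions, splices) and category filtering are
exercised by small handcrafted alignment tables instead. Perturbation
switches (`ir_point_mutation`, `ir_gene_deletion`, `ir_length_change`)
each break exactly one equality criterion and are asserted to produce
exactly the corresponding warning class.

## Problem sizes used in the tests

The property suites run on genomes of 20–500 bp with up to 200–400 random
reads (100 randomized sets for the sweep-vs-pileup oracle, 10 randomized
partitions for the conservation suite), the exhaustive boundary-splitting
check on a 30 bp toy partition over all 465 spans, and the end-to-end
checks on the 14.8 kb fixture — sizes chosen so exhaustive and brute-force
oracles stay exact while the full suite completes in about half a minute.

## Known limitations

* IR detection relies entirely on annotations; unannotated or mislabelled
  IRs yield an unpartitioned map rather than a corrected one.
* The BAM is read as a linear alignment; coverage at the circular origin
  junction is whatever the mapper produced against the linearized
  reference.
* No GC-content track, multi-genome comparison rings, or interactive
  viewing; one genome per figure.
* Gene labels are not globally decluttered beyond same-origin duplicate
  suppression; very dense annotations will overlap at small text scales.
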