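---
title: "Phylogenetic footprinting of degenerate binding sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic footprinting of degenerate binding sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisfoot)
```

## The screen

Functional transcription-factor binding sites tend to be conserved across
related species while the surrounding non-coding sequence drifts.
`cisfoot` implements a conservation-based ("phylogenetic footprinting")
screen for such sites in promoter-proximal sequence, built around the
biology of Notch signalling in the nematode pharynx: the Notch effector
LAG-1 (a CSL-family factor, CBF1/Su(H)/LAG-1) binds the degenerate
heptamer `RTGGGAA`, and the pioneer factor PHA-4/FoxA binds `TRTTKRY`.
Co-occurrence of conserved sites for both factors within a short distance
is treated as evidence for a combinatorial cis-regulatory module.

The screen proceeds in four stages over a focal genome and two or more
related genomes with single-copy orthologs:

1. **Upstream extraction.** For every eligible focal gene (a single
   ortholog in at least two other genomes) the 5 kb window upstream of
   the annotated gene start is extracted, strand-aware, truncated at
   contig edges. The window is deliberately *not* truncated at
   neighbouring genes: two divergently transcribed ("head-to-head")
   genes legitimately share one intergenic region, and a site falling in
   both windows is reported once with both gene ids.
2. **Motif scanning.** All occurrences of the degenerate IUPAC pattern
   are enumerated on both strands (minus-strand hits are matches of the
   reverse-complement pattern on the forward text), overlapping hits
   included. `N` in the genome never matches any pattern symbol, so
   assembly gaps cannot create sites.
3. **Conserved blocks.** Each focal upstream region is pairwise-aligned
   to the orthologous region of every other species, and conserved
   sequence blocks — at least 14 alignment columns at 70% or more
   identity — are extracted.
4. **Conservation calling and the composite filter.** A focal hit is
   *supported* by a species when it lies fully inside a conserved block
   of that species' alignment and the block's interval on the partner
   region carries at least one occurrence of the same motif (either
   strand). A hit is *conserved* with support from at least two other
   genomes. Genes with a conserved primary (LAG-1) site and a conserved
   secondary (FoxA) site whose nearest-edge gap is at most 110 bp are
   *composite* genes.

## Worked example

```{r example}
lag1 <- compile_motif("LAG1", "RTGGGAA")
lag1
scan_motif("CCGTGGGAATT", lag1)
check_mutant(lag1, wild = "GTGGGAA", mutant = "GAGGCAA")
```

The `check_mutant()` report mirrors how site-abrogating reporter
mutations are designed: the wild-type sequence must match the consensus
and the mutant must not, on either strand.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_bp` | 5000 | upstream window, bp from the annotated gene start |
| `primary_motif` | `RTGGGAA` | CSL/LAG-1 consensus |
| `secondary_motif` | `TRTTKRY` | PHA-4/FoxA consensus |
| `min_block_len` | 14 | minimum conserved-block length (alignment columns) |
| `min_block_identity` | 0.70 | minimum block identity fraction |
| `min_species` | 2 | other genomes that must support a hit |
| `max_composite_distance` | 110 | maximum nearest-edge gap between the two sites, bp |
| `strands` | both | scan strands |

The defaults are the screen's operating point; all are exposed through
`validate_config()` / `run_screen()`. The upstream window is measured
from the annotated gene-feature start (the GFF3 feature type is
configurable) — annotation conventions differ on whether this is the
transcription or translation start, and the screen does not attempt to
distinguish them. Scanning both strands is the inclusive default since
CSL sites act in either orientation; `strands` restricts it.

## Numerical and algorithmic choices

**Alignment.** Pairwise alignment uses affine-gap dynamic programming
(`Biostrings::pairwiseAlignment`) with match +1, mismatch −1, gap of
length L costing 2 + L, in ends-free ("overlap") mode by default, local
mode optionally. Tie-breaking among co-optimal alignments follows the
aligner's fixed traceback rule; identical inputs give byte-identical
alignments, which is the property the screen needs. The substitution
matrix treats `N` as a mismatch against everything, including `N`.

**Block maximality.** "Regions of at least 14 nt with at least 70%
identity" does not pin down a unique decomposition. The convention here:
report intervals meeting both thresholds that cannot be extended by one
column on either side without dropping below the identity threshold,
resolving overlaps greedily left to right (earlier start, then longer
block). This is deterministic and is verified against exhaustive interval
enumeration in the tests. Gap columns count against identity by default
(`identity_denominator = "all"`); the `"ungapped"` denominator is
available. One consequence of greedy selection worth knowing: the *family*
of qualifying intervals shrinks monotonically as thresholds tighten, but
the summed length of the selected non-overlapping blocks can occasionally
rise when a short block stops pre-empting a longer overlapping candidate.
Gene-level conservation counts behave monotonically in practice.

**"Aligned to blocks containing" the motif.** The default reading
requires the partner-side block to contain the motif *anywhere*; the
stricter positional reading (motif within the partner interval spanned by
the hit's own alignment columns) is available as `strict_position = TRUE`.
Both are implemented because the phrase genuinely under-determines the
rule; the anywhere-in-block reading is the default as the more literal
one. The composite distance is the nearest-edge gap, inclusive at the
bound (a gap of exactly 110 bp qualifies; overlapping motifs have
distance 0). FoxA sites in the composite filter are required to pass the
same two-genome conservation rule as LAG-1 sites.

## The synthetic promoter generator

Genome-scale inputs are large and their ortholog calls are data, not
computation, so the package ships a generator
(`simulate_ortholog_set()`) that emulates the statistical structure the
screen relies on. Each synthetic gene starts from a uniform-random
ancestral region that evolves independently along a star phylogeny to
each species: every site is substituted with probability *d* by a
uniformly chosen different base, optionally with geometric-length
indels. Under this replacement model two descendants agree at a site
with probability

$$ P(\mathrm{identical}) = (1-d)^2 + \tfrac{d^2}{3}, $$

which the calibration test checks at *d* = 0.2 against simulated pairs
(within three standard errors over 200 pairs of 500 bp). The star
phylogeny is a deliberate simplification: the conservation rule counts
per-species support, so tree shape is irrelevant to the correctness
being tested.

Three gene classes carry the truth table: **conserved** genes plant a
concrete expansion of the primary motif in the ancestor and hold it
invariant in every species with 20 bp invariant flanks (so the enclosing
block passes 14 nt / 70% at moderate *d*) and, for composite genes, an
invariant secondary site within 110 bp; **decayed** genes plant the site
in the focal species only and scramble the orthologous window; and
**negative** genes carry no site. Chance occurrences of the primary
motif are rejection-scrubbed from the ancestor and from every species'
region outside planted windows. The scrub is stronger than the minimum a
negative control needs, and it is deliberate: at low divergence an
entire upstream alignment is one conserved block, so a single chance
`RTGGGAA` in a partner region would lend false support to a decayed site
under the anywhere-in-block rule and make exact truth recovery
impossible. Secondary-motif chance occurrences are left untouched — they
cannot create a composite gene without a conserved primary site.

Defaults are the fixture the validation suite runs end to end: 20 genes
(7 conserved and composite, 5 decayed, 8 negative), a focal species plus
three others, 5 kb regions, *d* = 0.05, no indels. At these settings the
pipeline must recover exactly the planted composite genes with 100%
sensitivity on planted conserved sites and zero conserved calls on
decayed sites, which the acceptance tests assert. `shuffle_dinucleotide()`
provides the matching specificity control (an Altschul–Erikson Eulerian
shuffle preserving dinucleotide counts exactly).

What the generator does *not* emulate: realistic nematode base
composition and repeat structure, lineage-specific rate variation,
correlated indel placement, regulatory turnover (site gain/loss with
compensatory sites elsewhere), and alignment uncertainty at high
divergence. Passing the recovery tests therefore demonstrates that the
machinery is correct under the stated model, not that the screen's
genome-scale sensitivity or specificity on real genomes matches it.

## Degenerate inputs and edge behaviour

Empty upstream windows (genes at contig edges) are returned empty with a
warning and skipped downstream. Genes without strand are dropped with a
warning at annotation parsing; duplicate gene ids and malformed FASTA
records are fatal. Focal genes listed with two orthologs in one species
are excluded entirely (not single-ortholog), and genes with orthologs in
fewer than two other species are dropped — eligibility is fixed at two
regardless of the `min_species` conservation threshold, which only
governs per-hit support. A palindromic pattern matching both strands at
one offset yields two hits, by design; de-duplication belongs to the
conservation stage.

## Problem sizes

The validation suite runs the full pipeline at the default fixture
(20 genes × 4 species × 5 kb), property-based oracle comparisons on
1,000 random sequences for the scanner and 250 random alignments of up
to 60 columns for block extraction, and threshold sweeps on 0.7–1 kb
fixtures, chosen so the whole suite completes in a few minutes on one
core while still exercising every stage at the screen's real window
size.

## Known limitations

- The genome-scale results the screen is modelled on (thousands of
  eligible genes on real assemblies) require external genome and
  ortholog downloads and a specific — unrecorded — alignment
  parameterisation; reproducing them is out of scope here.
- Sites are predicted by consensus matching, not weighted scoring; a PWM
  layer would change the candidate set.
- Conservation is pairwise-alignment-based; a true multiple alignment
  could call blocks differently near indels.
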