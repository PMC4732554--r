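---
title: "ORF-evidence curation of de novo transcriptomes: methods and design"
author: "txcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ORF-evidence curation of de novo transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcurate)
```

## The problem

De novo transcriptome assemblers reconstruct transcripts from short RNA-seq
reads without a reference genome. The result is imperfect in characteristic
ways: a single coding region may be split across two contigs that the
assembler failed to join; a frameshifting indel introduced during sequencing
or assembly may break one open reading frame (ORF) into two; a contig may
contain an improbable exact duplication of its coding region (often on the
reverse strand); and two genuinely distinct coding regions may be fused into
one contig. txcurate detects all of these **before** any downstream
quantification or annotation is trusted, using only the transcripts'
ORFs and the protein-homology evidence of the three longest ORFs per
transcript.

## The evidence model

For each transcript all six reading frames are scanned for maximal
stop-to-stop codon runs (`findOrfs()`); the three longest translations are
the transcript's candidate coding evidence (`topOrfs()`). These candidates
are compared against a protein database by any external search engine; the
package consumes the standard 12/13-column tabular hit format
(`readHits()`) and never bundles a search engine or database.

Classification (`classifyTranscripts()`) then partitions the transcriptome
by how many candidates have significant matches and where those matches
point:

| class | evidence pattern |
|---|---|
| `UNIQUE_HIGH` | exactly one ORF matches below the high band (default E < 1e-12), or one ORF's bit score exceeds twice every other's |
| `UNIQUE_LOW` | best match in the lower band (1e-12 <= E < 1e-8) |
| `NO_HIT` | no match below the lower band |
| `BROKEN_ORF_ERROR` | >= 2 ORFs' best hits share one subject accession, each below the error band (E < 1e-10) |
| `MULTI_GENE` | >= 2 ORFs match distinct accessions below the high band |
| `LONG_REPEAT` | >= 2 ORFs with identical translations |

Precedence runs `LONG_REPEAT` > `BROKEN_ORF_ERROR` > score-dominant unique >
`MULTI_GENE` > `UNIQUE_HIGH` > `UNIQUE_LOW` > `NO_HIT`. Identical ORFs are
tested first because they would otherwise trivially satisfy the broken-ORF
rule while being a different kind of artifact (a duplication rather than a
split). The twice-the-score dominance test sits before the multi-gene test
because a sufficiently dominant ORF is treated as the transcript's single
gene product even when other ORFs pass the E-value band. `MULTI_GENE`
transcripts whose qualifying ORFs lie on one strand without overlapping are
additionally flagged as chimera/fusion candidates; opposite-strand dual-ORF
transcripts are not, since both strands may genuinely be transcribed.

Two separate E-value knobs exist deliberately: the partition band
(`highEvalue`, 1e-12) and the broken-ORF band (`errorEvalue`, 1e-10). They
serve different decisions and are documented as such rather than reconciled
into one number.

For uniquely annotated transcripts a single functional annotation is chosen
(`selectUniqueAnnotation()`): the lowest-E-value hit whose title avoids the
stopwords *chromosome, hypothetical, unnamed, unknown, uncharacterized*
(case-insensitive substrings), falling back to the stopworded best hit when
nothing cleaner exists. A breakpoint hint accompanies each broken-ORF call:
the gap between the two hits' subject-coordinate intervals, which localizes
the lesion on the matched protein.

## Merging fragmented transcripts

`findMergePairs()` joins transcript fragments via shared terminal anchors.
Each transcript is represented by its longest ORF's amino-acid sequence
(default) or by its raw nucleotide sequence. For every anchor length from 5
to 15 the suffixes and prefixes of all representatives are indexed; a pair
(A, B) is a candidate when a suffix of A equals a prefix of B, the anchor
has at least three distinct characters (low-complexity anchors cannot be
trusted to be unique), the anchor maps one-to-one across the whole set at
that length, and both identifiers share the same component prefix (the text
before the first underscore in Trinity-style `C55368_G1_I3` naming — the
assembler's own grouping of related contigs). When several lengths fire for
one pair, the maximal anchor is reported. The scan iterates to a fixed
point: accepted pairs are merged (`applyMerge()`, overlapping the anchor
region once) and products replace their parents before rescanning, so
chains of fragments coalesce and no output pairs a product with its own
parents.

The amino-acid default reflects the geometry of real fragment pairs: the
assembly break typically coincides with a small nucleotide difference
between the fragments (which is why the assembler did not join them), while
the protein sequence across the junction is conserved. The nucleotide mode
is provided for anchors outside coding regions.

## Iterative gene-family expansion

`findGeneFamily()` grows a gene family from a seed protein: query the seed
against the transcriptome's representative proteins, admit hits with
identity strictly above `identityCutoff` (default 40%) and absolute length
difference strictly below `lengthCutoff` (default 50 residues), then query
each admitted member exactly once until an iteration admits nobody. The
iteration matters: family members below the cutoff from the seed directly
are still reached through intermediate members, and the test suite
constructs a three-member chain (45%/45%/20% pairwise identities) that is
fully recovered only after two expansion waves.

Two readings of the length rule exist (absolute residues vs percent); the
package defaults to absolute residues with `lengthMode = "percent"`
available, and takes the absolute value of the difference — a signed test
would admit arbitrarily long hits in one direction. The internal backend is
a deterministic global aligner (BLOSUM62, gap opening 10, extension 0.5;
identity = matches over aligned columns); any external search can be
plugged in through the `backend` argument.

## Quantification and composition

Raw per-transcript read counts are length-normalized as
`normalized = 100 * raw / length(transcript)` — the constant reflecting a
nominal 100-nt read — with zero-count transcripts dropped from ranking
(`normalizeCounts()`, `rankTranscripts()`). No cross-library scaling is
performed; the package targets within-sample abundance ranking, not
differential expression.

`aaComposition()` profiles residue percentages of a representative ORF
(reported rounded to integers; exact values kept internally, summing to
100). `flagCompositionClass()` applies ordered, fully configurable
heuristic rules; the shipped defaults flag "proline-rich" at P >= 15% and
"putative extensin (L/H/V-rich)" at L+H+V >= 35% with each >= 8%. These
thresholds are reverse-engineered from two exemplar wall proteins (19%
proline; 18/13/10% leucine/histidine/valine over 143 residues) and are
flags for follow-up, never assignments.

## Secondary screens

`screenNcrna()` routes transcripts with no protein-level match through a
nucleotide-space comparison against a user-supplied noncoding-RNA set;
`screenProteome()` checks annotated genes for presence in a reference
proteome (default significance 1e-5, strict inequality, exposed as an
argument). Both consume externally produced hit tables; verdicts are
monotone in the threshold and every queried id appears exactly once.

## The synthetic-data generator

`simulateTranscriptome()` makes the whole workflow testable with no
database and no search engine. A seeded pool of random proteins (150–350
residues, typical single-domain plant protein sizes) is back-translated
with randomized synonymous codon usage and embedded in random UTR context
(50–300 nt per side, enough to produce realistic decoy ORFs for the top-3
selection). Error classes are planted constructively:

* **broken ORF** — one nucleotide inserted at a mid-CDS codon boundary,
  splitting the ORF into two fragments whose mock hits share an accession
  with abutting subject ranges;
* **long repeat** — the coding cassette duplicated in reverse complement
  within one transcript, yielding two identical reverse-strand ORFs;
* **mergeable pair** — one CDS cut into two same-component transcripts
  sharing a unique 12-residue terminal anchor, with a single synonymous
  nucleotide difference inside the downstream anchor copy (mimicking why
  an assembler fails to join such fragments);
* **chimera** — two coding regions concatenated on one strand;
* **no hit** — random non-coding sequence.

Mock E-values derive from a documented monotone map of matched residues
(floored at 1e-180); they are ordinally meaningful only, generated far
from the decision bands so threshold semantics are exercised without
modelling extreme-value alignment statistics.

Two design points deserve emphasis. First, back-translation uses seeded
*randomized* synonymous codons rather than one fixed codon per residue: a
fixed codon table leaves the reverse strand of every CDS nearly stop-free,
and the resulting long reverse-strand decoy ORFs displace genuine evidence
from the top-3 selection. Second, the generator enforces its ground-truth
contract by construction verification: after building each transcript it
checks that every planted coding segment is fully visible, in phase, among
the top three ORFs (and that merge fragments are the longest ORF of their
transcript), resampling the random context otherwise. Without this,
occasional chance decoys would make an injected label unrecoverable by
*any* correct implementation, turning truth-recovery checks into coin
flips. All resampling draws from the single seeded stream, so output
remains byte-identical for a given seed.

What the generator does **not** emulate: read-level sequencing error,
coverage-dependent fragmentation, alternative splicing, paralog families
with graded similarity, or realistic E-value statistics. Passing the
truth-recovery suite therefore demonstrates that the decision logic is
implemented correctly under unambiguous evidence, not that the thresholds
are optimal for any particular real dataset.

## Numerical and degenerate-input choices

* ORFs are stop-to-stop and include partial terminal runs (transcript ends
  are usually truncated mid-ORF); the minimum length is 10 residues,
  configurable. Ambiguous codons translate to `X` and never terminate a
  run. Scan order (forward frames 1–3, then reverse, 5'→3' within frame)
  fixes ordinals and every tie-break downstream.
* Best-hit selection orders by E-value, then larger bit score, then
  lexicographic accession, so permuting hit-table rows never changes any
  class (asserted as a property test).
* Equal-length ORFs in `topOrfs()` resolve by scan order; equal identities
  in merging resolve by requiring strict one-to-one anchor maps.
* Sequences shorter than one codon yield no ORFs with a message, not an
  error; empty transcript sets flow through the whole pipeline and produce
  empty reports with success status.
* Problem sizes in the shipped checks (100-gene simulations, 200-sequence
  oracle comparisons, 100-residue alignment fixtures) were chosen to give
  stable, fully deterministic results while keeping a complete run in the
  tens of seconds.

## Report bundle

`writeReports()` emits `high_annotated.csv`, `lower_annotated.csv`,
`annotated_none.csv`, `errors.csv`, `morethanone.csv`, `merged_pairs.txt`
and `counts_normalized.tsv`. Every transcript appears in exactly one of the
four partition files — multi-gene transcripts file under the high-
significance report (their annotations are high-significance) and appear
*additionally*, one row per annotation, in `morethanone.csv`. The exact
column layouts are this package's convention, documented in
`?writeReports`.

## A short worked run

```{r example, eval = FALSE}
sim <- simulateTranscriptome(nGenes = 100, nBroken = 5, nRepeat = 2,
                             nMergeable = 4, nChimera = 3, seed = 42)
res <- runPipeline(sim$transcripts, sim$hits, counts = sim$counts,
                   outDir = "reports")
res$classification
labelRecovery(sim$truth, res$classification, res$mergePairs)
```

## Known limitations

* "Same gene" means equal subject accession strings; isoforms deposited
  under different accessions are not unified, so some genuine broken-ORF
  errors will be classified `MULTI_GENE`.
* The score-dominance rule uses raw bit scores; databases with wildly
  different entry lengths can make dominance over-eager.
* Merging trusts anchor uniqueness within the input set; on very large
  transcriptomes short anchors (length 5–6) will often fail the one-to-one
  test and contribute little.
* Composition flags are heuristics derived from two exemplars; they are
  starting points for manual inspection.
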