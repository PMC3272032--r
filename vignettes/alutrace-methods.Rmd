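---
title: "Methods: detecting recent Alu insertions from Alu-anchored bisulfite reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting recent Alu insertions from Alu-anchored bisulfite reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Alu elements are ~300 bp primate SINE retrotransposons, mobilized in
trans by the LINE-1 machinery through target-primed reverse
transcription (TPRT): the ORF2P endonuclease nicks genomic DNA at a
degenerate `TT/AAAA` consensus, and reverse transcription of the Alu RNA
in place leaves three sequence hallmarks — a short exact target site
duplication (TSD) flanking the element, the cleavage motif in the 5'
flank, and a poly-A tail at the 3' end. Young AluY-subfamily copies are
still retrotranspositionally active, and their CpG-dense bodies are
normally kept heavily methylated, which silences their internal RNA
polymerase III promoter (the A box at element positions 5–16 and the B
box at 75–84).

`alutrace` re-implements, as a tested and reusable pipeline, an analysis
strategy for *Alu-anchored bisulfite PCR* libraries: amplicons that
contain the 5' end of an Alu element plus its (usually unique) upstream
genomic flank, sequenced after bisulfite conversion. From such reads the
pipeline (i) finds elements absent from the reference annotation —
candidate evolutionarily recent insertions — by mapping the Alu-masked
5' flanks to an in-silico bisulfite-converted reference, and (ii) calls
per-CpG methylation of the elements and their flanks from the same
reads.

## Pipeline model

1. **Reference preparation.** The reference is reduced to two
   three-letter spaces: CT (every C→T) and GA (every G→A). A read
   converted on the plus-strand chemistry matches the CT space exactly
   once it is itself C→T reduced; its reverse complement, G→A reduced,
   matches the GA space. All conversion-consistent differences vanish by
   construction, so ordinary exact matching is conversion-aware.
2. **Alu masking / flank extraction** (`extract_flank`). Each read is
   locally aligned (match +1, mismatch −1, affine gaps opening 8 /
   extension 2) in CT space against the bundled subfamily consensus set;
   the read is masked from the alignment start, and the retained prefix
   is the genomic flank. Reads with no hit scoring ≥ 25 are rejected
   `no_alu`; flanks shorter than 40 bp are rejected `short_flank`.
   The junction is *anchored at the first run of 10 consecutive match
   columns*: in a three-letter alphabet ~45% of random positions match,
   so a chance positive-scoring prefix of consensus interior laid over
   the flank would otherwise drag the inferred element start leftwards
   by up to tens of bp for 5'-truncated elements. The whole consensus
   (not only its 5' head) is used as the query for the same reason.
3. **Iterative mapping** (`map_iterative`). A seed-and-extend
   re-implementation of the multi-cycle decreasing-word-size strategy:
   word sizes 100, 80, 60, 40; a candidate locus needs an exact seed of
   the cycle's word size and is extended *ungapped* along its diagonal;
   acceptance requires whole-flank identity ≥ 0.95 in all cycles but the
   last, where instead a best perfect match of ≥ 40 bp is required
   (reported with identity 1.00). Resolved reads leave the pool. A read
   is **unique** if it has a single accepted locus or its best score
   beats the second best by ≥ 5 score units; exact ties are ambiguous.
   The margin, the tie rule, and the strictly ungapped extension are
   package choices: the generator emits substitution errors only, and
   ungapped extension keeps the mapper exactly equivalent to an
   all-offsets brute-force oracle, which the test suite exploits.
4. **Junction classification and clustering.** The junction of a unique
   read is the reference coordinate at its Alu-mask boundary (alignment
   end for CT-space hits, alignment start for GA-space hits). Junctions
   within 10 bp (absolute distance) of an annotated Alu are
   `known_adjacent`; the rest are `putative_novel` and are single-linkage
   clustered with a 10 bp merge window, cross-referenced against a
   known-polymorphic-insertion BED (novel = no known site within 50 bp),
   and assigned genic context by cluster midpoint with precedence
   exon > UTR > intron > intergenic ("exon" meaning coding exon,
   disjoint from UTR features).
5. **Hallmark annotation** (`annotate_features`). On an allele sequence
   with known insert boundaries (simulation truth, or a verified locus):
   the TSD is the longest exact string that is simultaneously a suffix
   of the upstream flank (within 25 nt of the junction) and a prefix of
   the sequence after the tail; the cleavage site is the 6-mer nearest
   the junction minimizing Hamming distance to `TTAAAA` (imperfect
   motifs are reported, not failed); the poly-A length is the
   uninterrupted A-run after stripping the leading non-A element
   remnant (`CTC…`), with the full tail region reported separately;
   the subfamily is the argmax alignment score against the consensus
   set, ties broken toward the more derived subfamily.
6. **Methylation calling.** Reads are aligned to the *unconverted* local
   reference in CT space; at each covered reference CpG cytosine a
   retained C is methylated, a T unmethylated, anything else (including
   an indel over the CpG) uncallable and excluded from denominators.
   The fraction of non-CpG reference cytosines read as T is a per-read
   conversion QC; reads below 0.98 are flagged but not dropped (no QC
   rule is inherited from the source protocol, so filtering is left to
   the user). Region summaries report percent methylation per A box, B
   box, arms and whole element; a region with no callable CpG is `NA`,
   never 0. Hemizygous allele comparisons use two-sample binomial
   confidence intervals per shared flank CpG.

## The synthetic world

The generator's defaults are the package's stated world: TSD lengths
4–17 nt and poly-A tails 11–45 nt (the ranges observed for verified
recent insertions), per-CpG element methylation probability 0.907 (the
published average for young elements), hemizygosity probability 36/47
(the verified-event fraction), bisulfite conversion 0.99, sequencing
substitution rate 0.005, 5 reads per locus, and amplicon flanks drawn
uniformly from 40–250 bp (the source libraries' flank distribution is
unpublished; this is a free choice). Background Alu copies diverge from
their consensus at 5% per base; novel insertions are inserted without
divergence, in plus orientation (the truth record carries no strand
field), with 10% of events 5'-truncated by up to half the element.

Nick sites are 6-mers within Hamming distance 1 of `TTAAAA`, the nick
falling between the TT and the AAAA; the TSD starts at the AAAA. Sites
are kept ≥ 50 bp from annotated elements and ≥ 400 bp apart, and a
drawn TSD that is a homopolymer is re-drawn: a homopolymer TSD abutting
the poly-A tail makes the TSD/tail boundary formally unidentifiable,
and exact round-trip recovery would be ill-posed. The truth
`breakpoint` is the 0-based position immediately after the first TSD
copy — the top-strand nick, which is exactly the coordinate a mapped
flank's 3' end reaches — so breakpoint error compares like with like.

Methylation states of a novel element are drawn once per allele and
frozen in the truth record; reads then reflect those states through the
chemistry. Clone-style simulations (`simulate_bisulfite_clones`) instead
draw states per molecule, which is what bisulfite cloning actually
samples and what the 90.7%-recovery check uses.

What the generator does **not** emulate: 454 homopolymer errors, PCR
duplicates and chimeras, restriction-site-determined flank lengths,
minus-strand novel insertions, and multi-chromosome references in the
bundled scenarios. A green end-to-end test therefore establishes
correctness of the algorithms under substitution-only noise and exact
truth bookkeeping, not robustness to platform-specific artifacts.

## Numerical and reporting conventions

* Coordinates are 0-based half-open internally; user-facing locus
  strings are 1-based inclusive (`chr1:start-end`).
* Library ratios are `round(100 * insertion_regions / regions_mapped,
  2)`; aggregate percentages are printed with one decimal. Recomputing
  the bundled eight-library worked example reproduces every printed
  value except the multi-library percentage, where the exact arithmetic
  100·87/327 = 26.605 rounds to 26.6 against a published 26.7 — an
  apparent one-ulp rounding slip in the source table, which the package
  reports as computed.
* `regions_mapped` ("distinct regions") counts merged loci (10 bp
  window) among uniquely mapped reads, not reads.
* The whole-element methylation level is reported read-weighted (the
  call-weighted mean of disjoint sub-regions equals it exactly); a
  locus-weighted average can be formed from the per-locus table, since
  the published averaging convention is unstated.
* Config files are JSON; every random draw funnels through the single
  config seed, and each generator stage derives a fixed offset of it,
  so stages are individually reproducible.

## Known limitations

* The mapper's ambiguity rule (score margin 5) is a documented choice;
  the source analysis does not define "unambiguous" operationally.
* Junction anchoring (first 10-match run) can shift an inferred
  junction a few bp to the right when the true element start is itself
  mutated; at the simulator's divergence settings this stays within the
  5 bp acceptance tolerance.
* Feature annotation requires allele sequences with known insert
  boundaries (from simulation or locus verification); the amplicon
  design never covers the element right arm or 3' flank, so hallmark
  annotation from reads alone is impossible by construction.
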