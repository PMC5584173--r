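---
title: "splicekey: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicekey: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicekey)
```

This vignette is the package's own account of the science it implements:
the detection model and its assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## 1. The detection model

### Paired splice-junction keys

Every annotated intron contributes a pair of exonic anchor sequences in
spliced (strand-aware) orientation: the **donor key** — the last *k* bases
of the upstream exon (the E5 sequence of the splicing-code view of intron
recognition) — and the **acceptor key** — the first *k* bases of the
downstream exon. A junction-spanning read from a fusion transcript must
contain a donor key of one gene immediately followed by an acceptor key of
another; that adjacency is the scanner's primary signal, and it converts
fusion detection into O(1) hash lookups per read offset instead of full
alignment.

*k* = 20 by default (configurable via `build_splicingcode(k = )` /
`scan_params(k = )`). Two 20-mers give a per-read random-match floor of
0.25^40 ≈ 8.3 × 10⁻²⁵ (section 4), small enough that random chimeras are
effectively impossible, while a single 20-mer anchor alone would not
constrain the second gene at all. Both keys share one *k*; nothing in the
model requires asymmetric lengths. Intronic (I3) sequences of the
splicing-code model are not used: junction-spanning mRNA reads contain only
exonic sequence.

### Table filtering

`filter_table()` applies three declared filters, mirroring the three
artifact classes that make anchor tables unreliable:

* **poor quality** — any non-ACGT base in a key;
* **highly repetitive** — key mononucleotide Shannon entropy < 1.0 bit
  (e.g. a 90/10 two-base composition is ~0.47 bits, well under it) or a
  homopolymer run ≥ 15 of the 20 bases; both thresholds exposed;
* **duplicates/ambiguity** — exact (donor, acceptor) pair duplicates keep
  only the first record in the deterministic (gene, transcript, intron)
  sort, with *every* member of a duplicated group flagged `duplicate`
  (so whole-gene duplications remain visible even through the kept copy);
  and any single key occurring in more than `max_gene_hits = 2` distinct
  genes is removed as ambiguous. The cap of 2 deliberately tolerates one
  recent duplication of a gene — the 17q21.31 region that motivates the
  package carries partial *KANSL1* duplications — while still suppressing
  repeat-derived keys.

The filter is idempotent, and retention counts (raw vs retained) are kept
on the table. Intron records are enumerated per transcript and
deduplicated at the table level; whether an intron catalogue should be
transcript- or gene-level is not decidable from the method description we
reconstruct, and per-transcript enumeration plus exact-pair dedup is the
assumption made here.

### Scanning and exact extension

For each read offset *p* (all offsets by default; `anchor_at_read_start`
restricts to the stricter variant where the donor key opens the read), a
donor-index hit at `read[p-k+1..p]` paired with an acceptor-index hit at
`read[p+1..p+k]` triggers **extension**: the remaining read prefix is
compared base-by-base against the spliced donor transcript upstream of the
junction, the remaining suffix against the spliced acceptor transcript
downstream, and the whole read must be consumed with
`max_mismatch_extension = 0` mismatches. Extension runs along the
*spliced* transcript, not genomic DNA: observed fusion isoforms span
several exons on each side of the junction, which only spliced-sequence
extension explains (a genomic-contiguous comparison would stop at the first
internal intron). Base qualities are ignored — the identity requirement is
the quality filter.

Candidates of maximal matched length *L* = L5 + L3 are kept per read, with
deterministic lexicographic ordering; a read matching more than
`max_pairings = 4` distinct gene pairs at maximal *L* is discarded as
ambiguous (counted in `ScanStats`). Reads shorter than 2*k* are counted
and skipped. The ambiguity policy is this package's own; the maximal-*L*
rule is forced by the model (a shorter reconstruction is strictly worse
evidence), and the cap guards against repeat-rich reads that survive table
filtering. Paired-end mates would be scanned independently; the method is
single-end by construction.

### The artifact filter

The classical failure mode of junction callers is a read that *also* has a
contiguous one-locus explanation: processed pseudogenes, tandem or
segmental duplications, and unannotated splice variants. The
`contiguous_locus_filter()` searches the full read (both orientations)
against a database of (a) every spliced transcript and (b) every gene's
genomic span extended by `flank = 20,000` bases — the 20-kb window follows
the upstream/downstream gene-context convention of the original screen —
allowing `max_mismatch = 2` mismatches and no gaps. Containment in any
single database sequence rejects the candidate (`rejected_contiguous`).
This replaces an external BLAST-against-EST-database stage with a
self-contained, deterministic screen; the mismatch bound stands in for
unpublished identity cutoffs and is configurable. No gapped homology and
no repeat-library masking are attempted.

Accepted junctions are classified totally: `intra_gene` (same gene; only
reachable when `require_distinct_genes` is off), `read_through` (same
chromosome and strand, acceptor downstream of donor in transcription
direction, gene-body gap ≤ `read_through_gap` = 100 kb — the gap value is
this package's choice, exposed as a parameter), `inverted_order` (same
chromosome, fused order reversing the genomic order in the donor's
transcription frame — the *KANSL1*→*ARL17A* architecture), else
`distal_fusion`.

## 2. Quantification

Junction identity is the coordinate 4-tuple (donor gene, donor junction
coordinate, acceptor gene, acceptor junction coordinate), so never-seen
isoforms are first-class. Support counts are raw read counts by default;
`dedup_identical_reads` collapses byte-identical reads for PCR-heavy
libraries. **NSJMR** — splice junctions per million reads — is
`count × 10⁶ / total_reads` with the denominator equal to total reads in
the library (not mapped reads; configurable by passing a different total).
Samples under the `gate = 2 × 10⁷` total-read depth gate are excluded from
presence/absence cohort calls: below that depth a singleton junction read
cannot be distinguished from sampling noise for a low-abundance fusion.
`translate_fusion_orf()` reports the longest ATG-to-stop open reading frame
across the three forward frames (ties to the leftmost start) for fusion
peptide inspection.

## 3. Cohort statistics

`fisher_exact_2x2()` is implemented in the package (log-factorial
hypergeometric enumeration over all tables with the observed margins)
rather than delegated, because the two-sided convention is load-bearing:
the **minimum-likelihood convention** — summing the probabilities of all
tables no more likely than the observed one (relative tolerance 10⁻⁷) — is
the default of mainstream statistical software and is what this package
documents and tests; tail-doubling would push a 14/13-vs-2/15 cohort table
from p ≈ 0.00996 to the other side of a 0.01 threshold. The test suite
checks the implementation against an independent `dhyper` enumeration and
against `stats::fisher.test` to 10⁻¹⁰.

Frequencies are reported to one decimal (the convention of the cohort
tables this reproduces); fold ratios are ratios of proportions with a
zero-denominator reported "not estimable"; odds ratios use the
cross-product with a Haldane 0.5 correction *for display only* when a cell
is zero — p-values never use corrections. No multiple-testing correction
is applied by default: the reproduced analyses are single-hypothesis
tests. Patients with replicate libraries should be collapsed to
patient-level positivity (any passing library positive) before building
the table.

## 4. The random-match error model

A candidate surviving extension has *L* bases identical to a specific
donor-prefix/acceptor-suffix concatenation. Under a uniform i.i.d. base
model, a random read matches with probability 0.25^L, computed in log
space (`random_match_probability()`); the dataset-level summary reports
the error at the minimum *L* (the weakest accepted call, at the 2*k* = 40
floor: 0.25⁴⁰ ≈ 8.3 × 10⁻²⁵) and at the lower-median *L* (a typical fully
matched read of ~98 bases: 0.25⁹⁸ ≈ 10⁻⁵⁹). `expected_false_calls(n, L)`
is the linear expectation bound n·0.25^L — at 2 × 10¹⁰ reads against the
40-base floor it is ~1.7 × 10⁻¹⁴, consistent with zero random chimeras
ever being accepted. The model is deliberately composition- and
quality-agnostic; base-composition-aware refinements would only lower
these bounds for the GC ranges of real exons.

The empirical counterpart is `generate_random_chimeras()`: seeded
exon–exon and exon–intron chimeric reads (random fragments of random
features of different genes, uniform split, lengths uniform in 75–101)
pushed through the full pipeline. Chimeras whose fragments abut exactly at
annotated donor/acceptor boundaries are excluded at generation — such a
read *is* a genuine junction read, not an artifact. The acceptance suite
runs 10⁵ + 10⁵ chimeras against a 20-gene genome and requires zero
accepted calls.

## 5. Pedigree analysis

The fusion is modelled as a single autosomal biallelic **dominant presence
locus**: phenotype positive ⇔ at least one + allele; no de-novo events, no
mosaicism (a de-novo-allowed mode is out of scope — the marker this
reproduces is strictly inherited). Consistency checking, forced-genotype
inference and swap scanning all rest on exhaustive genotype search with
constraint propagation (parents assigned before children, transmission
checked incrementally), enforced for pedigrees of ≤ 25 members —
correctness over scale; peeling algorithms would be the next step for
larger families, and the three-generation families of interest have 17.

Evidence handling: pedigrees carry a phenotype column and, optionally, a
known-genotype column (e.g. WGS zygosity). This matters structurally: with
phenotypes alone, a negative child of a positive parent is always
consistent (the parent may be heterozygous), so the classic mixed-sample
signature — one deviant child among 11 — only becomes a *Mendelian
violation* when the mother's homozygosity is pinned by sequencing
evidence. `example_pedigree()` ships exactly that configuration. When RNA
and WGS typing conflict for one individual, WGS takes precedence.
`mendelian_check()` reports all minimal-cardinality phenotype flip sets
(flipping an observation voids that individual's genotype pin);
`swap_scan()` tests every unordered pair with differing phenotypes,
moving phenotype *and* genotype call together — a swapped sample moves
wholesale.

`infer_genotypes()` reports, per individual, the set of genotypes
realizable in at least one consistent assignment (forced when a
singleton), and for ambiguous individuals a maximum-likelihood genotype:
for parents, by the **offspring-transmission likelihood** — the product
over children of the phenotype probability given the candidate genotype
and the co-parent (co-parent at its forced genotype, or marginalized under
the population prior when ambiguous) — and for childless individuals, by
the Hardy–Weinberg prior implied by the carrier frequency `prior = 0.289`
(the European-ancestry carrier figure; allele frequency
q = 1 − √(1 − 0.289) ≈ 0.157). The transmission convention is chosen so
the reported ratio is the interpretable one: a mother with 11/11 positive
children and a homozygous-negative father is favoured homozygous-positive
over heterozygous by (1)¹¹ : (½)¹¹ = 2048 : 1 exactly. Folding founder
priors into that ratio would multiply in a mother-given-grandparents term
and obscure the transmission evidence; the prior is still used where no
offspring evidence exists.

## 6. The synthetic-data generator

`make_genome()` draws i.i.d. uniform ACGT chromosomes and places
non-overlapping multi-exon genes on alternating strands (one transcript
per gene; multi-transcript models are supported by the table code and
exercised with hand-built annotations in tests). Defaults — 4–8 exons of
120–300 bp, introns 200–800 bp, reads uniform in 75–101 bp, substitution
errors only — emulate compact mammalian-like gene structure at desk scale
and the read-length range of the reproduced study. Substitution-only
errors are a deliberate simplification: the scanner demands exact
identity, so any error class merely destroys candidate reads; indels would
exercise nothing substitutions do not. Coverage bias, quality-score
realism and paired-end fragments are not modelled — so passing tests show
correctness of the calling logic under the stated read model, not
robustness to platform-specific artifacts in real libraries.

`inject_fusion()` builds the fused genomic allele (donor gene through its
breakpoint intron joined to the acceptor gene from its breakpoint intron,
transcription orientation on both sides, breakpoints uniform inside the
introns) and derives each isoform's mRNA from contiguous donor-prefix /
acceptor-suffix exon ranges. The generator *validates* that every isoform
is derivable from the allele: donor exits must not lie downstream of the
donor breakpoint intron. The bundled six-isoform default therefore places
the donor breakpoint in intron 6 — the smallest intron compatible with
donor junctions at exons 2, 3 and 6 — and the acceptor breakpoint in
intron 2 (entries at exons 3, 4, 7, 8), with the second isoform weighted
50×, emulating the observed architecture and expression skew of the
six-isoform fusion family and keeping ratio-recovery tests meaningful.
The inverted-order architecture is modelled at the allele-sequence level
only; the duplication complexity of the real 17q21.31 H1/H2 haplotypes is
not simulated. Per-isoform read counts are round numbers chosen for test
power, not study claims.

For artifact-filter testing, `plant_sequence()` appends extra sequence
(e.g. a processed cDNA copy, or a duplication-derived chimeric locus)
downstream of a chromosome's last gene — inside the 20-kb homology window,
without disturbing any annotated coordinate. A *single-gene* pseudogene
can only generate same-gene candidates, which `require_distinct_genes`
already blocks; the contiguous-locus rejection path is therefore exercised
by planting a chimeric cDNA locus, exactly the duplication-derived
configuration that produces real-world false fusions. `simulate_cohort()`
draws carrier status as a seeded binomial (default 0.289) with optional
per-sample read synthesis; cohort-level Monte-Carlo runs at carrier-flag
level, which *is* the binomial model those analyses assume.

All generators are bitwise-reproducible from their seed; every emitted
read appears in a truth table with its origin, position and injected
errors.

## 7. Numerical and degenerate-input choices

* Coordinates are 1-based inclusive end-to-end (the GTF/IRanges
  convention), declared once here to prevent off-by-one drift; all
  serialized formats use their native conventions.
* Fisher p-values: log-factorials, relative tolerance 1 + 10⁻⁷ on the
  point-probability comparison, clamped to [0, 1]; deterministic.
* Error probabilities: stored as log₁₀; `L = 0` returns exactly 1.
* Tie-breaks: candidate ordering is lexicographic (donor gene, acceptor
  gene, split offset); junction tables order by support then id; ORF ties
  go to the leftmost start; flip/swap sets are sorted.
* Degenerate inputs error early with named subjects: truncated FASTQ
  records report the read index, out-of-bounds exons name the transcript,
  empty candidate sets make `dataset_error_summary()` error rather than
  return fictitious bounds, `fold_ratio()` refuses a zero reference with
  guidance to report "not estimable", cyclic pedigrees and > 25-member
  families are refused.
* `scan_fastq()` streams 4-line FASTQ records in chunks (constant memory
  in read count); multi-line FASTA-style FASTQ is not supported.

## 8. Problem sizes used by the checks

The bundled verification uses a 20-gene two-chromosome genome for the
2 × 10⁵-read random-chimera control, a 4-gene genome bearing the
six-isoform fusion for end-to-end recovery (50 planted junction reads over
5,000 background reads), 100-replicate seeded cohorts of n = 200 for
carrier-frequency recovery and 200 replicates of 90-vs-90 for cohort
separation, and ≤ 10-member pedigrees for full 3ⁿ oracle comparison.
These sizes were chosen so every brute-force oracle (all-splits scan,
hypergeometric enumeration, 3ⁿ genotype grids) runs exactly, keeping the
fast paths honest.

## 9. Known limitations

* Detection is anchored to annotated splice sites by construction: a
  fusion whose junction uses an unannotated donor or acceptor site is
  invisible. This is the price of the key-table speed and specificity.
* Exact extension (0 mismatches) discards any junction read carrying a
  sequencing error; sensitivity per junction therefore scales with
  coverage, and the mismatch budget is exposed for noisier data.
* The homology screen is ungapped; a pseudogene with a small internal
  indel relative to its parent could evade `rejected_contiguous`.
* The pedigree model excludes de-novo events and mosaicism by design.
* The uniform-base error model is conservative in magnitude but not
  composition-aware.
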