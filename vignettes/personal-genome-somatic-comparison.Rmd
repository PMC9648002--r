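---
title: "Comparing somatic callsets across a personal genome assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing somatic callsets across a personal genome assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persoma)
```

## The problem

Somatic mutations in a tumor are conventionally called against a
population reference assembly. That reference is a mosaic of haplotypes
from unrelated individuals: it lacks repeat copies the patient carries,
carries alleles the patient does not, and differs in homopolymer run
lengths. When the matched normal sample is assembled de novo and used
as the reference instead, three things change for the same underlying
reads: read placement improves, some previously called somatic variants
turn out to be artifacts of reference mismatch, and new somatic events
become visible inside sequence that the population reference simply
does not contain (for example a somatic deletion inside an Alu copy
private to the patient).

`persoma` implements the comparison machinery this substitution
requires, end to end, at desk scale:

* **Cross-assembly SNV lift-over** by flanking-sequence alignment, with
  a two-step identity/length gate and a four-way classification:
  *identical* (alleles and both 50 bp flanks agree between assemblies),
  *equivalent* (alleles agree, flanks differ by germline variation),
  *mapped without call* (the locus exists on the target assembly but no
  consensus call is there), and *unmapped*.
* **Somatic SV selection** from jointly genotyped tumor-normal
  callsets, germline subtraction, caller-dialect harmonization of SV
  type labels, and consensus construction by breakpoint-distance
  clustering.
* **Cross-assembly SV mapping** using 100 bp flanks on each breakpoint.
* **Assembly contiguity statistics** including Top50, the summed length
  of the 50 longest scaffolds — a natural yardstick for a genome with
  48 chromosome arms.
* **Mitochondrial comparison**: rotation of circular contigs to a
  shared anchor, strand correction, and substitution calling.
* A **deterministic simulator** that manufactures a reference genome, a
  personal genome, and tumor truth with exactly the structure the
  analysis assumes, so the whole pipeline can be exercised and scored
  with no external data.

## The mapping model

For an SNV at position $p$ with alleles $r \to a$, two 101 bp queries
are built from the source assembly: the window $[p-50, p+50]$ as-is
(ref query) and the same window with $a$ substituted at the center
(alt query). Both queries are aligned to the target assembly; percent
identity is $100 \cdot m / \ell$ where $m$ is matched columns and
$\ell$ is total alignment columns, gaps included.

Step 1 accepts an SNV when both queries' best hits reach identity
$\ge 99\%$ and alignment length $\ge 101$ columns; SNVs failing step 1
are retried in step 2 at $(95\%, 95)$. In both steps the two hits must
agree exactly on scaffold, start, end and strand, and the mapped
position is the target base aligned to the query center. Note the
center base itself differs between the two queries: the alt query
always carries one mismatch against the normal-genome target, which is
exactly the one mismatch step 1 tolerates.

Because step 1's gate tolerates that one mismatch anywhere, "passed
step 1" is not the same thing as "no flanking differences". The
*identical* category is therefore defined directly: the ref query
aligns end-to-end with zero non-center mismatches and zero gap columns.
Everything mapped with a matching target call but flanking differences
is *equivalent* — the signature of germline variation between the
assemblies. Both the `step` and `category` columns are kept in the
per-SNV output so either accounting can be read off.

Mapping strand is free: on a minus-strand mapping the alleles are
complemented before they are compared with target calls.

### The alignment engine

Queries are short (101–200 bp for SNVs, 100 bp for SV flanks) and
targets are assemblies, so the engine is a seed-and-extend local
aligner: an exact k-mer index (k = 11 by default, 2-bit packed,
forward strand; reverse-strand hits come from aligning the reverse
complement of the query), seeds grouped into diagonal bands within
50 bp, and a full affine-gap Smith-Waterman kernel (Rcpp) run on each
band's window. Scoring is match $+1$, mismatch $-2$, gap open $-2.5$,
gap extend $-2.5$ (a gap of length $L$ costs $2.5 + 2.5L$), emulating
conventional nucleotide-search defaults; the acceptance gates are the
identity/length thresholds above, never e-values.

Two design points keep the heuristic honest:

* **Seed-count pruning.** Any alignment meeting an $(\mathrm{id},
  \ell)$ gate with at most $e$ error columns contains at least
  $\ell - k + 1 - e(k+1)$ intact k-mer seed starts. Seed clusters far
  below that bound (we use half of it) cannot yield a qualifying hit
  and are skipped. This is what makes 1000 queries against a 2 Mb
  genome take seconds rather than minutes.
* **Exhaustive rescue.** On genomes up to 64 kb total, a query with no
  seeds at all is aligned against everything, so on desk-scale targets
  the engine provably returns the same qualifying best hit as an
  exhaustive dynamic-programming search. The test suite enforces this
  equivalence against an independent DP oracle on hundreds of random
  instances.

Best-hit selection maximizes the number of matching bases, with
deterministic tie-breaks (identity, then scaffold name, then position).

## Somatic SV rules

Jointly genotyped tumor-normal SV callsets are reduced to somatic
calls by two rules, applied verbatim to genotype, alternate-read count
and allele fraction (AF):

1. normal `0/0`, tumor `0/1`/`1/1`, tumor alternate count $\ge 5$ and
   tumor AF $\ge 0.2$;
2. normal `0/1`, tumor `1/1`, tumor alternate count $\ge 10$, tumor AF
   $\ge 0.85$, and tumor-normal AF difference $\ge 0.45$ (loss of the
   reference allele over a germline het).

The AF-difference comparison carries a $10^{-9}$ epsilon so the
inclusive boundary survives binary floating point ($0.85 - 0.40 <
0.45$ exactly). Germline subtraction first reduces the normal-sample
evidence to records with AF $\ge 0.1$ and alternate count $\ge 5$, then
drops any tumor call with a compatible-type germline record whose
breakpoints both lie within the 1000 bp merge radius. "Overlap" is
deliberately operationalized with the same breakpoint radius used for
consensus merging, since no more precise rule is standard.

Consensus merging is single-linkage clustering: records of compatible
harmonized type (contractions pool with DEL, expansions with INS) link
when start and end breakpoints each differ by at most 1000 bp;
breakends link through both endpoint pairs. A cluster survives with
support from $\ge 2$ distinct labels (callers, replicates, or calling
methods), and its representative is the member from the earliest label
— deterministic by construction. The implementation is checked against
a brute-force transitive-closure oracle on every instance up to 200
records.

## The simulator

The simulator is the package's study design, not a fixture. Defaults
(all overridable through `simulation_config()`):

* two 1 Mb scaffolds (2 Mb of autosome-like sequence) of i.i.d.
  background at GC 0.41, plus a circular 16,569 bp chrM;
* a repeat library planted into the reference with recorded
  coordinates and 0.5–2% per-copy divergence: Alu-like 300 bp × 6,
  LTR-like 500 bp × 3, SVA-like 1.6 kb × 2, and an (AT) simple repeat
  × 4. Divergence matters: it is what makes flank mapping non-trivial
  and what creates the *equivalent* category;
* germline variation defining the personal genome: SNVs at $10^{-3}$
  per bp, short indels (1–10 bp) at $10^{-4}$, four personal-only
  Alu-like insertions, three 200–500 bp deletions, two tandem
  expansions, and one homopolymer-run extension (10–20 extra A's);
* somatic truth: 500 SNVs in three engineered flanking contexts — 300
  *clean* (flanks identical between assemblies), 150 *flanked* (1–3
  germline SNVs within the 50 bp flanks, placed $\ge 5$ bp from the
  center and the window edges so local alignment cannot trim them),
  and 50 *destroyed* (both flanks replaced by unrelated sequence in
  the personal genome, which defeats both mapping steps) — plus 20
  somatic SVs and one somatic deletion planted inside a personal-only
  Alu copy. Somatic MAF is a 0.8/0.2 mixture of 0.5 (clonal
  heterozygous) and 1.0 (homozygous/LOH), the range in which
  orthogonal validation of such calls is practical;
* caller profiles: per-caller false-negative rate (default 0.05),
  false positives as Poisson with mean $0.02 n$, breakpoint jitter
  SD 30 bp — well inside the 1000 bp merge radius — and a quality
  distribution. `noise_free_profile()` zeroes all three, and with it
  the callset equals the truth record-for-record, which is what the
  recovery tests exploit.

The personal genome is produced by applying a single non-overlapping
edit script to the reference, and every coordinate translation flows
through the aligned-block lift map derived from that script; the map is
exactly invertible wherever it is defined, and length bookkeeping
(personal = reference + net edit length) is asserted in tests. All
randomness flows from one seed through one RNG stream, so a
configuration reproduces byte-identical genomes, truth tables and
callsets.

Deliberate idealizations, and what they mean for interpretation:
somatic SNV sites are placed outside planted repeat copies (so each
flank query has a unique home — in real data, repeat-interior SNVs are
exactly the ones whose lift-over is ambiguous); there is no read-level
simulation, so caller noise is i.i.d. rather than locally correlated;
and germline edits are kept clear of the engineered somatic flank
windows except where a context demands them. Passing recovery tests
therefore demonstrates that the *comparison machinery* is correct under
its stated model, not that any particular caller is accurate on real
reads.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; BED export is the only
  half-open surface.
* N bases never count as matches in any alignment or identity figure.
* Indel normalization is left-align-and-trim against the attached
  genome; caller intersection happens only after both callsets are
  normalized, and multi-allelic records are split on read.
* N50 ties break toward the smaller rank ("first reaches half the
  total"); Top50 percentages use the post-filter total when a minimum
  scaffold length is applied.
* Percentage rendering is round-half-up at two decimals; raw values are
  always retained alongside the labels, and raw percentages over a
  partition sum to 100 exactly.
* Mitogenome comparison requires lengths within 1% and sizes its
  alignment band from the length difference (minimum 100 columns); the
  circular anchor must be at least 20 bp and locate uniquely with at
  most 2 mismatches on either strand, searched across the origin on
  the doubled sequence.
* Degenerate inputs fail loudly: empty FASTA records, unparseable VCF
  coordinates, zero-total reports and anchor ambiguity are all errors,
  not warnings.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  caller_profiles = list(a = noise_free_profile("a"),
                         b = noise_free_profile("b")))
study <- simulate_study(cfg)
res <- crossmap_somatic_snvs(study)
res$summary
#>         category count percent percent_label
#> 1      identical   300      60         60.00
#> 2     equivalent   150      30         30.00
#> 3 mapped_no_call     0       0          0.00
#> 4       unmapped    50      10         10.00
```

The three planted flanking contexts come back as exactly the three
mapped categories, with zero confusion — the partition invariant
(every SNV gets exactly one category, counts sum to the input) holds
by construction and is re-asserted in the tests.

Problem sizes throughout the test suite (2 Mb genomes, 500 SNVs, a few
hundred SVs, 16.5 kb mitogenomes, alignment oracle instances up to
20 kb) are the package's chosen desk-scale study conditions: large
enough that every code path and category is exercised with sensible
base-composition statistics, small enough that the full suite and the
acceptance script run comfortably on a laptop.

## Known limitations

* SNV lift-over handles single-base substitutions only; indel
  cross-mapping is out of scope (the flank construction is defined for
  a center base).
* Translocations/breakends are filtered and clustered but not
  cross-assembly mapped (no flank pair brackets a TRA).
* The simulator plants verbatim-with-divergence repeat copies; it does
  not model nested repeats, segmental duplications, or coverage- and
  mappability-dependent caller error.
* Mitochondrial comparison reports substitutions and indel runs; it
  does not quantify heteroplasmy, and codon-level effect annotation is
  limited to an optional user-supplied gene-interval table.
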