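---
title: "Methods: exact-match HLA typing and its synthetic evaluation"
author: "exactHLA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact-match HLA typing and its synthetic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exactHLA)
```

# The model

`exactHLA` types the classical HLA genes by placing short reads on a
library of allele exon sequences and keeping the alleles whose read
support is both complete and distinctive. The method rests on three
assumptions worth stating explicitly:

* **Exactness as error filter.** Only full-length, 100%-identity
  placements count. At HLA-scale polymorphism, a read with a sequencing
  error is much more likely to match nothing than to match a wrong
  allele, so exact matching doubles as error removal — at the price of
  throwing away roughly a fraction `1 - (1 - e)^L` of reads at per-base
  error rate `e` and read length `L`. Coverage, not error modelling,
  compensates; this is why depth is the dominant performance factor.
* **Spliced references suffice.** Reads are matched against
  concatenated typing exons. A read straddling an exon/intron boundary
  in the genome cannot match and is lost; at exon lengths of 110–280 bp
  versus 150 bp reads this loses a predictable fraction of boundary
  coverage and is absorbed by the score's boundary terms.
* **A true allele is evenly covered.** False alleles assembled from
  pieces of the two true haplotypes show punctured coverage at the
  positions where they differ from both — the signature the score
  function detects.

## The score function

For one candidate allele, each placed read `i` contributes its center
`read_i = (start_i + end_i)/2`; with centers sorted, `D_j` is the
distance between consecutive centers, and

$$\mathrm{Score} = \sum_{j=1}^{m} \left(\frac{D_j}{c}\right)^{3}.$$

Parameters, defaults, and why:

* **`c = 30` bp** — the distance scale at which a gap starts to count.
  With 150 bp reads covering each position ~5× (30× total on spliced
  exons), adjacent centers sit about `150/5 = 5` bp apart under even
  coverage, and `c` is chosen so `D_j/c > 1` flags spacings worse than
  one read per 30 bp. For other read lengths
  `suggestedScoreConstant(readLength)` applies the same `L/5` rule.
* **Exponent 3** — a single large gap must dominate many small ones;
  the cube makes one read-length gap (`(150/30)^3 = 125`) outweigh
  hundreds of ideal 5 bp spacings (`(5/30)^3 ≈ 0.005` each).
* **Cutoff 125** — exactly the score of one uncovered read-length
  stretch. A candidate scoring *above* 125 is discarded; a tie at 125
  is retained, reading "discard above the cutoff" literally. The
  cutoff is deliberately insensitive: at good depth the score filter
  barely engages and the later stages do the work, so the package
  exposes it but does not tune it.
* **Boundary distances (on by default)** — distances from the region
  start to the first center and from the last center to the region end
  are appended, so an allele covered only in its middle is penalized
  like any interior gap. The region end is taken as coordinate
  `regionLength` (one past the last base), which makes the empty
  profile degenerate cleanly to the single maximal distance
  `regionLength`. Turning boundaries off recovers a strict
  "between two adjacent reads" reading.

**A deliberate off-by-one.** `D_j` is defined here as the plain
difference of consecutive centers. An alternative reading — the count
of positions strictly between two centers — differs by 1 and is
inconsistent with the two anchor values this implementation reproduces
(ideal spacing of 5 at 30×, and a one-read-length gap scoring exactly
125); the anchor values win.

**Doubled center units.** For even read lengths the center is a
half-integer. Centers are therefore carried as `start + end` (twice the
bp coordinate) and distances rescaled by ½ on conversion, keeping all
comparisons exact integer arithmetic — no floating-point ties anywhere
before the final score evaluation.

# Grouping, duplicates, phasing

**Representative groups.** Alleles with identical typing-exon sequences
are indistinguishable by any read, so they are collapsed before
placement. The representative name is the longest shared leading run of
name fields; if members share no field (which cannot happen in
IMGT-style catalogues, where names are leaves of a prefix tree, but can
in adversarial input) the lexicographically smallest member stands in
and the group is flagged. Records with different *deposited* exon
subsets never co-group: real catalogues register only exons 2–3 for many
alleles, and comparing a two-exon record with a four-exon record by
silently intersecting would hide real differences. Each group records
the exons actually used, and they are reported in the final call.

**Duplicate removal.** A candidate whose read set is a proper subset of
another candidate's is removed. The "no unique sequence block" condition
collapses into the subset relation: holding any read the superset lacks
would break the subset property. Removal is evaluated against the
original candidate set in one pass, making it idempotent and
order-invariant (both property-tested).

**Phasing.** Unique read counts are recomputed among the survivors —
counting against *all* retained candidates, not just the other finalist,
since a removed false allele may have masked uniqueness. Ranking is by
unique reads, with ties broken by total placed reads, then lower score,
then name; the tie-break chain is not part of the scientific claim, it
exists so identical inputs give identical calls. Two unique-supported
top candidates → heterozygote; one → homozygote. When *no* survivor has
unique reads (fully redundant survivors, which representative grouping
makes legitimate), the best-covered candidate is called homozygous with
a `low_confidence_no_unique_reads` flag rather than failing; the
unique-support ratio of het calls is likewise carried as a flag instead
of a hard homozygosity rule.

**Fallback exons.** The primary exons (2–3 class I, 2 class II)
sometimes lack the discriminating variant. The cascade reruns with
primary ∪ fallback exons (4–5 class I, 3–4 class II), restricted to
alleles still in contention, when either (a) more than two candidates
tie at the top of the unique-read ranking, or (b) a finalist group
contains members that differ over the fallback exons, i.e. deeper
resolution is actually attainable. Trigger (b) is the package's own
choice of what "not enough specificity" means; without it, two alleles
identical over exon 2 but differing in exon 3 would silently collapse
to a homozygous representative call even though the data can resolve
them. When the fallback pass itself produces no call, the primary call
stands.

# The simulator

The simulator exists so that every stage has a ground truth. Per gene it
draws an ancestral exon set (class I: exons 2–5 of 270/276/276/117 bp;
class II: exons 2–4 of 270/282/111 bp — typical sizes for these genes)
and mutates it into `nAlleles` variants at 2% per base, giving
inter-allele Hamming distances of a few dozen bases over the typing
region, comparable to real allelic divergence. Two structures are
engineered in deliberately because they are the algorithm's hard cases:

* an **identical-exon quartet** (four alleles, same sequences, names
  differing at the fourth field) that must collapse to a six-digit
  representative, and
* a **near-duplicate pair** at Hamming distance exactly 1 within exon 2.
  When `substitutionRate > 0` a deterministic repair step keeps every
  *unintended* pair at distance ≥ 3, so "exactly one Hamming-1 pair" is
  a guarantee, not a probability. At rate 0 no repair runs — all-equal
  catalogues are themselves a supported degenerate case (one group).

Diploid read sets draw uniform start positions over each haplotype's
concatenated exons, `depth × L / (2 × readLength)` reads per haplotype,
random strand, and independent per-base substitution errors; no indel
errors are generated because exact matching discards an error-bearing
read regardless of error type, and no PCR duplicates are generated since
duplicate-aware preprocessing is out of scope. All randomness is fixed
by seeds; equal seeds give byte-identical FASTA/FASTQ output.

**What passing synthetic tests does not show.** The simulator emulates
uniform coverage, independent errors and a modest catalogue (dozens of
alleles per gene). Real data bring coverage waves from GC and capture
bias, correlated errors, paralogous reads from HLA pseudogenes, and
catalogues three orders of magnitude larger where representative groups
and near-duplicates are far denser. Synthetic recovery rates are
therefore evidence of algorithmic correctness, not of clinical accuracy.

# Evaluation conventions

`evaluateCalls()` scores each genotype as two allele slots matched as an
unordered pair at a chosen digit resolution; a representative-level call
matches any member of its group (field-prefix agreement after
truncation). Correct + missing + wrong = 2 per genotype, always.
`depthSweep()` defines sensitivity as the fraction of true alleles
called and specificity as the fraction of non-true panel alleles not
called, at the representative level; replicates are paired across
depths by simulating once at the highest depth and taking nested random
subsets, so depth effects are not confounded with sampling noise.

Problem sizes used by the shipped suite — chosen to exercise each claim
with enough replication while keeping the whole suite under a minute:
50 diploid samples per gene at 90× for full-recovery, 12 samples × 5
genes (60 paired replicates) across 90×/60×/30×/5× for depth
monotonicity, 1,000 random center configurations for score convexity,
and 10,000 mutated reads for exactness fuzzing.

# Known limitations

* Reads spanning exon junctions of the *genomic* sequence are lost by
  design (spliced references).
* Paired-end mates are treated as independent reads; mate consistency
  is never enforced, as the score is defined over individual reads.
* Homozygote calls at low depth inherit the known weakness of
  unique-read phasing: when one true allele's reads vanish, the other
  is called homozygous with no internal evidence of the loss — hence
  the confidence flags rather than hard guarantees.
* The score constant's `L/5` rule assumes roughly uniform coverage;
  heavily biased coverage would warrant a larger `c`, which is exposed
  but not auto-tuned.
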