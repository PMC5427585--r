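# exactHLA

HLA genotyping from short sequencing reads by exact-match read placement
and read-distribution scoring.

The classical HLA genes (*HLA-A*, *-B*, *-C* class I; *-DQB1*, *-DRB1*
class II) are the most polymorphic loci in the human genome, with
thousands of catalogued alleles that often differ by a handful of bases.
Calling the two alleles a person carries from short reads is hard for
two reasons: reads with sequencing errors or from paralogous loci create
spurious support, and short reads cannot phase variants that lie further
apart than one read, so false "recombinant" alleles appear fully
supported. `exactHLA` is for anyone who needs a transparent, fully
testable implementation of an alignment-based typing algorithm —
including a bundled simulator, so every stage can be exercised without
downloading an allele catalogue or sequencing data.

## The algorithm

Per gene, against a library of allele exon sequences (class I typed
primarily on exons 2–3, class II on exon 2, deeper exons in reserve):

1. **Representative grouping.** Alleles whose typing exons are
   base-for-base identical are collapsed into one group under a
   representative name (the longest shared name-field prefix, e.g.
   `02:01:01` for `02:01:01:01…:04`).
2. **Exact placement.** Every read is placed at every position of every
   representative's typing sequence where it (or its reverse complement)
   matches with 100% identity over its full length; anything less is
   discarded. `N` never matches.
3. **Read-distribution score.** For each candidate, with sorted read
   centers `read_i = (start_i + end_i)/2` and inter-center distances
   `D_j`,

   `Score = Σ_j (D_j / c)³`, with `c = 30` for 150 bp reads.

   Evenly covered alleles score low (ideal 30× tiling puts adjacent
   centers 5 bp apart); an allele with a single uncovered read-length
   stretch (`D_j = 150`) scores 125, the default cutoff. Candidates
   scoring **above** 125 are discarded.
4. **Duplicate removal.** A candidate whose placed reads are a proper
   subset of another's has no distinguishing evidence and is removed.
5. **Phasing by unique reads.** Unique read counts (reads placed on
   exactly one surviving candidate) are recomputed; the top two
   candidates give a heterozygote call if both hold unique reads, else a
   homozygote call. If the primary exons leave the top of the ranking
   ambiguous, the cascade reruns over primary + fallback exons
   restricted to the alleles still in contention.

## Worked example

Simulate a five-gene panel (12 alleles per gene, including an
identical-exon quartet and a pair differing at a single base) and one
diploid sample at 90×, then type it:

```r
library(exactHLA)
sim <- cmdSimulate(list(out = "demo", seed = 7))
res <- cmdTypify(runConfig(alleles = "demo/alleles.fasta",
                           reads = "demo/reads_S001.fastq",
                           exonMap = "demo/alleles_exon_map.tsv",
                           out = "demo/typed"))
for (cl in res$calls) show(cl)
```

```
GenotypeCall A: A*01:01:01 [hom], unique reads 295, exons 2,3
GenotypeCall B: B*06:01 / B*08:01 [het], unique reads 158/136, exons 2,3 (unique_support=158/136)
GenotypeCall C: C*03:01 / C*01:01:01 [het], unique reads 155/144, exons 2,3 (unique_support=155/144)
GenotypeCall DQB1: DQB1*01:01:01 [hom], unique reads 94, exons 2
GenotypeCall DRB1: DRB1*02:02 [hom], unique reads 89, exons 2
```

The simulated truth for gene A was `A*01:01:01:04 / A*01:01:01:02` —
two members of the identical-exon quartet. No read can separate them, so
the call is the representative `A*01:01:01`, reported as homozygous:
exactly the collapsing behaviour step 1 exists for. Genes B and C are
heterozygous member-level pairs, recovered exactly, each supported by
>130 uniquely aligned reads. The per-stage candidate counts
(`demo/typed/log.txt`) show the cascade narrowing 9 representative
groups to the final one or two calls per gene.

Command-line wrappers for the same three entry points live in
`inst/exec/` (`typify.R`, `simulate.R`, `evaluate.R`).

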