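# methsuite

Joint genetic and epigenetic inference from bisulfite (and enzymatic)
conversion sequencing, in one R package: a conversion-aware read aligner, a
pileup caller that genotypes SNPs and quantifies cytosine methylation from
the same observations, conversion-rate QC, a read-level run-length-encoded
output format for allele-specific methylation analysis, and a paired-end
read simulator with full truth tables.

It is written for methylation bioinformaticians who want a transparent,
testable implementation of the whole WGBS inference stack at desk scale —
every stage is an exported, documented R function operating on ordinary
data.tables, and every stochastic step is seeded.

## The methods in brief

**Alignment.** The reference is packed 2-bit (`pack_reference()`) and
indexed twice (`build_converted_index()`): a *C-less* FM-index over the
forward+reverse concatenation with every C converted to T, and a *G-less*
index with every G converted to A. The two indexed sequences are exact
reverse complements of one another, so plain backward search on both
covers both search directions. Reads are in-silico converted the same way,
seeded by maximal exact matches (>= 19 bp), checked against the 4-base
reference, chained by genomic proximity, and extended against the original
4-base reference with an **asymmetric substitution score**:

```
s(ref, read) = +1  if ref == read
             = +1  if ref = C, read = T   (C->T strands: OT/CTOT)
             = +1  if ref = G, read = A   (G->A strands: OB/CTOB)
             =  0  if either base is N
             = -4  otherwise               (including read C over ref T!)
```

with affine gaps (a k-gap costs 6 + k). Equally optimal placements get
MAPQ 0; otherwise MAPQ = round(60 (S1 − S2)/S1). The conversion strand is
reassessed from the alignment's own C/T vs G/A evidence after mapping.

**SNP + methylation calling.** Pileup base support uses the six-letter
alphabet {A, C, G, T, R, Y}: a read T on a C->T strand is recorded as Y
(could be a converted C), a read A on a G->A strand as R. Y support is
redistributed to {C, T} by four rules (unambiguous evidence for one base;
evidence for both; no evidence and non-C/T reference; no evidence and C/T
reference), R mirror-wise over {A, G}; genotypes then come from a Bayesian
model over the 10 diploid states with per-read likelihood

```
P(b | g) = (1 - c) * [ (1-e) or e/3 mixed over g's alleles ] + c * P(b | ref)
```

(e = sequencing error, c = contamination, priors from the polymorphism
rate theta). Methylation is counted on the informative strand only
(C->T-strand reads inform reference C's, G->A-strand reads reference G's),
split by context — CpG, and CpA/CpC/CpT separately — with NOMe-seq
handling (HCG methylation, GCH accessibility, GCG excluded, CCG flagged).

**epiBED.** Each read (or merged mate pair — overlap-aware, never double
counted) becomes one BED row with run-length-encoded per-position states
(`M`/`U`/`F`/`D`/`x` plus observed SNP bases, `Y`/`R` when conversion makes
the call ambiguous), convertible to a read-by-CpG matrix and a Fisher
exact allele-specific methylation test.

**QC.** Retention by context with per-cycle M-bias arrays; the CpC+CpT
pool estimates the background non-conversion rate, an elevated CpA level
flags genuine CpA methylation, and reads with extensive conversion failure
can be filtered.

## Worked example

```r
library(methsuite)

cfg <- sim_config(genome_length = 20000, depth = 30, rng_seed = 7)
sim <- run_simulation(cfg)                 # genome + SNPs + methylome + reads

packed  <- pack_reference(sim$ref)
indexes <- list(C_LESS = build_converted_index(sim$ref, "C_LESS"),
                G_LESS = build_converted_index(sim$ref, "G_LESS"))
recs <- align_pairs_table(sim$reads$r1, sim$reads$r2, indexes, packed)
recs <- mark_duplicates(recs)
sum(!bitwAnd(recs$flag, 4L))               # 6000 of 6000 records mapped

obs  <- pileup(recs, packed)               # filtered, mate-overlap-deduped
meth <- meth_table(obs, packed)
meth[context == "CpG"][1:3]
#>    contig   pos strand context   flag     M     U      beta
#> 1:   chr1    73      +     CpG            1     6 0.1428571
#> 2:   chr1    74      -     CpG            4     2 0.6666667
#> 3:   chr1   131      +     CpG            3     6 0.3333333

gt <- call_genotypes(obs, packed)
gt[!is.na(gt) & gt != paste(ref, ref, sep = "/")][1:3]
#>    contig   pos    ref     gt       gq    dp            sp
#> 1:   chr1  2619      G    C/G 99.00000    29  0:7:11:0:7:4
#> 2:   chr1  3079      G    A/A 91.32345    32 16:0:0:0:16:0
#> 3:   chr1  3612      T    C/T 34.43976    13  0:4:0:9:0:13
```

`beta = M/(M+U)` is the per-cytosine methylation fraction (73/74 are the
two strands of one CpG, noisy at this depth); `sp` is the six-letter
support `A:C:G:T:R:Y` — at chr1:2619 the 7 R observations are A's on G->A
strands that the reduction rules resolve using the unambiguous C and G
counts. All 18 planted SNPs are recovered at 18 called variant sites here
(`filter_variants()` adds the two-tier GQ filter with a common-SNP track).

```r
prof <- retention_by_context(recs, packed)
prof$by_context
#>    context retained total  retention
#> 1:     CpG    19592 26698 0.73383774
#> 2:     CpA      729 36579 0.01992947
#> 3:     CpC      521 26631 0.01956367
#> 4:     CpT      762 36398 0.02093522
infer_conversion_background(prof)$rate    # 0.0204 ~ 1 - conversion_rate
```

A command-line wrapper with `index`, `align`, `pileup`, `vcf2bed`,
`filter-snps`, `epibed`, `asm`, `qc` and `simulate` subcommands is
installed at `inst/cli/methsuite` (see `ms_main()`).

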