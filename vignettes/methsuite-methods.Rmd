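---
title: "methsuite: models, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methsuite: models, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what is being
modelled, the choices made where the design was genuinely open, the
numerical conventions, and what the tests do and do not demonstrate.

# The inference problem

Bisulfite (or enzymatic) conversion turns unmethylated cytosine into
uracil, read as T after amplification; methylated cytosine stays C. A
sequenced fragment therefore carries two confounded signals: genetic C/T
(and G/A) differences and epigenetic conversion. The package treats the
two jointly at every stage — alignment tolerates conversion asymmetrically
instead of degrading the reference to three letters, and the caller keeps
conversion-ambiguous base observations in a separate symbol class instead
of discarding or miscounting them.

## Strand bookkeeping

A fragment comes from one of four strand identities: the original top (OT)
or bottom (OB) strand, or their PCR complements (CTOT, CTOB). In
forward-reference coordinates the OT/CTOT pair shows conversion as
reference-C/read-T and the OB/CTOB pair as reference-G/read-A; this
"conversion class" (C2T vs G2A) is what scoring, pileup and methylation
extraction condition on. The mapping between search space and tag is fixed
by chemistry: a C-to-T-converted read searched in the C-less index hits
the forward strand part as OT and the reverse part as OB; a G-to-A
converted read in the G-less index hits CTOB (forward) and CTOT (reverse).
Directional libraries constrain mate 1 to {OT, OB} and mate 2 to
{CTOT, CTOB}; non-directional mode searches all four hypotheses for both
mates. After mapping, the strand tag is re-derived from the alignment's
own evidence (counts of ref-C/read-T versus ref-G/read-A pairs); ties,
including reads covering no cytosines, keep the seeding tag and are
flagged ambiguous.

# Indexing and search

Both FM-indexes cover the same text: the contigs joined with a
never-matching junction symbol, concatenated with the reverse complement
of the whole joined sequence, each strand converted *after* reverse
complementing. With the junction symbol self-complementary, the two
converted strand sequences are exact reverse complements of one another
under A<->T, C<->G, which is what makes plain backward search on the two
indexes equivalent to one bidirectional search — the simpler mechanism was
chosen deliberately; the result set is identical.

Numerical conventions:

* Sentinels: the inter-strand separator `!` and terminal `$` sort before
  all bases; reference N and contig junctions become a symbol `X` that no
  pattern symbol ever equals, so seeds cannot cross an N run or a contig
  boundary. Read Ns map to a pattern-only code that matches nothing.
* The suffix array is built by prefix doubling (robust on the repetitive
  references used in the duplicated-locus tests), sampled at spacing 4;
  occurrence counts are checkpointed every 64 BWT positions. Both
  spacings are configurable and provably do not affect query results
  (tested over spacings {1, 4, 32}).
* Seeding is greedy: repeatedly take the longest exact suffix match
  ending at the cursor (via backward search), record it if it reaches
  `min_seed_len` (default 19), and continue left of it. This yields the
  whole read as one seed for error-free reads and splits at mismatches.

# Alignment scoring

Defaults are BWA-MEM-like, since the aligner family this design follows
is BWA-MEM-based: match +1, mismatch −4, gap open 6, gap extend 1 (a
k-long gap costs 6 + k), band half-width 100. The asymmetric substitution
score treats the strand-appropriate converted pair (ref C/read T on C2T;
ref G/read A on G2A) as a full match and everything else as a mismatch;
N scores 0. Consequences that the tests pin down:

* a fully converted read scores identically to its unconverted original
  at the true locus;
* the *reverse* substitution (read C over reference T) is penalized like
  any mismatch, which is the genetic signal that three-letter aligners
  lose;
* the conversion-aware edit distance NM excludes tolerated conversions
  (they are counted separately in the ZC tag), so NM remains a genetic
  distance.

Extension first attempts gap-free scoring on the chain diagonal and falls
back to a banded affine-gap Smith-Waterman against the 4-base reference;
read ends that do not improve the local optimum are soft-clipped. The
4-base compatibility filter orders chain visiting rather than vetoing
reads: when too few chains pass (for example a sequencing-error C inside
an otherwise perfect seed fails the strict asymmetry check), chains built
from non-conforming seeds are still visited up to `max_total_chains`, and
the extension DP adjudicates. Candidates that share a placement but differ
only in strand hypothesis are collapsed before MAPQ counting; otherwise
any read without cytosine evidence would tie with itself and be reported
MAPQ 0.

MAPQ is `round(60 (S1 − S2)/S1)` clamped to [0, 60], with the hard rule
that two or more equally optimal placements give exactly 0, and S2 = 0
for unique hits. The formula is a package convention: it is monotone in
the score gap and reproduces the tie rule, which is the only printed
constraint in the method family this implements. Ties everywhere are
broken deterministically (score desc, contig order, coordinate, tag), so
alignment is reproducible without any random state.

Pairing adds a flat bonus (default 10) to forward/reverse combinations
whose implied insert lies within mean ± 4 sd; mates are never forced into
a pair — chimeric inserts (supported by the simulator's `chimera_rate`)
are reported at each mate's own best placement with the proper-pair flag
unset. Duplicate marking uses only coordinates (contig, unclipped 5'
position of each mate, orientation, conversion class) plus total base
quality for survivor choice, so conversion-pattern differences cannot
split a duplicate group.

# The joint caller

## Six-letter support and reduction

Per-site counts live over {A, C, G, T, R, Y}: Y is a read T on a C2T-class
read (possibly a converted C), R a read A on a G2A-class read. The
reduction to four letters implements exactly four rules (shown for Y; R is
the mirror over A/G): add Y to C or T when unambiguous evidence supports
exactly one of them; ignore Y when both are supported; ignore Y when
neither is supported and the reference is not C/T; add Y to the reference
when neither is supported and the reference is C or T. "Unambiguous
evidence" means at least one read (configurable) of a letter that cannot
be a conversion artifact. Mass is never created: the reduced total lies
between the unambiguous total and the full six-letter total.

## Genotype model

The likelihood of an observed base b under genotype g = {a1, a2} is a
contamination mixture

P(b | g) = (1 − c) · [½ p(b|a1) + ½ p(b|a2)] + c · p(b|ref),
p(b|a) = 1 − e if b = a else e/3,

with defaults e = 0.005, c = 0.01, θ = 10⁻³ (package conventions,
user-settable). The prior puts 1 − 3θ/2 on hom-ref, θ split uniformly over
the six heterozygotes and θ/2 split over the three hom-alts, which sums to
one. GQ is −10·log₁₀(1 − posterior of the argmax), capped at 99. Zero
post-reduction depth yields a missing call. The exact likelihood of the
original tool is not published in the sources this package follows; the
mixture above is this package's declared convention and is tested against
direct numeric evaluation of all ten posteriors.

An intrinsic asymmetry follows from the conservative reduction: C/T and
G/A heterozygotes are supported by only the unconfounded strand class
(half the depth), so their recall is bounded by that of other het classes.
The end-to-end test asserts this ordering rather than hiding it.

## Methylation extraction

Retained (C) versus converted (T) is counted on the informative strand
only; contexts come from the 4-base reference (next base for a + strand
cytosine, complemented previous base for a − strand one). CpH is split
into CpA/CpC/CpT throughout. For NOMe data, HCG sites feed the endogenous
methylation channel, GCH sites the accessibility channel, GCG sites are
excluded as intrinsically ambiguous, and CCG sites are *kept but flagged*
(the off-target GpC-methyltransferase effect is small, so dropping half of
all CCGs by default would cost more than it saves; the flag makes post-hoc
filtering one subset call).

Mate overlap is resolved before counting (higher base quality wins, ties
to mate 1), so overlapping mates contribute at most one observation per
position in both the pileup and the epiBED path.

## Variant filtering

The post-hoc SNV filter drops GQ ≤ 5, hom-ref and non-canonical-contig
calls, removes calls inside an exclusion track, then applies the two-tier
rule: calls intersecting a common-SNP interval with MAF ≥ 0.05 need
GQ ≥ 15, all others GQ ≥ 60. Tracks are plain BED (MAF in column 4),
matched with GenomicRanges.

# epiBED dialect (version 1.0)

One row per read or merged molecule: chrom, 0-based start, half-open end,
read name, mate (1/2/M), strand tag, RLE methylation string, RLE variant
string, RLE accessibility string (NOMe; "." otherwise), insertion side
field (`refpos:seq`, `;`-joined). RLE runs are count+symbol (`2x1M3x`);
decoded length must equal the span, and the reader enforces this.
Methylation alphabet: M retained, U converted, F filtered (low quality or
mate conflict), D deletion, x uninformative. Variant alphabet: the
observed base at supplied SNP sites, with Y/R substituted when the read's
conversion class makes the call ambiguous. Merging unites spans, keeps
agreeing states once, turns disagreeing M/U into F, and fills the
inter-mate gap with x; it is commutative because the lower-start record is
always placed first. How the original tool encodes insertions is not
documented; the side-field convention is this package's choice.

# The simulator

The generator is the package's ground-truth harness. Its defaults *are*
the design conditions of the recovery tests: 100 kb genome, GC 0.42,
SNP rate 10⁻³ (het fraction 0.5), CpG methylation mean 0.7, CpH 0,
conversion 0.98, error 10⁻³, 2×100 bp reads at 30× with 300 ± 30 inserts,
directional. Two scientifically motivated choices fixed at design time:

* **Bimodal methylomes.** Per-cytosine betas are Beta(mα, m(1−α))-style
  draws with concentration 0.5, because real CpG methylomes are strongly
  bimodal; a unimodal methylome at mean 0.7 would make per-site beta
  estimation at 30× dominated by binomial noise and would not resemble
  tissue data.
* **Strand-symmetric CpGs.** Both cytosines of a CpG share one beta
  (maintenance methylation), so the two strands of a CpG estimate a
  common quantity and per-CpG evaluation pools them.

What it emulates: diploid substitution SNPs on two haplotypes, molecule-
level Bernoulli(beta) methylation, per-cytosine conversion on the
molecule's own strand sense, all four strand identities (uniformly in
non-directional mode), i.i.d. sequencing error, chimeric mate-2 inserts,
and exact-copy duplicate injection. What it deliberately does not emulate:
indels (the extension DP is oracle-tested directly instead), PCR bias and
coverage waviness, quality-score decay along the read, context-dependent
error, overlapping-error correlation, and SNP-context interactions beyond
treating haplotype-created cytosines as unmethylated. Passing the recovery
suite therefore demonstrates correctness of the inference machinery under
a clean generative model, not robustness to every artifact of real
libraries.

Reproducibility: each stage seeds its own stream deterministically from
`rng_seed` (genome, methylome, reads at +0, +1, +2), and identical
configurations produce byte-identical FASTQ and truth tables.

# QC design

The background non-conversion rate is the pooled CpC+CpT retention with a
binomial confidence interval — pooling, rather than a model fit, is the
declared convention. The CpA-methylation flag fires when CpA retention
exceeds the background by more than chance *accounting for the binomial
error of both estimates* (one-sided two-proportion z at α = 10⁻⁴). The
strict α was a design-time power calculation: at the scales the flag is
meant for (thousands of CpA observations), genuine CpA methylation of a
few percent sits tens of standard errors above a 2% background, so
sensitivity is unaffected, while a looser rule that ignores the CpA
sampling error would false-alarm on a few percent of clean runs. The
conversion-failure read filter removes reads with ≥ 3 CpH cytosines of
which more than 2 are retained — thresholds are package conventions
(configurable), since only the filter itself, not its cutoffs, is
specified in the method family.

# Coordinates

All in-memory tables use 1-based inclusive coordinates, the R/Bioconductor
convention (GRanges, Biostrings); 0-based half-open coordinates appear
exactly twice, at serialization boundaries: BED/epiBED output and
FM-index text offsets. SAM output is 1-based as required.

# Problem sizes used by the test suite

Chosen as desk-scale package defaults: FM-index oracle equivalence on 20
random genomes of 1.5–4 kb with 1,000 patterns each against a
Biostrings-based naive scan; extension versus an exhaustive R dynamic
programming oracle on 500 random ≤ 80 bp windows including planted 1–3 bp
indels; the conversion-parity property on 1,000 simulated reads; the
end-to-end recovery run at the full 100 kb × 30× design point; QC flag
behaviour over 100 seeded 10 kb runs per condition; epiBED identity on
10,000 aligned reads. The whole suite runs in several minutes on one CPU.

# Known limitations

Single-threaded, in-memory, desk-scale: the naive-sorted suffix array and
R orchestration target genomes of megabases, not gigabases. No indel
*calling* (alignment handles indels; the caller genotypes substitutions
only), no somatic mode, no structural variants, no legacy epiread/
epiallele formats, no spike-in control handling (running the QC on a
designated control contig is equivalent), and the command-line layer is a
thin wrapper over the exported functions rather than a streaming pipeline.
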