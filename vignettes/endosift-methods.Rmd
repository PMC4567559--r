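---
title: "Recovering endosymbiont genomes from mixed host libraries: methods and design"
author: "endosift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering endosymbiont genomes from mixed host libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Obligate intracellular symbionts such as *Blattabacterium cuenoti* (the
bacteriocyte symbiont of cockroach fat bodies) cannot be cultured, and
their cells are rarely separated cleanly from host tissue. Shotgun
sequencing of crude tissue DNA therefore yields a mixture in which the
symbiont may contribute anywhere from a few percent to a third of the
reads ("purity"), alongside host nuclear DNA, the host mitochondrion and
highly expressed host rRNA genes. endosift implements a two-stage strategy
for recovering the symbiont chromosome from such a library without any
physical enrichment:

1. **TCSF** (translated contig selection and filtering): assemble the
   whole library de novo, keep contigs whose six-frame translation hits a
   related reference genome at `E < 1e-12`, and evict contigs whose best
   bit score against a mitochondrial or host-rRNA decoy exceeds their best
   reference score. The premise is that a reduced symbiont genome is a
   conserved gene subset of its free-living relatives: amino-acid
   similarity persists long after nucleotide similarity has decayed, so a
   translated search tolerates reference genomes from a different family,
   class, or even phylum.
2. **IMRA** (iterative mapping and reassembly): map *all* reads single-end
   onto the selected contigs, rescue every pair with at least one Full or
   Partial mate, reassemble the rescued pairs from scratch in paired-end
   mode, discard contigs shorter than 500 nt, and repeat until the contig
   count and total length saturate. Reassembly from a cleaned read pool
   removes branch points caused by foreign reads (debranching) and lets
   unmapped mate ends extend contigs into gaps (elongation).

The package also ships the measurement layer used to validate the
strategy: truth-labelled simulation, length-weighted TP/FN/FP selection
scoring, genome fraction, NGA50 and purity estimation.

## Pipeline stages and their parameters

### Read quality control

`filterPairs()` applies the stringent Illumina recipe: 3' bases with
Phred score < 27 are trimmed (`trimQ`), then reads with post-trim mean
quality < 27 (`minMeanQ`) or length < 80 nt (`minLen`) are discarded, and
pairs that lost a mate are removed. All comparisons are strict (`<`), so a
read of exactly 80 nt with mean exactly 27 survives. The mean is computed
on the post-trim read, which is the order the rule implies. Filtering is
idempotent.

### The overlap-layout-consensus assembler

`assembleReads()` is a greedy OLC assembler in the spirit of the
low-coverage-friendly assemblers traditionally used for this problem.
Its two user-facing stringency knobs are shared with the read mapper:

* `minOverlapIdentity` (`mi`, percent, default 90) and `minOverlapLen`
  (`ml`, nt, default 40) - parameter set A is 90/40, set B is 85/35, and
  an `ml = 45` variant is supported;
* `minContigLen`: 100 nt for the initial de novo assembly, 500 nt inside
  IMRA.

Internals, fixed for determinism:

* **Overlap discovery** anchors on each read's leading 21-mer plus a
  second 21-mer at a fixed interior offset; an overlap `a -> b` is
  discoverable when one of b's anchors occurs exactly in `a`. Under the
  substitution-only error model, candidate overlaps are verified by
  Hamming comparison on the implied diagonal. The two-anchor scheme keeps
  the probability that a sequencing error hides a true neighbour below
  about 1%.
* **Layout** is a successor election: each unambiguous read end claims its
  best (longest, then fewest mismatches, then smallest id) qualifying
  extension, and each claimed read accepts its best claimant, so the
  layout decomposes into disjoint paths. An end with two qualifying
  extensions whose extension sequences disagree (three or more mismatches
  in any six-column window - dense disagreement, which sparse sequencing
  errors do not produce) is a branch point and stops extension; this is
  what fragments assemblies at exact repeats.
* **Consensus** is per-column majority vote (ties break to the
  alphabetically first base).
* **Shadow removal**: reads whose discovery edges were lost start
  redundant parallel paths; any contig whose span aligns inside a longer
  contig at the overlap identity (allowing a 10 nt overhang) is removed
  and its reads transplanted onto the host contig.
* **Pair joining** (paired-end mode): contig ends linked by at least 3
  pairs with a consistent implied gap (within four insert standard
  deviations of the median) are joined when the ends share a verified
  exact overlap of at least 10 nt. No N-gaps are ever emitted. Circular
  sources assemble into a linear contig; a terminal self-overlap is
  reported as a `circular` flag but the ends are not auto-joined.

`mapReads()` classifies each read against its best contig position:
`Full` when the alignment covers the whole read at `mi`, `Partial` when it
covers at least `ml` read bases (a read overhanging a contig end, or a
locally diverged read), `Unmapped` otherwise. Ties break to the
lexicographically smallest contig, then the leftmost position.

### The homology search engine

`searchHits()` is a seed-and-extend local aligner with two modes:

* *translated* (the TCSF mode): all 36 frame pairs of a six-frame x
  six-frame search, BLOSUM62, gap open 11 / extend 1, word size 4;
* *nucleotide*: strand x strand, match +2 / mismatch -3, gap open 5 /
  extend 2, word size 16.

Exact word seeds are extended ungapped under an X-drop; promising HSPs are
re-scored by a windowed Smith-Waterman-Gotoh with traceback, so every
reported hit's score equals the optimal local alignment score of its
reported span (the band covers the whole window whenever the window is
small; long near-identity nucleotide hits use a 16-diagonal band, which is
exact for the substitution-only regime). Raw scores convert to bits via
fixed Karlin-Altschul constants (BLOSUM62 gapped: lambda 0.267, K 0.041;
+2/-3: lambda 0.625, K 0.41) and `E = m n 2^(-bits)` with `m`, `n` the
query and total subject nucleotide lengths; no effective-length correction
is applied. E-values therefore approximate BLAST's - the contract is
threshold behaviour at `E < 1e-12`, not E-value parity. `keepBestOnly`
reduces to one hit per query (max bit score, then lower E, then
lexicographically smaller subject id).

### Selection and decoy filtering

`selectContigs()` drops contigs without any reference hit below the
E-value ceiling, then compares each survivor's best *bit score* against
the reference with its best translated hit against the mitochondrial
decoy and best nucleotide hit against the host rRNA decoy; a strictly
better decoy score evicts the contig, and ties retain it (sensitivity is
favoured because false negatives cannot be recovered downstream, while
occasional false positives are suppressed by IMRA's length cutoff). Bit
scores are used as the comparator because they are independent of search
space size. Multi-record references are allowed; the best hit across
records counts.

### IMRA

`imraIterate()` loops map -> recruit -> reassemble -> filter. Saturation
is declared when the contig count is unchanged and the total length moves
by at most `saturationLenTol` (default 0 nt) for `saturationWindow`
(default 2) consecutive iterations; a single-contig fixed point stops
immediately; `maxIter` (default 30) caps the loop and flags
non-convergence. The returned assembly is the best iteration: fewest
contigs, then largest total length, then earliest. Reassembly is from
scratch each iteration from the recruited pairs - not incremental contig
extension - which is what heals mis-joins and removes debris. The contig
length cutoff (default 500 nt) is applied after every reassembly, before
the next mapping round; because a contig seeded by foreign reads can grow
by at most roughly one insert length per iteration, a cutoff above twice
the mean insert size (500 > 2 x 230) prevents contaminant fragments from
ratcheting upward. Choosing a cutoff below twice the insert mean triggers
a warning; the strict 1000 nt option purges even ~500 nt contaminant
seeds.

## The synthetic study system

`makeGenomeSet()` + `simulateLibrary()` emulate the structure of a
fat-body shotgun library at an adjustable scale (default 50 kb target,
scaled down from the real ~0.64 Mb chromosome):

* **Target**: circular, AT-rich (GC 0.26), >= 80% coding; ORFs are drawn
  codon-wise under the genome-wide AT bias with no internal stops, plus
  one conserved non-coding rRNA-family region (~1.5 kb).
* **Reference panel**: one genome per amino-acid divergence `d`
  (defaults 0.02, 0.17, 0.21, 0.26, emulating a same-species strain
  through a different-phylum free-living relative). Each reference keeps
  the target's gene complement; peptides are mutated at rate `d` with a
  similarity-biased substitution scheme, then back-translated under the
  *reference's own* codon bias, with GC raised along the divergence
  gradient (free-living relatives of this clade run 34-44% GC against the
  symbiont's 26%). Intergenic DNA is fully randomized and the rRNA region
  diverges at 0.8 d. This is the core of the study system: amino-acid
  identity decays as `1 - d` while coding nucleotide identity collapses
  much faster, which is exactly the asymmetry TCSF exploits.
* **Host**: random 40% GC DNA with one embedded host rRNA copy (70%
  identity to the target's rRNA region - conserved enough to retrieve
  reference hits, which is why the rRNA decoy filter exists).
* **Mitochondrion**: AT-rich, carrying one degenerate copy (~60%
  amino-acid identity) of a target gene, exercising the mitochondrial
  decoy filter.
* **Contaminant** (optional): a 16S-like fragment at 85% identity to the
  target rRNA region - close enough to the conserved family to be kept by
  selection (a false positive, as observed with environmental *Serratia*
  16S contamination) but too diverged (85% < 90% mapping identity) for
  its reads to elongate target contigs.
* Constructed homologs are post-processed so no 60-nt window reaches 95%
  identity to the target (chance windows at 85% identity are otherwise
  common); violating windows receive extra substitutions.
* **Library**: target pairs number `round(depth x L / (2 x readLen))`;
  total pairs are `targetPairs / purity`; the non-target remainder splits
  host : mito : rrna : contaminant = 0.90 : 0.07 : 0.02 : 0.01 by default
  (the real host/mito composition of such libraries is not documented, so
  these are exposed as configuration). Inserts are Normal(230, 25)
  truncated to [readLen, 3 x mean]; errors are i.i.d. substitutions at
  0.002/base; a configurable ~4% of reads receives qualities that fail
  the Q27/80-nt rule, half through low-quality 3' tails and half through
  borderline mean quality.

Everything is deterministic given the scenario seed.

### What the simulation does and does not show

The generator reproduces the *compositional* structure of the real
problem - purity, depth, divergence gradients, decoy homologies, a trace
contaminant - but not read-level realism: no indels, no position-dependent
Illumina error profiles, no PCR duplicates or chimeras, no genomic
repeats beyond chance, and uniform coverage. Consequences worth knowing:

* Clean uniform 20x coverage assembles the 50 kb target into one or two
  contigs straight away, so at that depth IMRA converges almost
  immediately and both selection modes keep everything. The behaviours the
  strategy was designed for - fragmented assemblies, iterative elongation,
  the translated-vs-nucleotide sensitivity gap - appear at the shallow
  (~10x) end of the realistic depth range, and that is where the package's
  mode-contrast checks run. On real data, repeats and coverage bias
  produce fragmentation at much higher depth.
* Passing tests demonstrate the algorithms' contracts, not performance on
  real tissue libraries.

## Evaluation metrics

`assignOrigin()` labels a contig `target` when an alignment covering at
least 95% of the contig (both strands; circular rotations of the target
considered) has identity above 99.0%. The identity threshold alone would
let a short perfect island mislabel a chimera, hence the coverage clause.
In selection scoring, kept contigs assigned to another genome count as
false positives, as do kept unassignable contigs whose strongest
sub-threshold alignment evidence is not the target; an unassignable contig
whose best evidence *is* the target (typically a short 1x-coverage contig
whose consensus errors land it just under 99% identity) is charged to
neither side. At 50 kb scale a single consensus error moves a 100-nt
contig's identity by a full percent, so this distinction is what keeps the
false-positive ledger meaningful. `genomeFraction()` counts each
covered target position once; `nga50()` is the largest block length L
such that reference-aligned blocks of length >= L sum to at least half
the target length, reported as 0 with a `defined = FALSE` attribute when
coverage is below 50%. Alignment blocks come from anchored near-identity
diagonal runs (exact for the substitution-only regime); a chimeric contig
contributes only its aligned blocks. `estimatePurity()` maps all reads
against the target and reports the Full/Partial percentage next to the
truth-label purity.

## Numerical and policy choices

* Coordinates are 0-based half-open throughout; minus-strand genes store
  `start < end` plus a strand flag.
* All tie-breaks (overlap choice, claims, best hits, contig naming) are
  fixed and lexicographic, so every stage is deterministic under a fixed
  seed and input order.
* Degenerate inputs: empty read sets assemble to an empty Assembly; an
  empty reference is an error; missing decoys skip that filter with a
  warning; empty seed contig sets abort IMRA with an explicit error; zero
  recruited pairs stop the loop with a warning.
* Problem sizes in the shipped tests are the scaled-down study
  conditions: a 50 kb target with a 250 kb host sample at the two
  published purities (28.5% and 2.4%) and depths of 6-20x. These sizes
  keep full five-seed study replicates tractable on a laptop while
  preserving every qualitative behaviour of interest.

## Known limitations

* The aligner has no composition-based statistics, masking, or HSP
  chaining; E-values are approximations with fixed Karlin-Altschul
  constants.
* The assembler and mapper assume substitution-dominated differences; an
  indel-rich library would need banded verification throughout (the
  option exists structurally but defaults to the diagonal case).
* Circular genomes are emitted as linear contigs with a circularity flag;
  terminal redundancy is not trimmed, so a completed circular target can
  legitimately appear as one contig slightly longer than the genome, or
  as a main contig plus one short origin-spanning fragment.
* Purity estimation counts Full/Partial mappings at the default
  stringency; highly diverged relatives of the target would be counted
  against it on real data.
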