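---
title: "Consensus repeat construction from short reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus repeat construction from short reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repcon)
```

## The problem

Transposable elements and other interspersed repeats make up large fractions
of most eukaryotic genomes, yet the standard annotation tools all presuppose
either a good reference assembly or a curated repeat library. For species
with neither — highly repetitive genomes, newly sequenced non-model
organisms — the repeat library has to come from the reads themselves.

`repcon` reconstructs *consensus* repeat sequences directly from unassembled
short reads. The driving observation is spectral: a repeat family with $c$
near-identical copies contributes each of its k-mers about $c$ times the
k-mer depth of a single-copy locus, so repeat-derived k-mers separate from
the bulk of the k-mer frequency spectrum. Assembling only those k-mers
yields the family consensus without ever assembling the genome.

The hard cases are *diverged* and *low-copy* families. When copies differ
from their consensus at rate $d$ per base, a k-mer straddling any mutated
position is private to one copy, so the fraction of consensus k-mers seen
intact in a given copy is $(1-d)^k$ — at $k = 30$ and $d = 0.08$ only about
8%. Frequency alone then misses most of the family, and assembly of the
surviving k-mers fragments at every variant position. The two ideas at the
core of this package address exactly that regime: **recruitment** of
intermediate-frequency k-mers by similarity to the highly frequent ones, and
randomized **polishing** of the recruited set into consensus k-mers before
assembly.

## Pipeline and model

### Counting and tier classification

`count_kmers()` counts canonical k-mers (a word pooled with its reverse
complement under the lexicographically smaller key; reads come from both
strands, so strand-resolved counting would halve every signal — forward-only
counting remains available via `canonical = FALSE`). Windows containing
non-ACGT characters are skipped rather than erroring, since real FASTQ
contains Ns.

The tier cutoffs are multiples of the **base frequency** $f_0$, the k-mer
depth of a single-copy locus. For reads of length $L$ at coverage $D$,
$f_0 \approx D\,(L-k+1)/L$. `estimate_base_freq()` recovers it as the mode
of the k-mer frequency histogram after excluding bins below a minimum count
(default 2): sequencing errors produce a large spike of count-1 k-mers, and
the next peak sits at the single-copy depth. Users with a known read depth
can set `base_freq` directly; the two notions coincide up to the
$(L-k+1)/L$ factor, and a single user-overridable scalar serves both roles.

`classify_kmers()` splits the table at two inclusive lower bounds:

* **highly frequent**: count $\ge$ `high_multiplier` $\times f_0$
  (default 10) — near-certainly repeat-derived;
* **intermediate**: count $\ge$ `mid_multiplier` $\times f_0$ (default 3)
  but below the high cutoff — enriched for diverged-repeat k-mers, but
  mixed with fluctuation noise.

Everything below the intermediate cutoff is discarded: k-mers from highly
divergent repeat regions still tend to sit above the average depth, and
dipping further down would mostly admit background and error k-mers.

The high multiplier can be read as a target copy number. The defaults suit
abundant families; for diverged, low-copy targets (around ten copies at
5–10% divergence) the package's *diverged preset* drops the cutoffs to
`high_multiplier = 2`, `mid_multiplier = 1.3` and uses two recruitment
rounds, because at 8% divergence a consensus 30-mer is shared intact by
two or more copies at only a third of positions, and the single-copy tier
carries most of the remaining signal.

### Recruitment

A diverged-copy k-mer is usually within a few edits of some highly frequent
k-mer. `recruit_kmers()` therefore keeps an intermediate k-mer when it

1. shares an exact seed of length `seed_len` (default 12) with some highly
   frequent k-mer (queries are tried in both orientations), and
2. reaches an alignment score of at least `min_score` (default $k-5$)
   against such a k-mer.

The score is the *match-only* optimal alignment score — matches reward 1,
mismatches and gaps cost nothing — which equals the longest-common-
subsequence length; `min_score` $= k-5$ thus tolerates five unmatched bases,
including small indels. Alignment is always against one k-mer at a time,
never across a concatenation of k-mers, so a spurious junction can never
qualify a query. For at most one edit the seed filter is lossless whenever
`seed_len` $\le \lfloor (k-1)/2 \rfloor$ (pigeonhole); the defaults satisfy
this with room to spare.

`iterative_recruit()` optionally repeats the step, aligning the remaining
intermediate k-mers against everything recruited so far. Each extra round
reaches further into the divergence tail at some false-positive cost; one
round is the default and the diverged preset uses two.

### Randomized polishing

The recruited set contains many slightly different versions of the same
underlying repeat position. Before assembly, `polish_kmers()` collapses them
onto consensus k-mers.

Two k-mers are *end-to-end matched* when they agree at a random sample of
$h$ of the $k$ positions. Per trial, one shared position subset is drawn for
the whole table and every k-mer is bucketed by the extracted h-mer; two
k-mers sharing a bucket in at least one of $n$ trials are linked. For a pair
within edit distance $e$ (differing at $e$ positions), a single trial
matches exactly when the sample avoids all $e$ positions, so

$$p \;=\; 1-\left(1-\frac{\binom{k-e}{h}}{\binom{k}{h}}\right)^{\!n},$$

evaluated exactly via
$\binom{k-e}{h}/\binom{k}{h} = \prod_{i=0}^{e-1}\frac{k-h-i}{k-i}$
(each factor a ratio of small integers, so the double-precision product is
exact over the supported domain; the ratio is 0 when $h > k-e$). The default
$e = 1$ tolerates one mismatch or a one-base shift; k-mers offset by an
insertion or deletion appear as distinct words that are themselves
end-to-end matched with their counterparts, so indels need no special
handling. The default trial count is the smallest $n$ for which
$p \ge 0.99$ at the configured $(k, h, e)$ — 7 trials at the default
$k = 30$, $h = 15$.

Sharing one position subset per trial across the whole table is what makes
the scheme practical: the pairwise matching probability above is preserved
exactly (for substitution-type differences), while bucketing by exact h-mer
replaces an infeasible all-pairs comparison with near-linear hashing work.
Linked pairs are merged transitively into connected components.

Each group is then replaced by its **weighted-vote consensus**: at every
position each member votes its base with weight equal to its count, the
winning base is taken (ties break to the alphabetically smallest base, for
determinism), and the consensus count is the maximum winning vote over
positions. Colliding consensus words pool by summing counts. Execution can
be partitioned by trial bucket (`n_partitions`), but all links feed one
global union-find, so the output is bit-identical for every partition count
— partitioning is a scheduling choice, never a semantics choice.

### Assembly and merging

`assemble_contigs()` is a native de Bruijn unitig assembler: nodes are
$(a-1)$-mers and edges the $a$-mers occurring in the polished k-mers (both
orientations for canonical tables), with $a$ = `assembly_k` defaulting to
$k-5$ so that k-mers still carrying a stray variant base co-assemble.
Unitigs — maximal paths whose interior nodes have in- and out-degree 1 —
are reported as contigs; reverse-complement twins are deduplicated to the
lexicographically smaller strand. Before extraction, dead-end branches
shorter than `assembly_k` whose edges each trace back to a single k-mer
occurrence are pruned (minimal tip cleanup; no bubble popping or coverage
cutoffs — a polished k-mer set rarely needs more). A contig's
`mean_support` is the mean per-occurrence count of the k-mers supporting
its edges.

Unitigs still break at any surviving variant or coverage gap, so
`merge_contigs()` performs a second, greedy round: repeatedly merge the
contig pair with the longest suffix-prefix overlap of length at least
`min_overlap` (default 10) with at most `max_overlap_mismatch` mismatches
(default 1), in either relative orientation, until no pair qualifies.
Length ties break toward fewer mismatches, then the forward orientation —
determinism again. At mismatching junction positions the base of the
contig with higher mean support wins, the same frequency-weighted logic as
polishing. Output below `min_output_len` (default $2k$) is dropped as
unusably short. The greedy rule terminates (every merge reduces the contig
count) and is idempotent on its own output.

### Clustering and evaluation

Different variant combinations of one family often assemble into several
near-identical repeats. `cluster_repeats()` links pairs whose similarity —
LCS of the better orientation divided by the *shorter* length, so a
fragment matches its full-length parent — exceeds `sim_threshold` (default
0.85), takes union-find components, and reports the longest member of each
cluster as its representative. Raising the threshold only refines the
partition.

`compute_metrics()` scores an assembled set against a reference library:

* `N` — assembled repeats; `N_0` — library entries with at least one hit;
* `N_h` — entries *fully reconstructed*: some single assembled repeat whose
  aligned matches, divided by the entire entry length (uncovered positions
  count as mismatches), exceed the identity threshold (default 0.85). A
  multi-contig tiling never counts, by design: full construction means one
  sequence;
* `C_avg` — mean covered fraction using the non-overlapping hit subset of
  maximum total length (weighted interval scheduling, exact DP);
* `C_m` — mean covered fraction using only the longest assembled repeat
  hitting the entry, computed with the same DP restricted to that repeat's
  hits, which guarantees $C_m \le C_{avg}$.

Hits come from standard local alignment (match 1, mismatch −1, gap open 2,
gap extend 1, via Biostrings); these scores are configuration, not claims.
A hit must reach the identity threshold *and* span at least `min_hit_len`
(default 50) library bases — any two random sequences share short perfect
local matches, and without a length floor `N_0` and `C_avg` would count
them. Coordinates are 0-based half-open throughout; abutting intervals do
not overlap.

## The simulator, and what passing tests mean

`simulate_genome()` plants repeat families in a uniform-random background:
each family is a random consensus whose copies are independently mutated
(i.i.d. substitutions; indels uniform on 1..`indel_max_len`, insertion and
deletion equally likely) and placed at non-overlapping, non-nested uniform
positions on random strands. `simulate_reads()` draws
`round(depth * genome_length / read_len)` uniform-start, random-strand reads
with i.i.d. substitution errors. Everything is deterministic given a seed.

This emulates the axes that matter to the method — copy number, per-copy
divergence, coverage, error rate — and deliberately nothing else. Real data
adds nested and tandem repeats, segmental duplications, non-uniform
coverage, indel sequencing errors, and quality-correlated error profiles;
the background is maximally non-repetitive where real genomes are not.
Passing the synthetic suite therefore shows the algorithms implement their
contracts and that the method behaves as designed *under its own model
assumptions*; it does not certify recovery rates on real libraries.

Test and verification scales were chosen to exercise each claim at
comfortable statistical power on a single CPU: 200 kb backgrounds with
500 bp families (40 copies at 2% divergence for the recovery check, 15
copies at 8% for the improvement check), 20× coverage of 100 bp reads at
0.5% error, and 10,000-replicate Monte Carlo for the grouping-probability
formula.

## Numerical and design choices

* **Thresholds** are inclusive at each tier's lower bound ("three times or
  more" reads as $\ge$).
* **Ties** everywhere break deterministically: lexicographically smallest
  base in voting, fewer mismatches then forward orientation in merging,
  smallest member id labeling clusters. Two runs with one seed are
  bit-identical, including across partition counts.
* **Degenerate inputs**: counting errors out when k exceeds every read;
  an empty high tier simply recruits nothing; an empty contig set merges
  and clusters to empty outputs; `estimate_base_freq()` refuses histograms
  with no bin above the error peak rather than guessing.
* **Transitive grouping**: linked k-mer pairs merge into connected
  components. Greedy pairwise merging was the alternative; components were
  chosen because bucketing makes the links an equivalence-by-reachability
  structure anyway, and component consensus is order-independent.
* **`mean_support`** of merged contigs is the length-weighted mean of the
  parts — a bookkeeping convention, only used to arbitrate junction bases.
* **Exactness**: the grouping probability uses the exact integer-ratio
  product, not `lgamma`-based binomials; the coverage DP is exact, not
  greedy.

## Known limitations

* Tandem and nested repeats are out of scope: unitigs collapse tandem
  arrays, and the simulator never plants nested copies.
* Very long or internally repetitive families can merge into chimeras when
  distinct families share a ≥ `min_overlap` junction by chance; raising
  `min_overlap` trades completeness for safety.
* The spectral premise needs reasonably uniform coverage; heavy
  amplification bias will blur the tier boundaries.
* All-pairs clustering is quadratic and intended for the thousands of
  assembled repeats a run produces, not for millions of sequences.
* `N_h` depends on a local aligner's single best hit per pair and
  orientation; a repeat that hits an entry in two disjoint local blocks is
  undercounted there (it still counts fully in `C_avg`).
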