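---
title: "Methods: threshold-calibrated graph clustering of amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-calibrated graph clustering of amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(clustom)
```

## The problem

16S rRNA amplicon surveys produce tens of thousands to millions of
reads that must be grouped into operational taxonomic units (OTUs)
before any ecology can be done. The grouping rule is a dissimilarity
threshold on pairwise sequence distance: reads within 3% of one another
are conventionally treated as one species-level OTU, within 5% as one
genus-level OTU. The obstacle is computational: the trustworthy
distance is the fraction of mismatches in an optimal global
(Needleman–Wunsch, NW) alignment, and computing it for all
`choose(n, 2)` pairs is quadratic in both pair count and alignment
cost. For `n = 50000` reads that is already
`r format(n_pairs(50000), big.mark = ",")` alignments.

`clustom` implements a three-stage answer: calibrate a cheap
alignment-free *k*-mer distance against the NW distance on a small
random sample, do the quadratic all-pairs work with the cheap distance
only, and reserve exact alignment for a drastically reduced set of
cluster representatives.

## Distances

**NW distance.** Each pair is aligned globally with affine gap costs
(match `+5`, mismatch `-4`, gap open `-10`, gap extend `-1`; a gap run
of length `L` costs `open + L * ext`). The alignment is then edited:
terminal gap columns are removed, and all remaining gap columns are
ignored, so the distance is the fraction of mismatching columns among
gap-free columns. Ignoring internal gaps matches how most 16S
phylogenetic pipelines treat indels (as missing data) and avoids
overcounting homopolymer sequencing artifacts.

Terminal gaps are *penalized* by default. A semi-global scheme (free
end gaps) sounds natural for reads of unequal length, but it lets two
unrelated sequences achieve a positive score from a short spurious
suffix–prefix overlap, which after end-gap stripping yields a distance
near zero — unrelated reads would merge. With full-length amplicons of
comparable span, penalized ends are the safe default;
`nw_scoring(free_end_gaps = TRUE)` remains available for data where
reads genuinely are nested fragments.

```{r}
al <- nw_align("ACGTACGTTT", "ACGTACCTTT")
al
nw_distance(al)
```

**k-mer distance.** For word size `k` (default 7), each sequence is
summarized by its vector of `k`-mer counts, and

```
k_dist(i, j) = 1 - sum_w min(n_i(w), n_j(w)) / (min(L_i, L_j) - k + 1)
```

i.e. one minus the shared word count normalized by the shorter
sequence's window count. It needs no alignment, is computed here over
2-bit-packed words in C++, and correlates strongly with NW distance —
but not perfectly, which is what the calibration and refinement stages
deal with. Windows containing ambiguity codes are skipped.

## Stage 1: threshold calibration

The user threshold `alpha` is an NW distance; the all-pairs filter
needs the equivalent *k*-mer threshold `beta`. A random sample of reads
(default 1000; all reads when fewer) is drawn, both distances are
computed for every sampled pair, and each pair is categorized against
the pair of thresholds: a *false positive* is a pair the `k`-mer filter
would accept (`k <= beta`) although its NW distance exceeds `alpha`.
`beta` is set to the largest observed `k`-mer distance at which the
false-positive count is still zero. False positives would let the
initial graph connect sequences that are truly farther apart than
`alpha` — an error the later stages cannot undo — whereas false
negatives (pairs the filter misses) are recovered by refinement. The
calibration is therefore deliberately one-sided.

```{r}
com <- generate_community(community_spec(
  n_species = 3, ancestor_length = 200, abundances = rep(8L, 3),
  seed = 42))
cal <- calibrate(com$seqs, alpha = 0.03, sample_size = 24, seed = 1)
cal
```

`autoplot(cal)` draws the sampled pairs in the `(k, d)` plane with both
thresholds; `glance(cal)` returns the confusion counts and the squared
correlation between the two distances.

## Stage 2: initial clustering

All `choose(n, 2)` `k`-mer distances are computed and every pair with
`k <= beta` becomes an edge of a similarity graph. Clusters are then
extracted greedily: the node of maximum degree is taken as a *seed*,
the seed plus its current neighbours form a cluster and leave the
graph, and the process repeats until only isolated nodes (singletons)
remain. The most-connected node stands in for the cluster's centre —
the true centre may not be realized by any read at all. Degree ties
break to the lexicographically smallest id, which makes the whole
pipeline deterministic.

## Stage 3: refinement and recovery

Pairs whose NW distance is within `alpha` but whose `k`-mer distance
exceeds `beta` are missing from the initial graph; they surface as
separate seeds or singletons. Refinement computes exact NW distances
for all pairs drawn from the (small) set of seeds and singletons,
builds a second graph with edges at `d <= alpha`, and runs the same
max-degree extraction on it. Recovery then expands each node of a
refined cluster back into its initial-cluster members (a singleton
contributes only itself), producing the final OTUs. Because the
expensive alignment stage only ever sees seeds and singletons, the
total number of NW alignments stays far below `choose(n, 2)`.

Calibration and the `k`-mer graph are built once at a 3% threshold;
refinement and recovery re-run per requested threshold, so one call
yields the entire threshold ladder:

```{r}
fit <- clustom(com$seqs, alphas = c(0.03, 0.05), seed = 1)
fit
glance(fit)
```

`tidy(fit)` gives one row per (threshold, read) with OTU and seed
assignments, and `write_otu_files()` exports the membership table,
representative FASTA and abundance table for one threshold.

## Evaluating a clustering

Two complementary frameworks are provided.

**Taxonomy-based.** With reference labels, each taxon's *representative
OTU* is the OTU containing most of its reads; taxa sharing one
representative OTU are merged into a *composite taxon* (this is how
species groups that are indistinguishable in 16S, such as
*E. coli*/*Shigella*, score as a unit), and taxa whose maximum is tied
across OTUs are excluded as ambiguous. Per (composite) taxon, TP/FP/
FN/TN counts give precision and recall; `f_measure()` combines the
*averaged* precision and recall into a harmonic mean — averaging first
weighs every taxon equally regardless of abundance.

```{r}
toy <- generate_toy_confusion()
conf <- taxon_confusion(toy$clustering, toy$taxonomy)
conf
f_measure(conf)
```

**Distance-based.** Without labels, each OTU's *core sequence* is its
member with minimum average NW distance to the rest. A read is a
*false conjunction* if it sits farther than `alpha` from its own OTU's
core (wrongly included) and a *false disjunction* if it sits within
`alpha` of another OTU's core (wrongly separated); `false_rates()`
reports both as fractions of all reads.

## The synthetic community generator

`community_spec()` / `generate_community()` plant a known partition:
one random ancestor, per-species centroids mutated away from it at the
between-species divergence (default 15%), and reads mutated from their
centroid at the within-species divergence (default 1%), with optional
indels and 3' truncation mimicking pyrosequencing reads. This emulates
exactly the premise the algorithm rests on — tight within-species,
wide between-species distance bands — and nothing more: real 16S data
add chimeras, skewed abundance distributions and conserved/variable
region structure that the generator does not model. It is a correctness
instrument, not a realism benchmark. Read ids are assigned after
shuffling so they carry no information about the planted labels; the
ground truth is returned as a separate table.

## Defaults and their rationale

| Parameter | Default | Why |
|---|---|---|
| `k` | 7 | small enough for sensitivity at 3–10% divergence, large enough that shared words imply relatedness on ~450 nt reads |
| `sample_size` | 1000 | calibration stabilizes well below this for survey-scale inputs; `choose(1000, 2)` alignments remain affordable |
| `alphas` | 0.03 | species-level convention; values in `[0.03, 0.10]` are supported, others warned about |
| scoring | +5/−4/−10/−1 | classic DNA scoring; gaps expensive relative to mismatches, as 16S indels are rarer than substitutions |
| end gaps | penalized | see *Distances* above |

Worked problem sizes in this vignette are kept small (tens of reads)
so it renders quickly; the pipeline itself is routinely run here on
hundreds of reads in seconds, and the `k`-mer stage on tens of
thousands.

## Limitations

- Calibration is sample-based: `beta` is a zero-false-positive
  threshold *on the sample*, a statistical rather than absolute
  guarantee for the full input.
- The greedy max-degree seed is a proxy for the cluster centre; for
  clusters whose centre is not realized by any read the proxy can be
  off-centre, slightly inflating within-OTU radii.
- Reads shorter than `k` cannot share words and always remain
  singletons in the initial graph.
- The refinement stage is quadratic in the number of seeds plus
  singletons; data with very many singletons (e.g. heavily chimeric
  input) erode the speed advantage.
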