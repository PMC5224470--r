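---
title: "Alignment-free virus-host prediction: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free virus-host prediction: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onfhost)
```

## The problem and the model

Metagenomic assembly recovers large numbers of viral genomes and contigs
whose hosts are unknown, because sequence alone does not reveal what a
virus infects. Because a virus replicates with its host's machinery, its
nucleotide composition tends to drift toward that of its host
("amelioration"), and avoidance of host restriction sites shapes word usage
further. `onfhost` exploits this: it scores every candidate host genome by
the dissimilarity of its oligonucleotide (k-mer) frequency profile to the
query virus, and predicts the host (or host taxon) with the lowest score.

For a genome $X$ with $n_X$ counted word positions, let $N^X_w$ be the
count of word $w$ ($w$ ranges over the $4^k$ k-mers) and
$f^X_w = N^X_w / n_X$. Counting treats every contig of a genome project
independently (no junction words), skips windows containing `N`, and by
default uses the forward strand only; an option adds reverse-complement
counts to the same profile.

The background-corrected statistics additionally model each genome by its
own order-$r$ Markov chain. Transition probabilities are estimated from
$(r{+}1)$-mer counts, word probabilities are the chain product
$p_w = \pi(w_1..w_r)\prod_{i=r+1}^{k} P(w_i \mid w_{i-r}..w_{i-1})$,
expected counts are $E_w = n_X\, p_w$, and the centered counts are
$\tilde X_w = N^X_w - E_w$. The flagship measure is

$$ d_2^* = \frac{1}{2}\left(1 -
   \frac{\sum_w \tilde X_w \tilde Y_w / \sqrt{E^X_w E^Y_w}}
        {\sqrt{\sum_w \tilde X_w^2/E^X_w}\,\sqrt{\sum_w \tilde Y_w^2/E^Y_w}}
   \right) \in [0, 1], $$

a correlation-type dissimilarity of standardized deviations from each
genome's own background. Ten companion measures are provided
(`onf_measures()`): Euclidean, Manhattan and Chebyshev distances, the
cosine-type $d_2$, Jensen–Shannon divergence of $(r{+}1)$-mer
distributions, and the background-corrected $d_2^S$, Hao
(composition-vector cosine), Teeling (z-score correlation), EuF (Euclidean
distance of relative deviations) and Willner (mononucleotide-normalized
abundance ratios, defined only for $k \le 4$). All scores are oriented so
that smaller means more similar; native similarities $s$ are wrapped as
$(1-s)/2$.

The measure formulations follow the standard literature forms of each
statistic. The original publications' supplementary equations were not
available to this implementation for reconciliation; where a measure has
minor variants in the literature (Teeling's variance term, the exact EuF
and Willner normalizations, JS over $(r{+}1)$-mers), the forms documented
above and in the function help are the ones implemented and tested against
independent brute-force oracles.

## Parameters that matter

- **k (word length, default 6).** Longer words are more specific but
  sparser. Accuracy of $d_2^*$ grows with $k$ on real benchmarks, but
  computation grows $4^k$-fold; $k = 6$ is the recommended operating point,
  $k = 9$ the practical maximum.
- **r (background order, default 2).** The order of the Markov chain
  subtracted by $d_2^*$, $d_2^S$, EuF (and defining the JS distributions).
  On real phage genomes, BIC selects order 2 for the large majority of
  sequences; `select_order_bic()` reproduces that choice per genome and the
  CLI accepts `--order auto` (modal BIC order across the query viruses,
  capped at $k-1$). The BIC likelihood scores transitions within contigs
  only; initial-context terms are omitted as asymptotically irrelevant and
  awkward for multi-contig projects.
- **threshold (optional).** Predictions are refused when the best
  dissimilarity exceeds the threshold; this trades recall (fraction of
  viruses with a prediction) for accuracy. The gate always applies to the
  single best score, also in consensus mode.
- **consensus n (optional, 1 = nearest host).** The n lowest-scoring hosts
  vote per rank; the modal taxon wins. Voting is per-rank independent, so
  the winning genus need not lie inside the winning family — the evaluation
  scores each rank separately, and per-rank voting is the direct reading of
  "most frequent taxon at a given taxonomic level".

## Numerical and degenerate-input choices

- Word indexing is lexicographic over A<C<G<T everywhere, and sums
  accumulate in that fixed order, so scores are bit-reproducible.
- Ambiguity codes other than `N` are normalized to `N` at read time and
  windows containing `N` never count; this keeps the $4^k$ state space
  exact. No pseudocounts anywhere: contexts never observed with a
  successor have undefined transition rows and contribute $p_w = 0$;
  words with zero expectation are skipped in background-corrected sums.
  Because each genome is centered against its own model, every observed
  word has positive expectation, so no observed signal is discarded.
- Context probabilities are the empirical frequencies of contexts *at
  transition positions* (row sums of the $(r{+}1)$-mer table, normalized),
  not raw $r$-mer frequencies. The two differ only in contig-terminal
  contexts, and this convention makes $\sum_w p_w = 1$ hold exactly
  (telescoping), which the centered statistics rely on.
- A sequence that exactly matches its own background has all-zero centered
  counts; measures report a degenerate-input error naming the sequence
  rather than returning 0/0. This happens for homopolymers at any order,
  and — less obviously — for *every* sequence at the maximal background
  order $r = k-1$: the order-$(k{-}1)$ model estimated from a sequence
  reproduces that sequence's k-mer counts exactly, so the centered
  statistics are only meaningful for $r \le k-2$.
- Tie-breaking (equal best scores, tied consensus votes) is by seeded
  uniform draw; a fixed seed gives deterministic output and the seed
  protocol makes predictions invariant to host column order.
- The one-sided rank-sum taxon test uses the exact null distribution when
  the combined group is smaller than 30 (and tie-free), otherwise the
  normal approximation with tie correction; p-values are Bonferroni
  multiplied by the number of taxa tested at the rank.

## What the synthetic benchmark emulates — and what it does not

`simulate_benchmark()` builds a fully self-contained world: each host
genome is emitted from its own Markov chain whose transition rows are drawn
from a symmetric Dirichlet, and each virus is emitted from a position-wise
mixture — with probability `alpha` the next base comes from its host's
chain, otherwise from a virus-specific unrelated chain. `alpha` is thus a
tunable amelioration level: 1 means the virus shares its host's
compositional statistics fully, 0 means not at all.

Three generator defaults deserve justification:

- **Generating-chain order 4 (analysis background order 2).** This
  asymmetry is deliberate and necessary. A sequence emitted from an
  order-r chain is *fully explained* by its own estimated order-r
  background: its centered counts are pure sampling noise, uncorrelated
  between virus and host, and background-corrected measures are
  structurally blind on such data (empirically, true-vs-random AUC ≈ 0.5).
  Real genomes carry compositional signature beyond any low fixed order;
  the order-4 generator gives the 6-mer profiles structure that an order-2
  background does not absorb, which is precisely the signal $d_2^*$ is
  designed to read. A consequence worth knowing: BIC on the benchmark's
  sequences selects order 4, so the order-2 recovery test uses explicit
  order-2 simulations instead.
- **Dirichlet concentration 8.** Per-row transition probabilities then
  vary with s.d. ≈ 0.075 around 0.25, comparable to the spread of
  nucleotide composition across real prokaryotic genera (GC content s.d.
  of roughly 10 percentage points). Smaller values would make hosts
  trivially separable cartoons; much larger values would make them nearly
  identical.
- **Sizes: 50 hosts × 100 kb, one 20 kb virus per host.** Genome lengths
  in the realistic range for bacteria (small end) and tailed phage; 50
  hosts keeps a full matrix cheap while leaving a 25-genus taxonomy for
  rank-level scoring.

Limitations to keep in mind when reading green tests: the simulator has no
genes, codon structure, GC islands, repeats, horizontal transfer or shared
ancestry between hosts — host genomes are *independent* chains, so there is
no within-genus compositional similarity; a correct genus call on synthetic
data means the generating host itself was ranked first. Hosts are also far
more separable than real congeneric bacteria: with the default world,
nearest-host prediction is essentially perfect down to 1 kb fragments and
at substitution rates up to 0.05, so the benchmark demonstrates that the
machinery finds the planted signal, not that real-data accuracy would
survive those perturbations. Conclusions about absolute accuracy on real
viruses cannot be drawn from it.

## Evaluation machinery

`accuracy_by_level()` scores predictions per rank: accuracy is
correct/predicted among viruses with known (non-`unknown`) truth at the
rank; recall is predicted/total. `roc_auc()` computes
$P(\text{true} < \text{random}) + \tfrac12 P(=)$ by the rank statistic
(lower score = positive class), `pair_ttest()` the two-sided Welch test,
and `pair_scores()` draws the random "non-interacting" pairs uniformly with
the true pair excluded. `random_baseline()` is the closed-form expected
accuracy of a uniform host guess — the taxonomically unbalanced host set
makes this the honest chance line. `robustness_sweep()` re-predicts after
fragment subsampling (never across contig junctions) and substitution
error (uniform replacement by one of the three other bases; `N` untouched),
reporting per-replicate accuracies and normal-approximation 95% intervals
(the interval construction for such sweeps is not standardized; mean
± 1.96 SE across replicates is used).

## Worked example

```{r example, eval = FALSE}
bench <- simulate_benchmark(simulation_config(n_hosts = 12, seed = 7))
scores <- compute_matrix(bench$viruses, bench$hosts,
                         measure = "d2star", k = 6, order = 2)
pred <- predict_consensus(scores, bench$taxonomy, n = 5, threshold = 0.45)
accuracy_by_level(pred, bench$truth)
```

The same pipeline is scriptable end to end:

```sh
Rscript -e 'onfhost::cli_main()' simulate --out bench --n-hosts 12 --seed 7
Rscript -e 'onfhost::cli_main()' predict \
    --virus-dir bench/viruses --host-dir bench/hosts --out results \
    --measure d2star --k 6 --order 2 \
    --taxonomy bench/taxonomy.tsv --truth bench/truth.tsv
```

## Known limitations

- No smoothing means very short queries (≪ 1 kb at k = 6) produce sparse,
  noisy profiles; the measures remain defined but discrimination fades.
- The rank-sum test has no power for taxa with very few hosts in the
  database, and Bonferroni correction is conservative when many taxa are
  tested.
- Habitat filtering is plain host-set restriction (`--host-filter`); the
  package ships no habitat annotations.
- The package predicts hosts from composition only; it does not and cannot
  certify infection. Low dissimilarity to a non-host through convergent
  composition is always possible, which is exactly why thresholding,
  consensus and the rank-sum test exist.
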