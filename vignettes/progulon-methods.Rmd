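---
title: "Methods: detecting protein co-regulation modules with progulons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting protein co-regulation modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind the package, and what the synthetic-data tests do and do
not demonstrate about real data.

# The data model

The substrate is a protein x perturbation matrix of log2 expression ratios
(`RatioMatrix`, a `SummarizedExperiment` with one `lratio` assay). Missing
entries mean a protein was not quantified in an experiment; the number of
quantified experiments is a protein's *feature count*. Feature counts gate
everything: training proteins need 45 features and scored ("test")
proteins 30 by default, because Random-Forest votes based on a handful of
ratios are not trustworthy. For deliberately small experiment subsets
(e.g. a 15-experiment nascent-chromatin panel) the minima drop to 7 and 5,
and eligibility is always re-derived from the matrix actually passed, so
column-subset analyses are self-consistent.

# Tree-based dissimilarity

For every experiment column *j* a surrogate regression tree predicts
column *j* from all other columns, fitted on the proteins quantified in
*j* (rpart, `minbucket = 5`, grown at `cp = 0.001`). Trees are pruned by
cost-complexity with the 1-SE rule on rpart's internal 10-fold
cross-validation; a tree pruned back to the root carries no co-regulation
signal and is discarded (a matrix of pure noise therefore raises an error
rather than returning a meaningless metric). The dissimilarity between two
proteins is the fraction of retained trees in which they occupy different
leaves (the unweighted leaf-disagreement form); a deviance-weighted
variant, where each tree counts proportionally to the deviance it
explains, is available behind `weighting = "deviance"`. The unweighted
form is the default because it is the simplest member of this
dissimilarity family and the downstream clustering only consumes ranks of
similarity.

Numerical decisions:

* **Missing predictors.** Before fitting and routing, predictors are
  median-imputed with medians computed from the tree's training rows and
  frozen, so leaf routing is deterministic. A protein for which *none* of
  a tree's split variables are observed would be routed purely by
  imputation; it is instead marked unassignable in that tree, and the
  pair-wise denominator is adjusted. Pairs with no usable tree are
  undefined (`NA`), never silently zero.
* **Fold determinism.** Cross-validation folds depend on row order, so
  training rows are sorted by protein ID before fitting; the dissimilarity
  is then invariant to the order in which proteins arrive.
* **Tie structure.** With few experiments the dissimilarity is coarse
  (many exact ties, including ties at 0). The top-fraction network
  therefore breaks boundary ties lexicographically, which keeps edge sets
  deterministic but means the network composition among tied pairs is a
  convention, not a measurement. At compendium scale (hundreds of
  experiments) ties are rare; at desk scale tests use denser fractions or
  structured fixtures (see below).

# Seed discovery

OPTICS (reachability ordering at `eps = Inf`, core distance to the
(minPts-1)-th other point) runs on the *complete* dissimilarity matrix;
undefined dissimilarities are imputed to the maximum observed distance and
reported. Clusters are extracted with the xi steepness criterion
(`xi = 1e-4` by default — on ratio-derived dissimilarities nearly any
sustained drop marks a density valley; the value is exposed because it is
data-dependent). A sentinel value above every reachability is appended to
the profile so clusters that run to the end of the plot are closed; flat
cluster membership assigns each point to its smallest enclosing xi
cluster (the full hierarchy is returned as an attribute). `minPts = 5` is
the package default, a typical density-clustering choice; it is exposed
because nothing in the method pins it down.

Cohesiveness clustering runs on the top-0.5% network only — the two
algorithms deliberately see different inputs. Every node seeds a greedy
growth (in decreasing weighted-degree order) that applies the single
vertex addition or removal that most increases
f(V) = w_in / (w_in + w_bound + penalty |V|), with penalty 2; candidate
groups whose match coefficient reaches 0.8 are merged, and groups smaller
than 4 or with internal density below 0.4 are dropped (the last two values
are the method's stated operating point; penalty and merge threshold are
the cited algorithm's defaults). Greedy growth guarantees a single-move
local optimum of f, not the global optimum: graphs exist on which no seed
can reach the global maximiser through strictly improving moves. The test
suite therefore checks global optimality against exhaustive search on
community-structured toy graphs and local optimality exhaustively on
arbitrary ones.

Seeds are intersections: for each OPTICS cluster the cohesiveness cluster
with the largest member overlap (ties: larger Jaccard, then lexicographic
order) is selected, each cohesiveness cluster serves at most one OPTICS
cluster, and intersections below 4 proteins are dropped — only proteins
grouped by both algorithms are trusted as training material.

# Balanced Random-Forest ensembles

With seeds of 4-80 proteins against a 1,000-protein negative pool, class
imbalance would swamp a single model. Instead, M = ceil(1000 / n_pos)
balanced models are fitted; each uses all positives plus an equally sized
negative draw, with the pool consumed in chunks without replacement and
reshuffled when exhausted, so every pool protein is used approximately
once. Each model is a 500-tree forest of unlimited depth
(`nodesize = 1`, mtry = sqrt(n_features), the standard classification
default). The RF score is the fraction of trees voting "positive",
averaged across models. Missing values are median-imputed per feature
within each model's training set, frozen for scoring. If a feature is
entirely missing among a model's 2 n_pos training rows it is imputed 0
(the neutral log-ratio).

Leave-one-out cross-validation retrains the *full* ensemble once per seed
protein with that protein removed, reusing the same negative pool, the
same number of models as the full ensemble, and the same RNG stream per
fold, so fold scores are comparable. Two open choices were resolved as
follows and are deliberately strict:

* The ROC AUC gate (>= 0.99) compares LOO scores of the positives against
  the ensemble scores of the 1,000 negative training proteins —
  cross-validation affects only the positive class, since negatives are
  never the class of interest.
* The "at least 4 of the top 10" gate ranks training proteins by their
  LOO score (not their optimistic in-training score).

# Membership cutoff by connectivity

An RF score only certifies co-regulation with the seed. A genuine module
must also be internally co-regulated, so membership is cut at the minimal
score on the inclusive grid {0.50, 0.51, ..., 1.00} (51 points) at which
the member set is enriched for top-network edges: a one-sided Fisher's
exact test on the 2x2 table over all unordered pairs of scored proteins
(internal to the member set x network edge), with pairs of undefined
similarity counted as non-edges. One-sided enrichment is the only
meaningful direction — a depletion of internal edges cannot make a
module. Training positives enter the member set only if their LOO score
clears the cutoff; they are not force-included. If no grid point reaches
P < 0.05 the candidate is discarded — a result, not an error, and the
command-line wrapper maps it to exit code 2.

# Module maps

Member-restricted dissimilarity matrices are embedded with exact
(non-approximated) t-SNE: per-point bandwidths found by binary search to
the target perplexity (default 30, shrunk to (n-1)/3 with a warning when
the member count is small), 500 gradient-descent iterations with early
exaggeration 12 for the first 100 and momentum switching from 0.5 to 0.8
at iteration 250, learning rate 200. Coordinates are deterministic given
the seed.

# Downstream statistics

* **Contribution vs coordination.** Per gene, the contribution of mRNA to
  protein changes is the pairwise-complete Spearman rho between the
  gene's mRNA and protein rows; a group's coordination is the median
  pairwise-complete Spearman rho over within-group pairs of one data
  level. These are distinct axes: a group can be tightly coordinated at
  the protein level with almost no mRNA-to-protein transmission, and vice
  versa.
* **Permutation tests.** Group medians are compared with medians of B
  random same-size gene sets (label resampling from the universe,
  B = 10,000 by default) and reported as P = (r+1)/(B+1), whose floor
  1/(B+1) avoids zero P-values.
* **Scale.** Median absolute deviation without the 1.4826 consistency
  factor — a robust scale for comparison across groups, not an estimate
  of a Gaussian sigma.
* **Enrichment.** Flat one-sided Fisher tests over supplied GMT sets with
  Bonferroni correction; sets smaller than 20 (after restriction to the
  analysed-and-annotated universe) are not tested. Graph-aware GO
  elimination is out of scope.
* **Conservation and genome position.** Co-regulated pairs (rho > 0.5)
  are tracked across datasets through a one-to-one ortholog map and split
  by progulon category; same-chromosome enrichment uses a two-sided
  Fisher test on pair counts against the mapped universe's
  same-chromosome fraction.

# Screen scoring

Readout values are normalized per (plate, readout, replicate) by
subtracting the median of that plate's negative-control wells — the
screened library is biased, so the plate median is not a neutral
reference. Replicates are combined per siRNA by the mean (median by
option). Each readout's hit threshold adapts to assay variability,
measured as the SD of combined negative-control activities: 3x SD when
SD <= 0.05, 2x when 0.05 < SD <= 0.13, 1x when SD > 0.13. A gene is a hit
in a readout when at least 2 of its 3 siRNAs pass the threshold in the
same direction, worth at most +1 regardless of direction. Process caps:
replication readouts contribute up to 5, DNA damage up to 4, and each of
the four cell-cycle conditions at most 1 (changes in one phase come at
the expense of others), so the maximum cumulative score is 13. Confidence
tiers: high above half the maximum, medium above a third. Thresholds are
computed on replicate-combined control values (per-well thresholds would
mix replicate noise into the tier decision).

# Synthetic data: what it emulates, and what it does not

`simulateProteomeHd` plants modules as shared latent response vectors plus
member-specific noise; the implied pairwise correlation is
responseSd^2/(responseSd^2 + noiseSd^2) (defaults 2 and 1, i.e. 0.8).
Modules have a tighter core (default: a third of the members at half the
body's noise), because real seeds are by construction the most tightly
co-regulated proteins of their module — strictly clustered cores or
well-characterised complex subunits — while the surrounding module is
looser. This heterogeneity matters at desk scale: with only a few hundred
background proteins the negative pool necessarily contains the held-out
module body, and a seed that is merely exchangeable with the body cannot
clear an AUC of 0.99 against it. Missingness is block-structured
(contiguous pseudo-project runs per protein) because proteins are
quantified per project, with a uniform option. Noise is Gaussian by
default with a t(3) option for ratio-like outliers.

Limits of the emulation: background proteins are mutually independent,
which real proteomes are not — at desk scale this makes the iid
background a single tree-leaf blob whose pairwise dissimilarities tie at
zero, a degeneracy real compendia do not show. Recovery tests for the
dual-clustering route therefore use matrices of mutually independent
modules (each module acting as the others' background) with an edge
fraction sized to the planted structure. Passing tests demonstrate the
algorithms' correctness and their behaviour under the stated generative
model; they do not certify performance on any particular real compendium,
where module tightness, missingness and background structure differ.

Problem sizes in the test suite were chosen as the smallest that exercise
the full default parameter set (1,000-negative pool truncates at a
520-protein pool; 100 experiments keep the 45/30 feature gates
meaningful): planted-module recovery uses 530 proteins x 100 experiments
over 5 generator seeds, the random-seed control 20 trials on
background-only matrices of the same shape, and the permutation-test
calibration 500 null simulations at B = 200.

# Known limitations

* The dissimilarity's tie degeneracy on small, homogeneous matrices
  (above) makes the top-fraction network composition convention-dependent
  there.
* Greedy cohesiveness growth finds local optima; merged or missed
  clusters are possible on adversarial graphs.
* The xi cluster extraction can carve sub-clusters out of within-cluster
  jitter at permissive xi; the seed-derivation intersection with the
  cohesiveness clusters is what makes seeds robust to this.
* LOO retraining is the dominant cost (n_pos x M forest fits); the
  implementation predicts only the held-out protein per fold, but very
  large seeds are still expensive.
* ID mapping is deterministic (exact, then synonym table, then
  case-insensitive) and makes no attempt at isoform resolution or remote
  lookups; the synonym table is a user input.
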