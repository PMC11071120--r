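---
title: "Modeling expression from promoter and long-range-contact TF binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling expression from promoter and long-range-contact TF binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regdom)
```

## The model

`regdom` asks how much of a gene's expression can be explained by the
transcription-factor binding sites (TFBSs) in its *3D transcriptional
domain*: the 10-kb proximal promoter upstream of the TSS, plus the distal
5-kb windows the core promoter physically touches through chromatin
looping. The response for gene $i$ is log-scale expression, and the model
is ordinary least squares

$$\log_{10}(\mathrm{TPM}_i + 1) \;=\; \beta_0 + \sum_j w_j S_{ij} + e_i,$$

where each column $S_{\cdot j}$ is a scored regulatory feature and the
fitted coefficient $w_j$ (the feature's RC) reads as activator-like when
positive and repressor-like when negative. Four nested feature sets are
compared: **B** (promoter TFBS scores), **BH** (B + six promoter histone
marks), **BL** (B + long-range-contact TFBS scores) and **BHL** (all).

The printed form of the model has no explicit intercept; we fit one and
report it separately from the RCs, because the response is not centered
and a log-scale offset would otherwise contaminate every coefficient.

### Domains

* **Core promoter**: $[\mathrm{TSS}-2500, \mathrm{TSS}+500)$, strand-aware.
* **Proximal promoter**: the 10 kb upstream of the TSS, strand-aware,
  clipped (and flagged) at coordinate 0.
* **Long-range contact (LRC)**: intrachromosomal Hi-C anchor pairs are
  Vanilla-Coverage normalized; when one 1-kb anchor overlaps a core
  promoter and its partner's center is intergenic (outside every gene body
  and proximal window) and more than 10 kb away, the partner anchor is
  kept. Overlapping partner anchors targeting the same gene are merged by
  interval union, and the merged center is stretched bidirectionally to a
  5-kb window.

Vanilla Coverage divides each pair's count by the product of its two
anchors' coverages and then rescales so total mass is conserved per
chromosome; the square-root variant is available via
`vc_normalize(method = "sqrt-vc")`. Because "more than 10 kb away" does
not name its reference points, we measure from the merged anchor center to
the nearest core-promoter edge — the conservative reading. A merged
window's contact weight `ct` is the **sum** of its constituent pairs'
normalized counts (not the mean); both choices are defensible and the sum
keeps `ct` additive under anchor merging.

### LRC activity

Each LRC window receives a histone score `hm`, the mean $\log_2$
fold-enrichment of the H3K27ac and H3K4me1 peaks overlapping it (0 if
none; partially overlapping peaks count fully, since no overlap-fraction
rule is part of the definition). The window's activity follows the
activity-by-contact form

$$A_{ic} = \frac{\mathrm{hm}_{ic}\,\mathrm{ct}_{ic}}
                {\sum_{m=1}^{T}\mathrm{hm}_{im}\,\mathrm{ct}_{im}},$$

so a gene's activities sum to exactly 1, or are all 0 when no window
carries both signal and contact. This invariant is asserted to $10^{-12}$
in the tests.

### TFBS scores

Sequences are scanned with a MATCH-style score: with column frequencies
$f(p,b)$ and information weights $I(p)=\sum_b f(p,b)\ln 4f(p,b)$, a
window's raw score $\sum_p I(p) f(p, b_p)$ is min–max normalized to
$[0,1]$; hits at or above 0.7 are reported (a single global threshold —
per-motif thresholds are supported by rescanning with a different cutoff).
Both strands are scanned and windows containing `N` are skipped.

Promoter hits are weighted purely by *position*. Hit midpoints are pooled
over all promoters into 100-bp bins; with observed density $D_{obs}$ and a
random density $D_{rnd}$, the weight of bin $b$ is

$$L(b) = \max\!\left(0,\; \frac{D_{obs}(b)-D_{rnd}(b)}{D_{obs}(b)}\right),$$

and the promoter score of motif $j$ for gene $i$ is
$\sum_k L_{ik}\sum_n \log_{10}(\mathrm{TPM}_{jn}+1)$ over the motif's $K$
hits and $N$ binding TFs. The double sum factorizes into
$(\sum_k L_{ik})(\sum_n \cdot)$, which the tests assert. $D_{rnd}$
defaults to the analytic uniform density $1/B$ — the exact expectation of
random placement — with a seeded empirical shuffle available; the analytic
form avoids adding randomization noise to a quantity whose expectation is
known.

LRC hits are weighted by *activity and match quality* instead:
$\sum_c\sum_k A_{ic} M_{ick} \sum_n \log_{10}(\mathrm{TPM}_{jn}+1)$, with
$M_{ick}$ the hit's match score. Neither score borrows the other's
weighting term.

Two conventions are worth naming. Expression always enters as
$\log_{10}(\mathrm{TPM}+1)$ — raw $\log_{10}$ is undefined at 0, and the
pseudocount keeps silent TFs in the sum at value 0 rather than $-\infty$.
And all mapped binding TFs present in the expression table contribute to a
motif's TF term; the 3-TPM expression filter applies only at network
construction. Promoter histone features are computed over the 10-kb
proximal window by default (`window = "core"` switches to the core
promoter).

## Feature selection and RC ensembles

The full model is reduced by stepwise selection minimizing
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2(p+1)$, yielding M1. Each feature
removed in that stage is then revisited once, in seeded random order: a
trial model M2 (current + candidate) is accepted only if it improves
**both** the AIC and the mean 5-fold cross-validated RSE (folds fixed by
the same seed, stratified by response quintile). The whole procedure runs
10 times with consecutive seeds; a feature's **RC ensemble** is its
coefficient in each run's final model, 0 when unselected. Ensembles are
tested against zero with a two-tailed one-sample t-test and
Bonferroni-corrected over the number of features; a zero-variance ensemble
gets $p = 1$ when its mean is 0 and $p = 0$ otherwise.

Two design points were genuinely open:

* **Stepwise direction.** Running *bidirectional* stepwise to convergence
  terminates, by definition, only when no single addition or removal
  lowers the AIC — so no removed feature could ever satisfy the greedy
  stage's AIC condition, the ten runs would be bit-identical and every
  ensemble would have zero variance. The default is therefore
  backward-only elimination (`direction = "backward"`), under which
  "features the elimination removed" can still improve the model when
  reintroduced and the greedy stage has a role. `direction = "both"`
  remains available.
* **Acceptance rule.** Requiring improvement in both AIC and CV-RSE is the
  strict reading of "assessed using AIC and 5-fold CV";
  `require_both = FALSE` relaxes it to AIC alone.

Model performance is summarized by the mean training RSE
($\sqrt{\mathrm{RSS}/(n-2)}$, the $n-2$ degrees of freedom by definition)
across the ten runs. For model *comparison*, `evaluate_models()` reports
the Pearson correlation of **held-out** (5-fold CV) predictions pooled
across folds and runs: in-sample correlation is inflated by
$\sqrt{p_{\mathrm{selected}}/n}$ even for pure-noise designs, which would
make randomized controls look weakly predictive.

### A known limitation

The ensemble t-test only filters features whose *selection varies across
seeds*. Features retained by the (deterministic) stepwise stage keep
near-identical coefficients in all ten runs, so a noise feature that
survives elimination — which happens with probability
$\approx P(|t| > \sqrt 2) \approx 0.16$ per feature — is flagged
significant no matter how small its coefficient. On the standard synthetic
study (54 noise features) this yields roughly 7–14 false-positive
features alongside perfect recovery of the planted ones, and randomized
controls retain a similar number of chance features. Interpreting
significant features with small |mean RC| therefore warrants caution; the
magnitude, not just the adjusted p-value, carries information. The same
mechanism means cross-validated correlation for randomized controls is
small but not zero (selection happens outside the CV loop).

## Networks and embedding

For every significant TFBS feature, each binding TF expressed above 3 TPM
in at least one condition is connected to every modeled gene whose
promoter (or LRC windows) contains a hit of that motif. TF vertices are
typed by compartment — a TF active in both appears as both a `prmTF` and
an `lrcTF` vertex. Cofactors (proteins with a PPI confidence strictly
above 0.4 to a network TF, expressed above 3 TPM) connect only to TF
vertices. Edges are binary and undirected.

Before embedding, the network is densified with 2-hop closures: each
vertex, in lexicographic order, gains unit-weight edges to its 2-hop
neighbors (most shared neighbors first, ties by id) until its degree
reaches a cap (default 1000). Embedding trains two objectives — one
preserving direct-edge affinity through
$p_1(v_i,v_j)=\sigma(u_i^\top u_j)$, one preserving shared neighborhoods
through per-vertex context vectors — by sequential stochastic gradient
descent over sampled edges with 5 degree$^{0.75}$-distributed negative
draws per positive and a linearly decaying step size from 0.025. Training
is single-threaded and seeded, so vectors are bit-identical across runs;
the sample budget defaults to $1000\,|E|$, which desk-scale networks
(tens to a few thousand edges) train in seconds. The two 100-dimensional
blocks are L2-normalized per vertex and concatenated into the final
200-dimensional vectors.

Clustering follows the two-stage convention: PCA-initialized t-SNE to 2D
(Rtsne, perplexity capped at $(n-1)/3$), then K-means **on the 2D
coordinates** — not on the full vectors. Vertex *similarity* queries, by
contrast, use Pearson correlation of the full 200-dimensional vectors.
Both choices are stated because they deliberately differ from each other.
`k = "auto"` scans 2–15 and takes the best mean silhouette width, lowest
k winning ties.

## The synthetic study generator

`generate_study()` builds every input the pipeline consumes — gene models
with per-condition TPM, contacts, peaks, PFMs with a motif→TF map, PPI
edges, hit tables, and optionally sequences with motif instances planted
at the hit offsets (exact consensus, score 1.0, or single-mismatch
variants spanning scores down to ~0.72). Crucially, the response is
generated *through the package's own scoring functions*: the generator
derives promoters, normalizes its contacts, computes activities and
feature scores exactly as the pipeline would, then draws
$y = \beta_0 + S w + \varepsilon$ and back-transforms to TPM. Parameter
recovery is therefore well-posed — with `noise_sd = 0` the full-model fit
reproduces the planted coefficients to numerical precision, which is a
test, not a coincidence.

Default study conditions: 1000 target genes, 40 motifs (hence 80 TFBS
features plus 6 histone features), 3 LRC windows per gene, 20 promoter
and 10 LRC features planted at effects $\pm 0.5$, two histone marks
planted at $\pm 0.3$, noise sd 0.3 on the log10 scale, ~80% of LRC
windows carrying enhancer marks. TF expression is fixed (3–30 TPM) so the
TF term in the scores is exogenous to the modeled response. Test problem
sizes are scaled to the property being checked: 60–200 genes for unit
checks, the full 1000-gene study for end-to-end selection, and a
60-vertex 2-block stochastic block model ($p_{in}=0.3$, $p_{out}=0.01$)
for embedding recovery, where K-means at $k=2$ reaches an adjusted Rand
index ≥ 0.9 in at least 8 of 10 seeds.

What the generator does **not** emulate: the exaggerated TPM dynamic range
implied by unbounded Gaussian log-scale noise; correlated or clustered
motif co-occurrence (features are independent across motifs); replicate
structure and mapping noise; distance-dependent Hi-C contact decay; and
sequence composition biases (backgrounds are uniform random). Passing
tests demonstrate the machinery is faithful to its stated model, not that
real chromatin obeys it.

## Numerical conventions

* Formula identities (activity normalization, the score factorization)
  hold to $10^{-12}$; OLS matches the normal equations to $10^{-8}$.
* Degenerate inputs: genes with no active LRC get all-zero activities;
  motifs with no promoter hits are dropped from histograms with a warning;
  constant or duplicate design columns are removed (with a manifest)
  before fitting; zero embedding vectors are left unnormalized with a
  warning; constant vectors yield `NA` correlations.
* Ties: auto-k and K-means ties resolve to the lowest k / first center
  set under the fixed seed; 2-hop closure ties resolve by vertex id.
* Every stochastic stage takes an explicit seed and is bit-reproducible.
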