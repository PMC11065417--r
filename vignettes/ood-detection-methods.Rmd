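---
title: "Evaluating extrusive OOD detectors: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating extrusive OOD detectors: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oodeval)
```

## The problem

A classifier deployed in the field — the motivating case is insect-pest
identification, where a model trained on a fixed set of species meets
leaves, vehicles, faces, or untrained insect species — will happily emit a
confident label for inputs that belong to none of its classes.
Out-of-distribution (OOD) detection adds an abstention mechanism: a
scalar confidence score is computed for every input and compared to a
threshold; low-confidence inputs are flagged instead of classified.

`oodeval` implements the *extrusive* family of detectors: scores wrapped
around an already-trained classifier, with no retraining. Three scores
are compared throughout, under one orientation (higher = more ID-like):

* **MSP** — maximum softmax probability, $\max_i \,
  \mathrm{softmax}(f(x))_i$, computed from the logit vector $f(x)$. The
  softmax is evaluated after subtracting the row maximum, so it is exact
  under constant logit shifts and safe for logits beyond `exp()` range.
* **MAH** — class-conditional Mahalanobis confidence. Penultimate-layer
  ("pre-logit") features are modelled as class-conditional Gaussians
  $\mathcal N(\mu_c, \Sigma)$ with a tied covariance; the score is the
  negated squared Mahalanobis distance to the nearest class,
  $M(x) = \max_c -(f(x)-\hat\mu_c)^\top \hat\Sigma^{-1} (f(x)-\hat\mu_c) \le 0$.
* **EBM** — the energy score
  $E(x) = -T \log \sum_i e^{f_i(x)/T}$ (temperature $T = 1$ by default),
  exposed as the confidence $-E(x)$, i.e. the log-sum-exp of the logits.

The evaluation protocol splits ID data 70/15/15 into ID1 (classifier
training), ID2 (detector fitting — consumed only by MAH) and ID3
(testing), then measures ROC metrics of ID3-vs-OOD score separation:
AUROC, FPR95 (false-positive rate at the smallest threshold reaching 95%
TPR, step-function convention, no interpolation), the Youden-optimal
threshold $\arg\max_t \mathrm{TPR}(t) - \mathrm{FPR}(t)$ with its
operating point, accuracy at that threshold on size-equalized sets, and
boxplot-style five-number summaries of the score distributions.

## What the synthetic generator emulates

The pipeline's experiments run on synthetic data whose structure is
exactly the assumption behind the Mahalanobis score: penultimate
features of ID class $c$ are drawn from $\mathcal N(\mu_c, \Sigma)$ with
class means themselves drawn once, i.i.d.
$\mathcal N(0, \texttt{mean\_scale}^2 I)$, as a pure function of the
seed. The defaults used by the experiments are 10 classes, 16
dimensions, `mean_scale = 3` and unit isotropic within-class covariance:
classes are well separated (typical inter-mean distance far exceeds the
within-class spread), emulating the high-accuracy regime of a
well-trained classifier, while keeping every simulation a second-scale
computation. Drawing means i.i.d. Gaussian (rather than on a sphere) is
the simplest structure satisfying the class-conditional Gaussian
assumption.

"Degree of out-of-domainness" — in the field a qualitative spectrum of
OOD datasets from contextually near (other insects, leaves) to far
(vehicles, faces) — is reduced to one controllable scalar: under the
default `mean-shift` mode, each OOD sample anchors on a uniformly chosen
ID class and is displaced by Euclidean distance $\delta$ along a
seed-determined per-class unit direction. At $\delta = 0$ the OOD
distribution *equals* the balanced ID mixture, so every detector is at
chance by construction — a built-in null. Two alternative modes
(`covariance-inflation`, and a per-sample `mixture` of the two) model
spread-based rather than location-based novelty. The mapping of any real
OOD dataset onto a $\delta$ value is illustrative only; the sweeps
assert trends, not dataset-specific values.

Class-size profiles for the imbalance experiment conserve their total
exactly: balanced (remainder of a non-divisible total goes to the
lowest-indexed classes — deterministic and testable), unbalanced-empirical
(counts proportional to supplied weights; the default emulates the
long-tailed geometric decay of field image corpora), and
unbalanced-uniform (counts proportional to independent uniform draws).
Non-integer targets are rounded by the largest-remainder method so no
profile ever drifts from its total.

The toy image generator (ellipses with class-determined aspect ratio and
intensity; OOD rectangles from a disjoint shape/intensity family) exists
to exercise the directory-per-class image path end-to-end; it does not
model insect morphology, pixel statistics of natural images, nuisance
backgrounds, or label noise. Passing tests on these data demonstrate
that the plumbing and the scoring mathematics are correct — not that any
particular AUROC will transfer to real corpora.

## The reference classifier and its output head

The trainable reference classifier is a multinomial logistic regression
optimized by minibatch AdamW (learning rate $10^{-3}$, batch size 256,
decoupled weight decay $10^{-2}$) on the cross-entropy loss, with one
checkpoint per epoch carrying its held-out accuracy. Its penultimate
features are the inputs themselves, so the Mahalanobis score sees the
raw feature space.

One genuinely open design choice deserves its own section: the logit
parameterization. A softmax likelihood only identifies logit
*differences*; any component shared across classes is invisible to
training, to accuracy and to MSP — but it is precisely what the energy
score reads. A plain linear head $f(x) = Wx + b$ ties that shared
component to the linear growth of $\|Wx\|$, so samples displaced far
from the data in a random direction get *larger* log-sum-exp, inverting
the energy score's intended behavior. Deep networks do not behave this
way: their logit norms collapse off-manifold, which is why the energy
score tracks ID density in practice. The reference classifier therefore
uses a *radial softmax* (Gaussian-discriminant) head,
$f(x) = Wx + b - \tfrac12\|x\|^2$: for unit within-class covariance
this is the discriminant-function vector of a generative Gaussian
classifier ($w_c = \mu_c$, $b_c = -\tfrac12\|\mu_c\|^2 + \log \pi_c$
recovers the Bayes rule), its log-sum-exp approaches the log mixture
density, and training, accuracy and MSP are provably identical to the
linear head (the shared term cancels in the softmax — a tested
invariant). A plain linear head remains available
(`linear_adapter()`, `head = "linear"`), and the adapter contract
accepts any external classifier exposing `features()` and `logits()`.

A consequence worth knowing: with the radial head and a modestly trained
$W$, the energy confidence is dominated by the radial density term, so
EBM behaves like a (less sharp) relative of MAH and improves little with
classifier accuracy, while MSP — which sees only logit differences —
remains the weakest far-OOD detector and keeps a high FPR95 at every
shift. Both behaviors are visible in the shipped sweeps.

## Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `temperature` | 1 | positive real | the conventional energy-score temperature; as $T \to 0^+$ the energy ranking converges to max-logit (tested at $10^{-3}$) |
| `reg_eps` | $10^{-6}\,\mathrm{tr}(\hat\Sigma)/d$ | variance units | scale-aware diagonal load before inversion; keeps the zero-covariance degenerate case invertible without distorting well-conditioned fits |
| `tied` | `TRUE` | — | one pooled within-class covariance $\hat\Sigma = \sum_c S_c / N$ (the operative single-$\Sigma$ form); per-class covariances behind `tied = FALSE` |
| `ratios` | 0.70/0.15/0.15 | fractions | the ID1/ID2/ID3 protocol; stratified per class by default so no class is empty in ID2 |
| `mean_scale` | 3 | feature units | class-separation-to-noise ratio of the synthetic population |
| `shift_grid` | 0, 1, 2, 4, 8 | feature units (isotropic SDs) | spans chance to near-saturation for every score |
| `epochs` | 60 | — | past accuracy saturation for the default population; checkpoints 1–60 span chance to converged |
| `id2_n_total` | 150 | samples | small enough that uniform-random profiles starve some classes, making MAH's imbalance sensitivity visible |

## Numerical and convention choices

* **Ties at the threshold**: a sample with score exactly at the
  threshold is predicted ID. Fixed so every metric is exactly testable.
* **AUROC**: trapezoidal integration over the threshold sweep; with the
  tie convention this equals the Mann–Whitney statistic
  $P(s_{ID} > s_{OOD}) + \tfrac12 P(s_{ID} = s_{OOD})$, verified
  exactly against a pairwise oracle and against an independent ROC
  implementation.
* **FPR95**: value of the step-function ROC at the largest threshold
  whose TPR reaches the level; no interpolation.
* **Youden ties**: broken toward higher TPR, then higher threshold; in
  the perfectly separable case this returns the lowest ID score with
  operating point (TPR, FPR) = (1, 0).
* **Quantiles**: linear interpolation between order statistics (R type
  7), stated because boxplot conventions differ.
* **Largest-remainder rounding** everywhere counts must sum exactly
  (profiles, splits), ties to the lower index.
* **Degenerate inputs**: zero within-class covariance yields point-mass
  classes; fitting then requires `reg_eps > 0` and the error message
  says so. Classes with fewer than two samples abort the fit by default;
  `drop_small = TRUE` excludes them instead, which is the mechanism the
  imbalance experiment exercises (a starved class simply vanishes from
  the Gaussian mixture, degrading MAH coverage of that class's test
  samples).
* **Determinism**: every generator and experiment is a pure function of
  its spec and seed; sub-streams are derived per pipeline stage so ID
  draws, OOD draws, splits and subsampling are mutually independent.
  RNG state of the caller is always restored. Exact bit-reproducibility
  of *training* across hardware is not promised, only statistical
  reproducibility of accuracies.

## Experiment design

All three experiment axes freeze the test set per seed before any loop,
so methods and conditions are contrasted on identical samples. The
accuracy axis uses a 15-checkpoint sequence of one model (undertrained
through converged) rather than independently trained networks; the
out-of-domainness axis replaces a suite of real OOD datasets with the
$\delta$ grid; the imbalance axis refits only the Mahalanobis model per
ID2 profile while classifier and test set stay fixed — by construction,
MSP and EBM score files are then *bit-identical* across profiles, which
the tests assert exactly rather than statistically.

Problem sizes were chosen once for the package's test conditions: 1,000
ID samples across 10 classes per replicate, 200 OOD samples per
condition, 5 replicate seeds for sweeps and 12 for the imbalance
contrast, and a 10,000 + 10,000 Monte-Carlo check of the $\delta = 0$
null. These sizes put sampling error well inside the asserted bands
while keeping the full suite and the acceptance script in the
tens-of-seconds range on one CPU.

## Known limitations

* The synthetic features satisfy the Mahalanobis model exactly, so MAH
  is evaluated on home turf; real penultimate features are only
  approximately Gaussian and real covariances are ill-conditioned in
  high dimension. Relative method rankings here should not be read as
  predictions for any particular real corpus.
* The radial-softmax head gives the energy score a density
  interpretation by construction; classifiers whose logit geometry
  differs (e.g. heavily weight-decayed linear probes) can invert the
  energy score's response to far OOD, as documented above.
* The accuracy axis spans checkpoints of one linear model; architecture
  effects (the interesting comparisons among deep networks of different
  capacity) are out of scope.
* Scores are computed from a single layer; multi-layer feature
  ensembling, input preprocessing, and relative-Mahalanobis corrections
  are deliberately not implemented.
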