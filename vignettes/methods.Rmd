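---
title: "Multilayer graph-regularised dictionary classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer graph-regularised dictionary classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepdict)
```

## The model

`deepdict` represents a feature vector $z \in \mathbb{R}^c$ through a stack
of dictionaries $D_1,\dots,D_M$ with an elementwise activation
$\vartheta$ applied strictly *between* dictionary applications:

$$ z \;\approx\; D_1\,\vartheta\!\big(D_2\,\vartheta(\cdots D_M b)\big),
   \qquad \lVert d \rVert_2^2 \le 1 \ \text{for every atom } d .$$

Columns are samples throughout: the data matrix $Z$ is $c \times N$, the
final-layer code matrix $B$ is $K_M \times N$. For $M = 1$ the model is
plain sparse coding, $Z \approx D_1 B$, with no activation anywhere.

Joint training minimises

$$ J \;=\; \lVert Z - D_1\vartheta(D_2\vartheta(\cdots D_M B))\rVert_F^2
   \;+\; \lambda_1 \lVert B\rVert_1
   \;+\; \lambda_2\, \mathrm{Tr}(B^\top L B)
   \;+\; \lambda_3\, \ell_{\mathrm{sm}}(\theta, B, H)
   \;+\; \lambda_{lc} \lVert B - S H\rVert_F^2 $$

over $\{D_m\}$, $B$, the softmax parameters $\theta \in \mathbb{R}^{C\times
K_M}$ and the prototypes $S \in \mathbb{R}^{K_M \times C}$. Here
$\ell_{\mathrm{sm}}$ is the mean cross-entropy of the linear softmax head
$g_c \propto \exp(\theta_c^\top b)$ over the $N$ samples (per-sample
averaging keeps the term scale-free in dataset size), and $H$ is the
one-hot $C \times N$ label matrix. Inner codes $B_1,\dots,B_{M-1}$ are not
free variables: they are determined by the decode composition, so only
$B_M$, the dictionaries, $\theta$ and $S$ are optimised.

The graph term is the package's central structural constraint. A
heat-kernel affinity over the *final-layer atoms*,

$$E_{ij} = \exp\!\big(-\lVert d_i - d_j\rVert^2/\sigma\big)
  \ \text{ if } d_i, d_j \text{ are k-NN (OR-symmetrised)},\ 0
  \text{ otherwise},$$

defines the Laplacian $L = \mathrm{diag}(E\mathbf{1}) - E$, and
$\mathrm{Tr}(B^\top L B) = \tfrac12\sum_{ij} E_{ij}\lVert B_{i\cdot} -
B_{j\cdot}\rVert^2$ pushes geometrically similar atoms toward similar usage
across samples. The membership test of a directed k-NN graph is
asymmetric; we symmetrise by OR (an edge exists if either endpoint selects
the other) because the smoothness identity — and hence positive
semidefiniteness of the penalty — requires a symmetric affinity. The
$K_M \times K_M$ Laplacian acts on code *rows* (atom-usage profiles); this
is the only dimensionally consistent reading of the penalty.

## Optimisation

* **Initialisation.** Layer 1 by per-class K-SVD (each class's
  sub-dictionary learned independently and concatenated in class order, so
  the initial dictionary has contiguous class blocks); layers $2,\dots,M$
  by K-SVD on the previous layer's codes, with the activation ignored at
  this stage. K-SVD itself initialises atoms from unit-normalised random
  data columns and purges near-duplicate atoms ($|\cos| > 0.99$) between
  sweeps — both standard housekeeping that avoids the rotated local minima
  a random-sphere start falls into. The OMP coding phase uses a nonzero
  budget of $\lceil K/10\rceil$ by default ($\ell_0$ for the K-SVD phases,
  $\ell_1$ for joint fine-tuning, since K-SVD needs explicit supports while
  joint optimisation needs subdifferentiability).
* **Alternation.** Each epoch: (a) a few proximal-gradient steps on $B$
  with the $\ell_1$ shrinkage as prox; (b) a chain-rule gradient step on
  every $D_m$ followed by projection of atoms onto the unit ball; (c) a
  gradient step on $\theta$ and the closed-form prototype update
  $S \leftarrow B H^\top (H H^\top)^{-1}$ (class-mean codes, absent classes
  left untouched); (d) periodically, an atom-graph rebuild. In full-batch
  mode every step passes a backtracking line search, so the recorded
  objective trace is non-increasing to within $10^{-8}$.
* **Monotone-safe graph refresh.** The objective treats $L$ as fixed
  between refreshes (a lagged evaluation of a graph that in truth depends
  on $D_M$). A rebuilt graph is adopted only if it does not increase the
  current objective; otherwise the old graph is kept until the next
  refresh (every `graph_refresh = 10` epochs by default). This
  trust-region-style guard preserves the monotonicity guarantee exactly
  while still letting the graph track the dictionary.
* **Stopping.** 300 epochs by default, early stop when the per-epoch
  decrease stays below $10^{-7}$ for 10 epochs; training aborts with a
  diagnostic if the objective exceeds $10^3$ times its initial value.
  Stochastic mode replaces the line searches with fixed-rate mini-batch
  steps (`learning_rate = 0.01`) and makes no monotonicity promise.

## Test-time encoding and prediction

A test sample $y$ is encoded by minimising
$\lVert y - \mathrm{decode}(b)\rVert^2 + \lambda_1\lVert b\rVert_1 +
\lambda_2' \lVert b - P\rVert^2$ with proximal gradient. The prior $P$
defaults to the mean training code with weight $\lambda_2' = 0$ (off);
the quadratic prior form is kept so a caller can switch it on. When the
prior is off the solver warm-starts from the convex $\ell_1$ fit against
the *linearised* stack (the product of the dictionaries with no
activation): the all-zero vector is a stationary point of the ReLU
objective — $\vartheta'(0) = 0$ kills the gradient — so a cold start at
zero would never move. The warm start also keeps test-time codes in the
same $\ell_1$ basin as the codes produced by the proximal updates during
training, which matters because the softmax head is fitted to the latter.
Prediction applies the softmax head to the code; argmax ties break toward
the lowest class index.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `n_layers` (M) | 3 | stack depth; accuracy saturates beyond ~3 layers on the synthetic sets |
| `n_atoms` | derived | atoms per layer; layer 1 rounded to a multiple of C for per-class init |
| `lambda1` | 0.1 | $\ell_1$ weight on codes (dimensionless) |
| `lambda2` | 0.1 | atom-graph smoothness weight |
| `lambda3` | 1 | softmax loss weight |
| `lambda_lc` | 0.1 | label-consistency weight; set 0 to ablate |
| `knn_k` | 5 | graph neighbour count |
| `sigma` | `"auto"` | heat-kernel bandwidth; median of squared k-NN distances, floored at $10^{-12}$ |
| `epochs` | 300 | full-batch alternation rounds |
| `graph_refresh` | 10 | epochs between graph rebuilds |
| `grid` | {0.001, 0.01, 0.1, 1, 10, 100} | candidate $\lambda$ values for grid search |

The $\lambda$ defaults are mid-grid values; `grid_search_lambda()`
evaluates cross-validated accuracy over the grid (all three weights tied by
default to keep the candidate set small; pairwise-tied and full-cube
searches are available) and breaks ties toward smaller weights.

The evaluation protocol is stratified five-fold cross-validation with a
70/30 per-class train/test split inside each fold: samples are first
partitioned per class into disjoint rotating blocks; fold $i$'s training
set draws $\lceil 0.7\,n_c\rceil$ samples per class from outside block
$i$, and everything else is the fold's test set. This honours the train
fraction exactly (e.g. 70/30 on balanced $n = 100$) while keeping the
rotation property of classic k-fold plans. `repeat_and_average()` and the
`cv` command repeat the whole procedure (10 times by default) and append
arithmetic-average rows.

Reported metrics are macro-averaged one-vs-rest precision, recall and F1,
overall accuracy, and balanced accuracy (mean per-class recall), all as
percentages. The balanced-accuracy column is labelled `balance`; it stands
in for the loosely specified "stability/balance" score family sometimes
reported alongside these metrics, being the only member of that family
consistent with accuracy-like magnitudes.

## The synthetic generator

`plant_model()` draws random unit-norm dictionaries chaining through
`dims` and assigns each class a contiguous block of final-layer atoms;
per-sample supports are random `sparsity`-subsets of the class block, so
class supports never overlap across classes. Coefficients are
*non-negative* ($0.5 + |g|$ with $g$ standard normal): with symmetric
signs the class-conditional mean code would be zero and no linear
classifier — including the softmax head the model trains — could separate
the classes from their codes, which would defeat the generator's purpose
of producing class-structured data. Non-negative codes also match the
ReLU decode semantics. A `smoothness` parameter correlates neighbouring
atoms' latent coefficients (AR(1) across the block ordering), emulating
codes that vary smoothly along an atom graph; `orthonormal = TRUE`
orthonormalises the planted dictionaries, giving an identifiable model for
recovery studies.

`sample_features()` decodes drawn codes through the planted stack and adds
Gaussian noise scaled to a requested SNR (default 20 dB).
`sample_images()` renders each sample as a smooth background ellipse plus
one Gaussian blob per active atom — position a deterministic function of
the atom index, size and eccentricity class-specific, amplitude following
the coefficient. The renderer exercises the full image pipeline and yields
linearly separable classes by design; it does **not** simulate MRI physics
(no bias fields, partial-volume effects, anatomy or scanner noise), so
passing tests demonstrate correctness of the machinery, not clinical
performance on real MRI. The default test fixture is 3 classes, $M = 2$,
$c = 64$, $K = (48, 36)$, sparsity 5, 20 dB SNR, 50 samples per class —
sizes chosen so the full suite runs in minutes on one CPU.

## Numerical choices

* Atom normalisation rescales only columns with norm $> 1$; zero columns
  stay zero. OMP breaks correlation ties toward the lowest atom index and
  stops early when the residual norm falls below $10^{-12}$.
* The $\ell_1$ encoder is monotone FISTA (momentum step rejected whenever
  it would increase the objective) with step size $1/\lVert D^\top
  D\rVert_2$, the spectral norm obtained by power iteration (100
  iterations, tolerance $10^{-10}$). Non-convergence at `max_iter` sets a
  warning flag on the result rather than raising an error.
* K-SVD replaces unused atoms with the worst-reconstructed training
  column; an all-zero data matrix leaves the dictionary untouched.
* Softmax probabilities are computed in the max-shifted form, so extreme
  logits cannot overflow.
* `sigma = "auto"` uses the median heuristic over directed k-NN squared
  distances; two identical atoms produce an affinity of exactly 1.
* Images: RGB collapses to Rec.601 luminance (0.299, 0.587, 0.114);
  intensities outside $[0,1]$ are linearly rescaled; vectorisation is
  row-major; 3-D NIfTI volumes are rejected with an instruction to slice.
* Serialisation stores every array bit-exactly with a format version;
  loading a mismatched version or a corrupt file raises an explicit error.

## Known limitations

* The stack operates on extracted feature vectors; there is no true
  convolutional weight sharing or pooling. A pretrained feature extractor
  can be plugged in through `feature_spec(kind = "external")`.
* Test-time encoding solves a nonconvex problem for $M > 1$; the
  linearised warm start makes it deterministic and empirically reliable
  but carries no global-optimality guarantee.
* Greedy OMP is exact only on well-conditioned instances (the test suite
  constructs its oracle-equivalence problems from a low-coherence
  two-basis dictionary with decaying coefficients; on generic coherent
  dictionaries greedy selection can be suboptimal — a property of the
  algorithm, not a defect of the implementation).
* The objective is nonconvex; monotonicity is guaranteed, convergence to
  a global optimum is not. Stochastic mode trades the monotonicity
  guarantee for speed.
* Class imbalance is handled only through stratification and macro
  averaging; there is no cost-sensitive loss.
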