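---
title: "Metaheuristic tuning of lightweight CNNs for histopathology classification"
author: "HistoTuneR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaheuristic tuning of lightweight CNNs for histopathology classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HistoTuneR)
```

## The problem

Histopathological images of lung and colon tissue fall into five
diagnostic categories (colon adenocarcinoma, benign colon, lung
adenocarcinoma, benign lung, lung squamous-cell carcinoma). HistoTuneR
implements a desk-scale version of a classification pipeline for such
images in which every architectural and training hyperparameter that
matters is chosen by a population metaheuristic rather than by hand:
the Al-Biruni Earth Radius (BER) algorithm tunes a lightweight
convolutional feature extractor, and the Coati Optimization Algorithm
(COA) tunes a convolutional-recurrent classifier head. The tuning
objective throughout is the validation classifier error rate,

$$\mathrm{fitness}(x) = \frac{\#\,\text{misclassified}}{\#\,\text{total}}
\times 100,$$

minimized; all reported metrics are percentages.

"Desk scale" is a deliberate design point: every stage runs on one CPU
in minutes, using a synthetic hematoxylin-and-eosin-like image
generator as the data source, so that the complete pipeline — data,
optimizers, networks, tuning, evaluation — is exercised and tested
end-to-end without any external download.

## The feature extractor

The extractor stacks one unit per stage:

1. a 1x1 pointwise convolution changing the channel width,
2. a channel shuffle (reshape channels to `(g, C/g)`, transpose,
   flatten) so information crosses group boundaries,
3. a depthwise 3x3 convolution, applied independently per channel,
4. a second 1x1 pointwise convolution,
5. an efficient channel attention (ECA) module,

followed by 2x2 max-pooling between stages. The depthwise-separable
decomposition is the computational point: for a feature map of side
$D_f$, kernels of side $D_k$, $M$ input and $N$ output channels, the
separable unit costs $Q_1 = D_f^2 D_k^2 M + D_f^2 M N$
multiply-accumulates against $Q_2 = D_f^2 D_k^2 M N$ for a standard
convolution, so

$$\frac{Q_1}{Q_2} = \frac{1}{N} + \frac{1}{D_k^2},$$

which approaches $1/9$ for 3x3 kernels as $N$ grows.
`separableConvCost()` exposes this identity and the test suite
cross-checks it against explicitly counted multiply-accumulates.

ECA computes one attention weight per channel: global average pooling,
a short 1D convolution across the channel axis (kernel length odd,
default 3, a tuned hyperparameter), and a sigmoid; the input map is
rescaled channel-wise. One ECA module is placed after each unit's final
pointwise convolution (the reference description is ambiguous between
one module per unit and one in total; per-unit is the reading
consistent with "after this layer" applying to the unit it closes).

**Random convolutional features.** The extractor weights are
He-initialized from a derived seed and held fixed; only the classifier
head is trained by gradient descent. Random convolutional features are
a well-established baseline, and holding them fixed makes the BER
search a pure architecture/training-rate search with a clean
interpretation: widths, ECA kernel, learning rate and weight decay are
what change between trials, not a co-adapting weight state. It also
keeps every tuning trial cheap enough that full populations fit in a
CPU-minute budget. The cost is absolute accuracy: a fully trained
extractor would score higher on hard data. On the synthetic task this
regime is comfortably above chance, which is what the end-to-end
acceptance checks assert.

## The classifier head

The head follows the convolutional-recurrent pattern: conv blocks
(3x3 kernels, ReLU, 2x2/stride-2 max-pool, batch normalization,
dropout), after which the feature map is read as a sequence along the
width axis — each column is one timestep whose feature vector stacks
height x channels — into an LSTM; the last hidden state feeds a
64-neuron fully connected layer and a softmax over the five classes.
The reference text leaves the bridge between the extractor and the
recurrent head unspecified (its CRNN prose describes a two-class audio
setting); reading the width axis as "time" is the natural image
analogue and keeps the LSTM meaningful at small spatial sizes.

The loss is label-smoothing cross-entropy with mass $\varepsilon$
(default 0.1, tuned by COA in $[0, 0.2]$): the named but undefined
"LSR" loss is implemented as the standard smoothing regularizer, and
$\varepsilon = 0$ recovers plain cross-entropy exactly. Optimization
uses Adam with an L2 penalty added to the gradients; learning rate and
weight decay are tuned on log scales.

All forward and backward passes (im2col convolution, pooling, batch
normalization, dropout, LSTM backpropagation-through-time, Adam) are
implemented in vectorized base R inside the package and are verified
against central finite differences in the test suite at tolerance
1e-5.

## The BER optimizer

A population of agents $\vec S \in \mathbb{R}^d$ is split into an
exploration and an exploitation subgroup (default fraction 0.5, at
least one agent each). Per iteration:

- **Exploration.** Each explorer moves to
  $\vec S + \vec D \odot (2\vec r_2 - 1)$ with
  $\vec D = \vec r_1 \odot (\vec S - 1)$. The subtraction of 1 is
  applied elementwise, literally as printed in the source description
  (the alternative readings — all-ones vector versus a normalized
  leader — are not recoverable from the text).
- **Exploitation.** Each exploiter flips a fair coin between moving
  toward the leader, $\vec r_2 \odot (\vec S + \vec r_3 \odot (\vec L -
  \vec S))$, and searching around it, $r\,(\vec S^* + k)$ with
  $k = z + 2t^2/N^2$ and the Earth-radius coefficient
  $r = h \cos x / (1 - \cos x)$, $h \sim U[0,2]$,
  $x \sim U(0^\circ, 180^\circ)$. The source presents both strategies
  without a selection rule; an unbiased coin is the neutral choice.
- **Greedy acceptance and elitism.** A candidate replaces its agent
  only if strictly better; the best-ever record is refreshed after
  every acceptance, so the reported best-fitness history is
  non-increasing for every objective and seed.
- **Stagnation-triggered mutation.** If the best fitness improves by
  less than `stagnationTol` (default 1e-9) for `stagnationWindow`
  consecutive iterations (default 3), every explorer is replaced by
  $k z^2 - h\cos x/(1-\cos x)$ drawn independently per dimension, and
  the counter resets. Mutation replaces rather than perturbs — the
  mutation formula does not reference the current position.

The coefficient vectors $\vec r_1, \vec r_2, \vec r_3$ are i.i.d.
$U(0,1)$ redrawn per update; the source's description of them as
"measured by $\vec S(t)$" is not interpretable as printed. Angles are
resampled while $|1 - \cos x| \le 10^{-12}$ to guard the denominator.
Candidates are clipped to the box componentwise. The draw order of
every operator is documented in the code so that an independent scalar
transcription fed the same RNG stream reproduces a full iteration to
1e-12, which the tests verify.

## The COA optimizer

Each iteration has two phases over a population of $P$ coatis:

- **Phase 1 (iguana attack).** The first $\lfloor P/2 \rfloor$ agents
  climb toward the population best ("iguana"):
  $x_j + r_j(\mathrm{Iguana}_j - I_j x_j)$ with $r_j \sim U(0,1)$ and
  $I_j \in \{1, 2\}$ drawn per dimension. For each remaining agent a
  ground iguana is dropped uniformly into the box; the agent moves
  toward it if it is fitter, away otherwise. The ground iguana is a
  transient reference point generated fresh per agent — it never
  enters the population or the best-ever record, which the source ties
  to "the fittest member of the population". $r$ and $I$ are drawn
  before the branch so the random stream does not depend on which
  branch is taken.
- **Phase 2 (predator escape).** Every agent proposes
  $x_j + (1 - 2r_j)(lb_j/t + r_j(ub_j/t - lb_j/t))$: local bounds
  shrink exactly as $1/t$, equal to the global box at $t = 1$.
  Proposals are clipped to the global box — the local bounds only
  shape the step, a deliberate choice where the source is silent.

Acceptance is strictly greedy in both phases and the best is refreshed
after every acceptance, including between the phases.

## The tuning harness

Both optimizers search the unit box $[0,1]^d$; `decodeVector()` maps
coordinates into physical ranges — linear or base-10 log interpolation
for continuous dimensions, rounding half away from zero for integers,
equal-width bins for categorical choices. The default spaces are:

| stage | dimension | range | scale |
|---|---|---|---|
| BER / extractor | ECA kernel | {3, 5, 7} | categorical |
| | width multiplier | [0.25, 1.0] | linear |
| | learning rate | [1e-4, 1e-1] | log |
| | weight decay | [1e-6, 1e-3] | log |
| COA / head | LSTM units | [16, 128] | integer |
| | dropout | [0, 0.6] | linear |
| | batch size | {8, 16, 32} | categorical |
| | label smoothing | [0, 0.2] | linear |

The width multiplier scales the base stage widths (8, 16), rounded to
multiples of the shuffle group count; when a down-scaled stage is
narrower than the proposed ECA kernel, the kernel is clamped to the
largest odd value that fits (a dependent hyperparameter, not a failed
trial). Tuning is sequential, mirroring the reference flow diagram:
BER first (head held at its defaults), then COA with the BER-best
extractor fixed, which also lets all COA trials share one feature
computation. Each trial trains for a small fixed budget (default 5
epochs) as a fitness surrogate; the same derived training seed is used
for every trial, including the logged untuned-default baseline, so
fitness differences are attributable to the hyperparameters alone. The
validation set for fitness is carved from the training portion (80/20
by default); the held-out test portion is never touched until the
final evaluation.

## The synthetic data generator

Each class is a parameterized texture process emulating the statistics
of an H&E stain: a base colour from the pink/purple palette, a Poisson
number of elliptical "nuclei" (expected count `blobDensity * area`)
with class-specific eccentricity and a dark hematoxylin tone, an
oriented band-limited sinusoidal texture, and Gaussian pixel noise,
rounded to integers in [0, 255]. The five default classes differ in
all of these parameters; a single `difficulty` knob in [0, 1]
interpolates every class parameter toward the across-class mean, so 0
is separable by mean colour alone (a nearest-centroid baseline scores
essentially perfectly, which the tests assert) and larger values
degrade any classifier smoothly. The generator emulates the
class-per-folder directory layout of public histology archives and
round-trips losslessly through PNG (JPEG is supported for fidelity
with such archives).

What the generator deliberately does not model: real nuclear
morphology, stain-deconvolution physics, slide-level artefacts,
inter-patient variability, or any spatial correlation beyond blobs and
one texture band. Passing the end-to-end checks on this data therefore
demonstrates that the pipeline's machinery — optimization, feature
extraction, training, evaluation — works and interacts correctly, not
that the architecture would reach any particular accuracy on real
histopathology.

## Numerical choices and degenerate inputs

- Boundary handling is componentwise clipping everywhere, so tests can
  rely on accepted positions satisfying the box exactly.
- Greedy acceptance uses strict inequality; ties keep the incumbent.
- Non-finite fitness values become $+\infty$ with a warning, and a
  stagnation comparison between two infinities counts as no progress.
- A single global seed determines every stream via labelled 31-bit
  hashing (`deriveSeed()`); identical seeds give bit-identical runs.
- Batch normalization uses biased batch variance in training and
  exponential running statistics (momentum 0.9) at inference; dropout
  is inverted. 0/0 metric ratios are reported as 0 and flagged;
  undefined one-vs-rest AUCs (a class absent from the truth) are
  excluded from macro averages only.
- Problem sizes: the packaged end-to-end runs use 5 classes x 64
  images at 32x32 pixels, difficulty 0.2, optimizer budgets of 5
  agents x 5 iterations, 5-epoch trials and a 15-epoch final fit —
  sizes chosen so a full tuned pipeline completes in about two CPU
  minutes while every pipeline stage still does real work. Optimizer
  benchmarks use the 5-dimensional sphere function on $[-5,5]^5$ with
  20 agents for 200 iterations.

## Worked example

```{r example, eval = FALSE}
spec <- syntheticSpec(imagesPerClass = 64, imageSize = 32,
                      difficulty = 0.2, seed = 101)
res <- runFullPipeline(spec, splitRatio = 0.8, seed = 101)
res$testAccuracy
reportTable(res$reports$test)
```

The result bundles both split reports (five class rows plus the macro
`Average` row, with one-vs-rest accuracy, precision, recall, F-score
and AUC in percent), the tuned and default validation errors, the full
trial logs of both optimizers, and the final model handles.

## Known limitations

- The extractor is a fixed random-feature map; accuracy ceilings on
  hard or real data are below those of end-to-end trained weights.
- The pure-R training engine is single-threaded and sized for small
  images; it is a correctness-first implementation, not a performance
  library.
- BER's exploration move subtracts 1 elementwise as printed in its
  source; on boxes far from the unit scale this biases exploration
  toward the point $(1, \ldots, 1)$, which is worth knowing when
  reusing the optimizer outside the unit-box tuning harness.
- Only box constraints are supported, subgroup sizes are fixed, and
  the two optimizers are not hybridized — each tunes its own stage.
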