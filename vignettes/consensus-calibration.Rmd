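---
title: "Calibrated consensus prediction of missense-variant effects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated consensus prediction of missense-variant effects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpconsensus)
```

## The model

A missense-variant effect predictor emits, per amino-acid substitution, a
binary class call — deleterious or neutral — and a confidence on a scale
of its own choosing: a continuous score, or a small set of categorical
grades. `snpconsensus` combines several such predictors under one
assumption: *a tool's confidence is worth exactly what it has historically
delivered*. On a labelled benchmark we estimate, per tool and per
predicted class, the observed accuracy as a function of the reported
confidence, and we use that observed accuracy — not the raw score — as
the tool's weight.

For a mutation evaluated by $N$ tools (those that answered; tools may
abstain), each contributes a sign $P_i$ (+1 for a deleterious call, −1
for neutral) and its calibrated confidence $C_i \in [0, 1]$:

$$\mathrm{score} = \frac{1}{N}\sum_{i=1}^{N} C_i\, P_i \in [-1, +1].$$

Scores in $[-1, 0]$ call neutral and scores in $(0, +1]$ call
deleterious; a score of exactly zero is a tie and is deliberately
resolved to neutral (the closed end of the neutral interval), the
conservative choice for a pathogenicity screen. $|\mathrm{score}|$ is the
consensus classifier's own raw confidence and is itself calibrated to
observed accuracy by the identical procedure, so the confidence a user
sees for a consensus call is directly interpretable as "fraction of such
calls that were correct on the benchmark".

Averaging over the $N$ *available* tools, rather than substituting a
placeholder for absent ones, is a deliberate design choice: it lets the
consensus return a prediction for every mutation even though individual
tools abstain, without biasing the score toward either class. The
alternative — a fixed denominator of six with zero-filled gaps — would
shrink |score| for sparsely covered mutations, conflating "tools
disagree" with "tools were silent".

## Calibration: binned observed accuracy

Continuous confidences are calibrated per (tool, predicted class)
stratum:

1. sort the stratum's labelled predictions by raw confidence (stable,
   with the mutation key as tie-breaker, so the fit is invariant to input
   order);
2. partition into `n_bins` equal-count bins (default **60**; when the
   record count is not divisible, the first `n %% n_bins` bins take one
   extra record — a deterministic rule);
3. compute each bin's raw accuracy (fraction correct) and representative
   confidence (mean raw confidence of its members);
4. smooth the accuracies with a centered moving average over
   `smooth_window` bins (default **5**, odd; the window truncates at the
   curve ends, so bins 1 and 60 average over 3 bins);
5. evaluate the curve by piecewise-linear interpolation between the
   representatives, clamped to the first/last bin value outside the
   fitted range.

Categorical confidences need no binning: the calibrated value is the
exact per-category, per-class fraction correct. Tools in the
three-class mould (neutral / possibly deleterious / deleterious) are
coerced at parse time: the middle class becomes a deleterious call
carrying a reserved category token whose calibrated value is pinned at
0.5 — a maximally uncertain deleterious vote — rather than estimated
from data.

Parameters that matter, and their defaults:

| parameter | default | meaning |
|---|---|---|
| `n_bins` | 60 | resolution of the confidence axis; more bins = finer curve, noisier per-bin estimates |
| `smooth_window` | 5 | bins averaged per smoothed point; wider = smoother, more edge bias |
| `min_per_bin` | 5 | small strata use `floor(n / min_per_bin)` bins (≥ 1) instead of failing |

With 60 bins and window 5 a stratum of $n$ records estimates each
smoothed point from roughly $5n/60$ records; at benchmark scale
($n \sim 10^4$) the per-point standard error is below 0.02.

### Numerical choices

* **Centered window.** The smoothing window is centered on each bin;
  a trailing window would systematically shift the curve along the
  confidence axis.
* **Edge truncation.** At the curve ends the window truncates rather
  than pads; padding with replicated edge bins would double-weight
  exactly the bins with the most extreme accuracies.
* **Ties across bin boundaries.** Heavily tied raw scores can give two
  bins identical representative confidences; such bins are merged by
  record-weighted mean so the curve's x-values stay strictly increasing
  and interpolation stays well defined.
* **No monotonicity enforcement.** Fitted curves are *not* isotonized;
  a non-monotone stretch is evidence about the tool, not a numerical
  artifact to be smoothed away. Monotonicity is a property we verify on
  well-behaved simulations, not a constraint we impose.
* **Score orientation.** Raw values are binned ascending regardless of
  the tool's convention (some tools score low = damaging); the fitted
  per-class curve carries the orientation, so no manual re-orientation
  is needed or wanted.
* **Degenerate inputs.** An empty (tool, class) stratum simply yields no
  entry, and later lookups fail loudly naming the tool and class; a
  stratum smaller than `n_bins × min_per_bin` reduces its bin count; a
  single-bin curve calibrates to a constant.

## Evaluation

Benchmark class proportions are arbitrary, so headline metrics are
computed on a *normalized* confusion matrix: each true-class row is
rescaled to half the total, leaving sensitivity and specificity intact.
Normalized accuracy is therefore the balanced accuracy,
$(\mathrm{sens} + \mathrm{spec})/2$, and MCC is computed from the
reweighted counts (with the usual 0 convention when a marginal
vanishes). AUC is the mid-rank Mann–Whitney statistic,
$P(s_\mathrm{pos} > s_\mathrm{neg}) + \tfrac12 P(\mathrm{tie})$, which is
invariant under the class reweighting and under any strictly increasing
transform of the scores, so it is computed once from raw scores. Tools
are scored only over the mutations they evaluated, with coverage
reported alongside — folding abstentions into the error rate would
conflate two different failure modes.

Inter-tool agreement is the phi coefficient (Pearson correlation of the
binary call vectors) over mutations both tools evaluated. Composition
bias of a dataset is summarized by tallying wild-type and mutant residues
separately against expected background frequencies and pooling the 40
observed-vs-expected pairs into one Pearson coefficient (pooling, rather
than averaging two per-side coefficients, weights both sides equally and
was chosen for simplicity; the per-residue fold deviations are reported
so either view can be reconstructed).

## Benchmark construction and leakage removal

Meaningful evaluation requires that no benchmark mutation — indeed no
benchmark *position* — appear in a predictor's training data, because
most predictors use position-specific evolutionary features. The builder
pipeline is: concatenate labelled sources → purge every mutation key
annotated both neutral and deleterious (both records go; a coin-flip
would inject label noise) → deduplicate (the survivor's source field
lists all contributing sources, sorted, making the result independent of
concatenation order) → remove every mutation at a position overlapping
the reference sets.

A query position *overlaps* a reference position when the two proteins
share an identifier and position (direct overlap), or when an alignment
fragment with e-value ≤ 1e−10 and identity ≥ 50% (inclusive — "at
least") maps the positions onto each other *through its alignment
columns*. Column-mapped correspondence is the stricter of the two
readings of "located in an aligned fragment" (the laxer one would flag
every position inside the fragment), and is unambiguous.

Two aligner backends satisfy the same interface: a reader for standard
12-column BLAST tabular output, and a built-in Smith–Waterman aligner
(BLOSUM62, gap open 11 / extend 1) for desk-scale work. Two
approximations are documented rather than hidden: (a) the tabular format
carries no per-column alignment, so ungapped fragments get a linear
position map and *gapped* fragments are treated conservatively — every
position in a qualifying fragment counts as overlapping, which can only
remove more, never fewer, mutations; (b) the built-in aligner has no
e-value model, so a minimum fragment length (default 30 columns) stands
in for the significance filter.

Activity-based labelling rules for experimental sources: a record whose
annotation set is exactly `{=}` (no activity change) is neutral; any
other annotation set without `=` is deleterious; a set containing `=`
*plus* another token is contradictory and excluded. Where a quantitative
activity change is available, changes strictly greater than 50% are
deleterious — the boundary value 0.5 is neutral, following the strict
reading of "larger than".

## The simulator

The simulator exists so that calibration, consensus and evaluation are
testable end to end with known ground truth. Each simulated tool draws a
confidence from a class-conditional distribution (uniform or beta), is
correct with probability given by its accuracy curve (constant, identity
$P(\mathrm{correct}\mid c) = c$, or logistic), abstains at its missing
rate, and — the one ensemble-level knob — shares a per-mutation latent
difficulty: with probability $\rho$ a tool's correctness is decided by
the shared latent uniform, otherwise by an independent draw. This leaves
every marginal accuracy exactly at its profile value, makes $\rho = 0$
exactly conditional independence (with a closed-form expected phi used
as a test oracle), and induces increasing positive correlation as $\rho$
grows. Random streams are sub-seeded per tool name, so adding a profile
never perturbs the other tools' draws.

One profile field deserves a note: a "class bias when wrong" is only
meaningful when the truth is unknown — for a labelled mutation a wrong
binary call is necessarily the opposite class. The bias therefore
applies only to mutations labelled `unknown`, where it sets the
deleterious-guess probability.

The default six-tool ensemble spans marginal accuracies ≈ 0.65–0.75
(the range typical of individual state-of-the-art predictors on
independent data), mixes four continuous and two categorical tools,
sets $\rho = 0.2$ (weak positive correlation, as observed between real
predictors built on partly shared evolutionary signal), and spreads
missing rates from 0 to 40% with the strongest tool always answering.
These defaults are the package's standing study conditions, not tuning
knobs.

**What the simulator does not emulate** — and hence what passing tests
do *not* show about real data: real tools' score distributions and their
sequence-dependent failure modes (shared homologs, alignment depth),
label noise in curated databases, non-stationary class balance across
protein families, and correlation structure beyond a single shared
difficulty factor. Tests demonstrate that the machinery is correct and
that the method behaves as designed under its stated assumptions; they
are not a claim about accuracy on any real benchmark.

## Problem sizes and determinism

The shipped tests and the acceptance script use ensembles of 20,000
mutations (split in half for calibration vs. evaluation), 60,000 records
for calibration-recovery checks, and exhaustive small fixtures for exact
oracles — sizes at which binomial noise sits comfortably below the
asserted tolerances (e.g. a fitted curve within 0.05 of a known identity
relationship, a consensus-over-best-tool gain of at least 0.02). Every
stochastic quantity is reproducible bit for bit from a single integer
seed.

## Known limitations

* Calibration accuracy is bounded by benchmark size: strata thinner than
  a few hundred records yield coarse curves (mitigated, not solved, by
  bin-count reduction).
* The consensus assumes tool errors are not strongly correlated; six
  copies of the same predictor would calibrate beautifully and vote
  uselessly. The phi-correlation report exists precisely so users can
  check this assumption on their own tool set.
* Piecewise-linear interpolation with end clamping cannot extrapolate:
  raw confidences outside the fitted range are assigned the edge bin's
  accuracy.
* The builder guarantees independence only with respect to the reference
  sets it is shown, under the alignment backend's sensitivity; remote
  homology below the fragment thresholds is, by construction, not
  flagged.
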