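---
title: "Measuring story and schema representations at encoding and recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring story and schema representations at encoding and recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schemarep)
```

## The problem

When people experience a naturalistic event that follows a familiar script
— eating at a restaurant, catching a flight — their memory for the
specific episode is supported both by *story-specific* representations
(what happened in this particular narrative) and by *schematic*
representations (the abstract script shared by all narratives of that
kind). `schemarep` quantifies both kinds of representation in
multivariate neural activity patterns, separately during encoding
(watching/listening) and during free recall, and relates them to a
behavioral measure of how many story details a person later recalls.

The paradigm the package models: 16 narratives, half following a
restaurant script and half an airport script, half presented as video and
half as audio, each built from the same four ordered schematic events
(e.g. entering the restaurant, being seated, ordering, eating). Subjects
encode all 16 stories (about 3 minutes each, preceded by a short
countdown) and later freely recall each story from its title alone, at
their own pace. Recall transcripts are scored against a rubric and
normalized to a fraction of recallable details in [0, 1].

## The measures

**Event patterns.** For each story, a design matrix with one boxcar
regressor per schematic event (plus a countdown nuisance regressor) is
convolved with a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
undershoot ratio 1/6, 30 s support, peak-normalized; `hrf_kernel()`),
z-scored column-wise, and fit by OLS to every vertex's timeseries
(`fit_event_patterns()`). The K = 4 event betas form the story's spatial
pattern sequence. Convolution is done at TR resolution: events last tens
of seconds, far above the 1.5 s TR, so microtime upsampling would change
nothing that these analyses measure.

**Encoding similarity.** Story-by-story similarity for a subject is
computed against leave-one-subject-out group templates: the other N−1
subjects' timeseries are averaged and *then* fit by the GLM (the quoted
order; with shared designs it coincides with averaging betas, by
linearity of OLS). Similarity of story A to story B is the mean over
events k of the Pearson correlation between the event-k patterns
(`pair_similarity()`), giving a 16 × 16 matrix per subject
(`across_subject_matrices()`). A within-subject variant
(`within_subject_matrix()`) compares a subject's stories to their own
other stories; its diagonal is identically 1, so a story score is
undefined there and the package refuses to compute one.

**Reinstatement.** Recall is unconstrained, so encoding patterns cannot
be aligned to recall by the clock. Instead a fixed-template ordered-state
HMM (`hmm_posterior()`) assumes the four encoding event patterns are
replayed in order: the chain starts in event 1, ends in event K, and can
only stay or advance. Emissions are isotropic Gaussians on
vertex-z-scored vectors with variance equal to the pooled variance of the
template's raw betas (`estimate_variance()`); the posterior is exact
forward–backward in log space, with the end constraint imposed by
initializing the backward pass with mass only on state K. The
self-transition probability defaults to `1 − (K−1)/(T−1)`, which makes
the expected number of advances over a T-timepoint recall exactly K−1.
Posterior-weighted recall patterns are correlated with the template, and
reinstatement strength is the mean advantage of corresponding over
non-corresponding events (`reinstatement_strength()`). Group templates
average betas across **all** participants (as the within-vs-across
variants are defined; a leave-one-out toggle exists).

A property worth stating plainly: applied to pure-noise recalls, this
measure is *not* zero-mean — the HMM prefers segmentations that resemble
the template, so the corresponding-event correlation is positively
biased. The bias is identical for every template (verified by an
ANOVA-style check across 16 templates on noise), which is exactly why
all downstream inference uses *contrasts* between templates (story and
schema scores) rather than raw strengths.

**Scores.** For each story: the *story score* is its self-similarity
minus its mean similarity to other same-schema, same-modality stories;
the *schema score* is the mean similarity to other same-schema stories
minus other-schema stories (same modality); an *across-modality schema
score* uses only other-modality comparisons. Group inference uses
permutation nulls: story identities shuffled within schema × modality
cells, or schema labels shuffled within modality. Two numerical points
discovered while building the nulls, both documented in the function
help: (1) the story relabeling must be applied to the subject's own axis
only — relabeling both axes of the similarity matrix leaves the
group-mean story score algebraically unchanged, a degenerate null; (2)
for group-level inference on across-subject matrices we share one
relabeling across subjects per draw (`shared = TRUE`), because
leave-one-out templates couple subjects' matrices: with independent
per-subject relabeling the null is too narrow and rejects a true null
~12% of the time at α = 0.05. The per-subject scheme remains the default
of `permutation_null()` for compatibility with vertex-map nulls, which
shuffle separately per participant.

**Behavior models.** `loso_regression()` fits, per left-out subject, an
intercept-and-slope regression of rubric scores on a neural score pooled
over the training subjects' story-recalls, and evaluates held-out
predictions by R² against the training-mean baseline (negative R² is
preserved, not clipped). Its permutation p shuffles neural scores within
subjects, so significance reflects within-subject, across-story
coupling. `nested_f()` asks whether schema scores explain behavior
beyond story scores (F on pooled SSEs with a within-subject permutation
null); `coefficient_contrast()` compares encoding vs reinstatement
slopes with a sign-flip null; `predict_target_from_maps()` regresses one
region's score on every searchlight's score with a shared
within-subject shuffle. Fold fits use closed-form OLS; `lm()`/`anova()`
serve as independent oracles in the tests.

**Maps, clusters, mediation.** Searchlights are BFS balls on a vertex
adjacency graph (default 11 steps ≈ 15 mm at 1.4 mm spacing), sampled at
random centers, kept if they hold ≥ 100 valid vertices, until every
vertex is covered ≥ 10 times; synthetic ring and triangulated-grid
meshes ship as generators. Searchlight values and their nulls are
averaged back to vertices, converted to two-sided permutation p-values
and Benjamini–Hochberg q-values. Conjunctions intersect positive
supra-threshold sets (schema effect at FDR < 0.001 with subsequent-memory
effect at FDR < 0.05). The hippocampal long-axis split assigns the
boundary plane y = −20 to the posterior segment. Regional subclustering
stacks eight per-vertex result maps and picks k by mean silhouette over
k-means solutions with 50 restarts (k below the number of features);
`mediate()` fits the standardized single-mediator model, for which
c = c′ + a·b is an exact algebraic identity, and tests the indirect
effect with a bias-corrected (BC, not BCa) percentile bootstrap.

## The synthetic study generator

Real group maps depend on a specific fMRI dataset and its preprocessing;
at desk scale the package validates by *parameter recovery* instead. The
generator (`simulate_study()`) plants exactly the structure the measures
assume. Each subject's event pattern for story i is

  P = a·G(schema, event) + d·S(story, event) + γ·M(modality, event) + η,

with G, S, M i.i.d. standard-normal vertex patterns, per-subject
fidelities a (schema) and d (story), and pattern noise η. Encoding
timeseries are the z-scored convolved design times these patterns plus
white temporal noise — by construction the GLM inverts it exactly when
noise is zero. Recall emits each event's pattern scaled by a
reinstatement fidelity r over a random number of TRs per event, in
order, without HRF convolution (the reinstatement measure is
convolution-agnostic, and direct emission keeps the generator an exact
oracle for the HMM). Behavior is `clip(b0 + b_schema·a + b_reinst·r +
noise, 0, 1)`, returned with the planted coefficients.

Default conditions mirror the study: 16 stories (4 per schema × modality
cell), 4 events, 45 s events, 5 s countdown, TR 1.5 s, 30 subjects, and
a planted behavior model `0.2 + 0.3·a + 0.3·r + N(0, 0.1²)`. Defaults
chosen where nothing is dictated: fidelities a, d, r ~ Beta(2, 2) (spans
[0, 1] with interior mass), γ = 0.3, pattern noise sd 0.5, temporal
noise sd 1, recall noise sd 1, 200 vertices per simulated region (above
the 100-vertex searchlight minimum), recall event durations uniform on
5–15 TRs (the durations' distribution is a free parameter; unpaced
recall motivates a broad range). All draws flow from one root seed
through named substreams (`substream_seed()`), so e.g. regenerating
temporal noise never changes the planted patterns.

What the generator does *not* emulate: hemodynamic nonlinearity, motion,
scanner drift beyond white noise, spatial autocorrelation, modality
differences in SNR, or rubric scoring noise structure. Passing recovery
tests therefore shows the estimators are correct and calibrated under
the planted model, not that real BOLD obeys that model.

## Worked example

```{r example, eval = FALSE}
study <- simulate_study(seed = 1, n_subjects = 30)
patterns <- fit_study_patterns(study$encoding)
enc_sims <- across_subject_matrices(study$encoding, patterns)
tab <- score_table(enc_sims, study$design)

obs <- mean_score(enc_sims, study$design, "schema")
null <- permutation_null(enc_sims, study$design, "schema", "schema",
                         n_perm = 1000, seed = 7, shared = TRUE)
z_vs_null(obs, null)

score_mat <- matrix(tab$encoding_schema, 30, 16, byrow = TRUE)
fit <- loso_regression(score_mat, study$behavior)
fit
loso_permutation_p(score_mat, study$behavior, n_perm = 1000, seed = 7)$p
```

## Numerical choices and edge cases

- Timestamps are seconds; the TR grid is 0-based; event intervals are
  half-open `[start, end)`; an event shorter than one TR, or spanning
  the whole run (constant boxcar), is an error.
- Constant vertices in `detrend_zscore()` are flagged invalid and
  zeroed rather than erroring; zero-variance patterns in correlations
  are errors naming the offending event.
- All HMM probability arithmetic is in log space with log-sum-exp; the
  forward–backward posterior is tested to 1e−8 against exhaustive
  enumeration of all monotone paths on small instances.
- Permutation p-values are plug-in proportions (no +1 smoothing):
  one-sided `#{null ≥ obs}/n`, two-sided `#{|null| > |obs|}/n`; a
  reported 0 means p < 1/n_perm. The paired coefficient contrast uses ≥
  on absolute values so that a degenerate all-zero contrast yields p = 1
  rather than 0.
- `mediate()` resolves perfect x–m collinearity by attributing the
  shared effect to the mediator (b = r_my, c′ = c − a·b), preserving the
  exact decomposition. Under a *complete* null (x, m, y mutually
  independent) the BC bootstrap test of a·b is conservative — the CI
  contains 0 in roughly 99% of runs — which is a known property of
  product-of-coefficients bootstraps; calibration is nominal under the
  partial null (a ≠ 0, b = 0), and that is the case the acceptance
  tests check.
- Mediation recovery is validated with unit-variance path construction
  (noise sds `sqrt(1 − a²)`, `sqrt(1 − b²)`), so planted *standardized*
  paths are exactly the nominal a and b and the planted indirect effect
  is a·b.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run the chain at reduced but
structurally faithful sizes, chosen once: recovery and calibration tests
use 16 stories with 6 s events (21 volumes), 2–5 subjects and 30–60
vertices; the null-calibration study repeats 200 simulated datasets at
n_perm = 200; power and mediation checks use the full 30 subjects × 16
stories with scores planted directly; the acceptance script runs the
complete pipeline at 30 subjects × 200 vertices with n_perm = 1000.

## Limitations

Single-region analyses in the synthetic world couple the contrast
scores (e.g. a high schema fidelity raises off-diagonal reinstatement
similarity and thereby *lowers* the reinstatement story score), so
pipeline-level mediation estimates on fully synthetic data can be
negative even when all planted couplings are positive; the planted-path
recovery in the acceptance script is the unconfounded check. No
mixed-effects models are fit (the LOSO permutation design absorbs
subject structure instead); no volumetric searchlights, surface
smoothing, registration, or learning of HMM templates from recall.
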