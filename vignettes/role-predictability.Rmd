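---
title: "Incremental semantic role predictability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental semantic role predictability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Comprehenders interpret sentences incrementally: as each word arrives they
assign and revise semantic roles — who is the agent (A, "the doer") and
who the patient (P, "the undergoer") of the event. Across typologically
very different languages, listeners prefer to interpret an ambiguous early
argument as the agent. How such a preference can be acquired from
child-directed speech is not obvious, because languages differ radically
in the cues they offer: a verb-initial language with symmetrical voice
marking, a rigid verb-medial language, and a verb-final case-marking
language with pervasive agent omission present entirely different
evidence to the learner.

`rolepred` quantifies *position-dependent role predictability*: the
probability that an incremental classifier, trained on naturalistic
child-directed utterances, assigns to an argument's correct role given
the sentence prefix consumed so far. The package provides the whole
analysis chain:

1. a data model for role-annotated utterance corpora (JSONL/TSV);
2. seeded generators for artificial-language corpora emulating the three
   archetypes (licensed child-language corpora cannot be redistributed);
3. the incremental semantic role prediction model (a recurrent network);
4. extraction of position-conditioned predictability records;
5. hierarchical Bayesian beta regression of those records on sentence
   position, role and language, with convergence diagnostics, pairwise
   language contrasts, PSIS-LOO model comparison and stacking.

# The semantic role prediction model

The model processes an utterance as a sequence of *elements*: each
annotated argument span is consumed as a single element, the verb span as
a single element, and every other token alone. Four components act on
this stream (all sizes configurable via `srp_config()`):

* **Token embeddings.** `learned` (trainable, the default),
  `hash_random` (fixed vectors derived deterministically from a hash of
  the surface string, so results never depend on external downloads and
  out-of-vocabulary items are impossible), or `pretrained_vectors`
  (fixed vectors from a word-vector text file). A trainable
  character-convolution mode is deliberately not implemented: in the
  original analyses subword embeddings outperformed the character CNN,
  and nothing downstream depends on it.
* **Sequential encoder.** An LSTM read over the tokens of one element;
  its final state is the element representation. Multi-token arguments
  ("the fox") are thus represented as wholes, not by their heads.
* **Sentence processor.** A second LSTM over element representations,
  carrying the sentence prefix.
* **Two one-hidden-layer classifiers.** The *next-word predictor* maps
  the processor state to a distribution over the vocabulary (the target
  for an element is the first token of the next element; end of sentence
  is a reserved symbol). The *role classifier* maps the concatenation
  `[argument encoding; processor state; verb encoding or zeros]` to a
  distribution over {A, P}. At every time point it re-classifies every
  argument seen so far, independently of the other argument's
  classification, so earlier interpretations can be revised ("the fox"
  first looks like an A; after "is hunted by the wolf" it is a P).

Both LSTMs, the classifiers and full backpropagation-through-time are
implemented in compiled code inside the package (no external deep
learning framework is required); the analytic gradients are verified
against central finite differences in the test suite.

**Training** happens in two stages. *Pretraining* fits only the next-word
pathway on unannotated adult-directed text, giving the processor basic
distributional knowledge. The *main stage* trains everything jointly:
role cross-entropy at the final sentence position (summed over the
utterance's arguments) plus `lambda` times the per-position next-word
cross-entropy. `lambda` defaults to 1 — joint training empirically helps
role classification, and no standard value exists. Optimization is
Adam, batch size 16, early stopping on validation role accuracy
(pretraining: validation next-word loss), best-epoch parameters returned.
`kfold_evaluate()` runs the standard 10-fold protocol: every utterance's
reported trajectory comes from a model that never saw it in training; the
non-test portion is split 90/10 into train/validation per fold.

An untrained model reports exactly 0.5/0.5 for every role because both
softmax output layers start at zero — a convenient calibration anchor
used by the tests.

# The synthetic languages

Real child-language corpora (and the adult conversation corpora used for
pretraining) are licensed and not bundled. `generate_cdu_corpus()`
fabricates corpora from a `language_spec()`: a distribution over the six
full orders of {A, P, V} (per voice where applicable), independent
per-role omission probabilities (rejecting the zero-argument outcome),
role marking, role-skewed pronoun realization, a Zipfian lexicon with
per-verb-class A/P noun pools — disjoint within a class but overlapping
across classes, so a noun's plausible role is cued by the verb rather
than globally (the cue strength is the `sel_strength` knob) — and
Poisson adjunct noise. Factorial stimuli are *reversible*: their nouns
are drawn uniformly, carrying no selectional cue, as in comprehension
experiments.

Three shipped presets encode the archetypes. Their omission rates and
1st/2nd-person pronoun rates were derived analytically from the
documented descriptive statistics; the free remainder of the verb-medial
preset (other-pronoun composition, per-voice omission, selectional
strength) was calibrated once so that the agent-preference and
reanalysis phenomena are demonstrable, and then frozen:

* `verb_initial_voice` — verb-initial orders dominate; a voice affix on
  the verb decides whether the subject-marked phrase is A or P; patient
  voice more frequent; frequent P omission (overt A share ≈ 0.60); A
  arguments mostly 1st/2nd person pronouns (rate ≈ 0.67).
* `verb_medial_rigid` — AVP dominates (≈ 75% of utterances A-initial); a
  rare passive (≈ 8%) realizes the patient first with an auxiliary on
  the verb and the demoted agent in an oblique marked phrase, and is
  predominantly agentless (per-voice omission override, as in spoken
  passives); A arguments are mostly speech-act pronouns while P
  arguments are often "it"-type pronouns, so lexical-noun tokens mirror
  the overt A-majority (≈ 0.63); the selectional-association knob is set
  low (0.2) so initial lexical nouns stay role-ambiguous before the
  verb — the calibration the reanalysis demonstration depends on.
* `verb_final_case` — verb-final orders dominate; accusative suffix on P
  usually present, nominative on A usually bare; agent omission so
  frequent (0.47) that "PV" is the most common overt pattern and the
  overt A share is ≈ 0.43, giving the characteristic inverted baseline.
* `verb_final_deterministic` — the case-marking preset with both markers
  applied with probability 1; the marker-to-role mapping is then a
  function, which makes held-out accuracy ≥ 0.95 a learnability oracle.

Derivation of the omission rates: with independent omission and
rejection of doubly-omitted draws, the overt A share is
$(1-o_A)\,/\,((1-o_A) + (1-o_P))$; solving for the target shares gives,
e.g., $o_A = 0.47, o_P = 0.30$ for the verb-final archetype.
`expected_pattern_distribution()` computes the implied overt-pattern
distribution in closed form and is the oracle for the statistical
fidelity tests (3 standard errors at n = 5000); the generator's
latent-draw log is the *exact* oracle for pattern counts.

What the generator does **not** emulate: discourse coherence and
information structure (omission is independent of context), prosody,
age grading, morphological fusion (markers are separate tokens by
default so token-level embeddings see the cue), and the long-tailed
lexical statistics of real speech beyond a simple Zipf law. A green test
on synthetic data therefore establishes that the pipeline recovers the
structure the generator put in — not that any particular natural
language behaves this way.

`generate_stimuli()` builds factorial, lexically matched experiment
analogues (voice × order × case conditions); both arguments are full
lexical nouns and case markers are always realized, mirroring the
structure of comprehension experiments in which stimuli are deliberately
cue-ambiguous or fully marked.

# Predictability records

`extract_records()` converts a trajectory into regression rows. An
argument is read off at its own first occurrence and at each subsequent
informative event — the other argument's occurrence and the verb's
occurrence — from the trajectory state *after* consuming that element
(so "after verb" includes the verb itself). Two binary flags code the
position: `after_argument` (the other argument precedes the read-off
point; always `FALSE` for single-argument utterances) and `after_verb`.
Flags accumulate: in AVP the agent contributes records with flags
(F,F), (F,T), (T,T) and the patient one record (T,T). Adjunct tokens are
never read-off points, so an argument contributes at most three records.
An exhaustive brute-force enumeration over all ten realizable overt
patterns backs this logic in the tests.

`baseline_accuracy()` is the proportional baseline: predicting labels at
random according to their empirical proportions yields, on items of a
given role, exactly that role's proportion (43% for A and 57% for P
under the verb-final archetype's overt-role distribution).

# The hierarchical beta regression

Records are probabilities in [0, 1]; the beta likelihood requires the
open interval, so responses pass through the standard compression
`(y(n-1)+1/2)/n` (`squeeze_to_open_interval()`); the package reports
near-boundary posteriors, so some such transform is unavoidable.

The model: `p_correct ~ Beta(mu*phi, (1-mu)*phi)` with `logit(mu)` a
linear function of the position flags, role, language, nominality and
verb class, including the full crossing
`after_argument*after_verb*role*language` (the bare four-way product
without lower-order terms is rank-deficient under treatment coding, so
the full crossing — which spans exactly the 16-cell basis — is the
default) plus `nominality:role`; by-sentence random intercepts and
slopes for the two position flags and role, non-centered. Priors:
Normal(0, 1) on slopes, Student-t(3, 0, 2.5) on the intercept and the
group standard deviations, and Half-Normal(0, 10) or Exponential(1) on
`phi` (selectable; the choice is recorded in the fit). Links: logit for
the mean, log for `phi`.

Sampling is a package-internal No-U-Turn sampler (multinomial proposals
with biased progressive sampling, the generalized momentum-sum u-turn
criterion, dual-averaging step size targeting `adapt_delta`, and
expanding diagonal-metric adaptation windows). Defaults: 4 chains ×
1,000 post-warmup draws — with the ESS > 400 rule this is the smallest
comfortable configuration at 100 draws-per-chain-equivalent per the
usual recommendation. Every fit computes rank-normalized split-R-hat and
bulk/tail ESS for every parameter; a fit violating R-hat < 1.01 or
ESS > 400 is flagged `converged = FALSE` with a loud warning (or an
error with `fail_on_diagnostics = TRUE`). Post-warmup divergences are
reported per chain. The pointwise log-likelihood matrix is retained, so
`compare_loo_stacking()` can compute PSIS-LOO elpd (generalized Pareto
tail smoothing with the Zhang–Stephens estimator, Pareto-k diagnostics)
and stacking weights maximizing the leave-one-out log score over the
simplex.

Cell means on the probability scale (`cell_means()`,
`posterior_epred()`) are population-level predictions (random effects at
zero, other factors at their reference levels), summarized as posterior
mean with 66% and 95% intervals; `pairwise_language_contrasts()` takes
draw-wise differences between languages within each role × position cell
and flags a contrast as `suppressed` when less than 95% of its mass lies
on one side of zero.

The variant with random slopes for the flag × role interaction — which
did not converge in the original analyses — is expressible by adding the
interaction to `group_slopes`, but is not a default.

# Numerical choices and degenerate inputs

* Spans are 0-based half-open; discontinuous argument spans are not
  representable and importers reject overlap, with the utterance id and
  field named in every schema error.
* Token surfaces are NFC-normalized UTF-8; case is preserved.
* Serialization is deterministic (stable key order and number
  formatting): writing the same corpus twice yields identical bytes, and
  a model checkpoint reloads to bit-identical trajectories.
* All generators and training runs are pure functions of their seed;
  seeds derived internally stay below 2^31.
* Single-level factors, unseen factor levels, empty corpora/batches and
  an utterance without a verb span raise immediate, named errors. A
  stimulus regression with a single item warns and drops the random
  effects rather than fitting an unidentifiable grouping variance.
* The softmax output layers are zero-initialized; LSTM forget-gate
  biases start at 1.

# Known limitations

* The regression's verb-class factor enters as a fixed effect
  (48 levels); with small synthetic corpora many classes are sparse, so
  the pipeline's default formula omits it and keeps nominality — the
  full set remains configurable.
* The NUTS implementation is diagonal-metric only; strongly correlated
  posteriors (e.g., very few groups with many observations each) mix
  more slowly than under a dense metric.
* PSIS diagnostics are reported but high Pareto-k observations are not
  refit exactly, unlike the reference R implementation of LOO.
* The agent-preference and reanalysis demonstrations are scaled-down
  qualitative replications on synthetic corpora; posterior magnitudes
  from licensed naturalistic corpora are out of scope by design.
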