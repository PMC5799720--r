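---
title: "laylink: methods, models, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{laylink: methods, models, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laylink)
```

# The problem

Patients increasingly read their own clinical notes. Those notes are dense
with jargon — disease names, drug brand names, acronyms, procedure
shorthand — and a large fraction of adults read below the level the notes
assume. laylink implements a dictionary-based comprehension aid: it finds
medical-term spans in note text and attaches *lay definitions*, together
with the tooling needed to build and grow such a definition lexicon
(term-importance ranking and synonym mining).

This vignette explains the models and procedures, the tunable parameters
and their defaults, what the synthetic-data generators do and do not
emulate, and the design decisions taken where the design was genuinely
open. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

# The annotation model

## Normalization

Two normalizations are distinguished on purpose:

- **Key normalization** (`normalize_key()`): Unicode NFC, lowercase, trim,
  collapse internal whitespace. Applied to everything stored — lexicon
  keys, class keys, vocabulary terms.
- **Surface normalization** (`normalize_surface()`): key normalization
  plus stripping a trailing possessive `'s` from each word. Applied only
  when a text span is compared against a dictionary, never to stored keys.

The split matters for possessive eponyms: "Cushing's syndrome" and
"Cushing syndrome" must reach the same concept record through exact
matching, without ad-hoc stemming. Consequently the concept table is
*indexed* by the surface normalization (rows that collide after stripping
must agree on their concept ID — the table's declared
one-concept-per-surface dialect), while the stored fields keep the key
form. Normalization is idempotent, which the property tests check on
random strings.

## Recognition

The recognizer is a deterministic stand-in for a full concept-recognition
engine (which would add lexical variants, derivational morphology, and
candidate scoring — explicitly out of scope). It tokenizes into maximal
alphanumeric runs (internal apostrophes kept, hyphens split), then matches
token windows up to `max_ngram` tokens (default 6, the longest surface a
clinical dictionary realistically stores) greedily: leftmost starting
position, longest window first, and an accepted match consumes its tokens.
No overlapping or nested spans are ever emitted — the display model is one
highlight per span. The test suite checks equivalence against an
exhaustive window-scan oracle that enumerates every matching window and
selects spans by the same leftmost-longest rule.

Real tagger output can be imported from a TSV of spans instead; spans are
bounds-checked against the text and overlaps are resolved
leftmost-longest with a logged warning.

## Semantic-type gating

Each concept carries one or more semantic types. The gate
(`classify_policy()`) is:

- **FULL** if *any* type is in the prioritized set — clinically core
  categories such as "Disease or Syndrome", "Pharmacologic Substance",
  "Laboratory or Test Result";
- **SKIP** if *all* types are in the deprioritized set — categories too
  general to carry standalone clinical meaning, such as "Geographic Area"
  and "Temporal Concept" (skipped terms are not annotated at all);
- **SHALLOW** otherwise — looked up at stages 1–2 only.

The shipped default config has 21 prioritized and 3 deprioritized types.
Only five of those are documented verbatim; the remainder are conventional
clinical categories chosen once to fill the stated counts, and the whole
config is a runtime file (`[prioritized]` / `[deprioritized]` sections)
meant to be replaced where a curated list exists. The same applies to the
modifier list (`[modifiers]`): the documented examples are *chronic*,
*severe*, *left*; the shipped default extends them with common disease and
laterality modifiers (acute, bilateral, upper, …), all single words by
construction.

## The four-stage lookup

For a match with surface `s` and preferred name `p` (policy FULL):

1. resolve the lexicon at `normalize_surface(s)`;
2. else at `normalize_key(p)` — the preferred name acts as a synonym hop;
3. else at `trim_modifiers(s)`, provided trimming changed the term and
   left it non-empty (otherwise the stage would duplicate stage 1);
4. else resolve each distinct remaining word individually; if any word has
   definitions the result is a *partial match* (`partial = TRUE`), with
   one labeled item per defined word in word order, rendered as
   `[word]: definition`.

SHALLOW policies stop after stage 2. A complete miss produces no result
and no highlight — including the stage-4 case where no word is defined
(an open design point; highlighting a span the system cannot explain at
all would only frustrate).

Stage 3 trims the *surface* only, not the preferred name — the closest
literal reading of the procedure, which describes trimming after the
preferred-name search. Stage-4 word lookups consult the lexicon directly
(no per-word preferred-name hop). Stage-2 hits are displayed under the
surface form, with the preferred name recorded on the result — the
reader sees the term that is actually in their note.

## Display policy per entry class

- **ACRONYM**: only the rank-1 (most frequent) sense is shown. Sense ranks
  are authored in the lexicon file, standing in for expert judgment; the
  package does no runtime sense disambiguation (a known limitation — an
  acronym used in an unusual sense gets the usual definition).
- **DRUG with senses**: all senses in rank order (multi-purpose drugs keep
  all their readings); `max_senses` caps the display if wanted.
- **DRUG without senses**: the drug-class definition, tagged
  `DRUG_CLASS` — coverage through class membership when no term-level
  definition exists yet.
- **TERM**: all senses in rank order.

## Memoization and rendering

`annotate()` memoizes lookups in a per-call hash table keyed by
(policy, surface, preferred name); the policy is part of the key so
SHALLOW and FULL results never cross-contaminate. The cache is an
optimization only: the acceptance suite asserts bit-identical serialized
output with the cache on and off over 100 generated notes.

`render_html()` wraps each linked span in a `<span>` whose `title`
attribute carries the definitions (hover display). Everything is
entity-escaped and no `<a>` elements are emitted — dangling links in
annotated medical text are worse than none. The golden-file test freezes
one rendered fixture (stored as `.txt`) after manual inspection.

# Term-importance ranking (adapted distant supervision)

## Model

Candidates are the distinct recognized surfaces in a corpus. The feature
vector is fixed: term frequency, document frequency, word count, character
length, mean word length, a general-English frequency-rank bucket
(1–10 across a packaged 1,000-word list, 11 = absent), and a 20-trigram
indicator block over word-final trigrams common in medical vocabulary
(-mia, -tis, -oma, …). Distant labels come from membership in a consumer
vocabulary; the base model is an L2-regularized logistic regression
(glmnet, `alpha = 0`, fixed `lambda = 0.01` — deterministic, no solver
randomness). Adaptation is *stacking*: the base model's probability is
appended to the features and a second ridge-logistic model is fit on the
small manually labeled set. Stacking was chosen over instance weighting or
fine-tuning because it is simple, reproducible, keeps the base weights
frozen, and exhibits the behavior that matters — recovery from biased
distant labels; the choice is recorded in the model's provenance field.

## What the simulation world states

`gen_importance_world(n = 2000, rho, seed)` draws features from fixed
distributions (Poisson counts, a length model, a bucket distribution
skewed toward out-of-list, sparse suffix indicators), sets the true
importance probability to `plogis(eta + b0)` where `eta` is the
standardized generative signal scaled to separation `gamma = 3.5` and `b0`
is calibrated so the positive base rate is 0.25 — a strong but imperfect
separation between lay-familiar and unfamiliar terms.

The consumer vocabulary contains each truly important term with
probability `rho` (its *recall*), but the misses are **systematic, not
uniform**: retention probability decreases with a technicality score
(medical suffixes, absence from the general-English list), calibrated so
mean retention over true positives still equals `rho`. This models the
documented failure mode — the terms a lay vocabulary lacks are precisely
the technical ones — and it is what makes adaptation meaningful: uniform
random misses barely perturb a *ranking*, so a base model trained on them
loses almost nothing and adaptation has nothing to fix (we measured
exactly that with an earlier uniform design, and replaced the mechanism
before freezing the acceptance test). With systematic misses the base
model partially learns "vocabulary-ness" instead of importance, and the
manually labeled set corrects the bias.

What a green test establishes: on this stated world, held-out AUC of the
base model is ≥ 0.9 without noise, and adaptation does not lose (mean over
20 seeds) at recall 0.6. What it does not establish: performance on real
EHR term distributions, whose features, label noise and class balance are
unknown here.

# Synonym mining

Candidates for a target term are its neighbors in an undirected
interwiki-link edge list (the package consumes a pre-extracted list; no
crawling). Terms are embedded by their word vector, or the mean of
in-vocabulary word vectors for multi-word terms — the simplest defensible
composition; fully out-of-vocabulary candidates sink to the bottom of both
rankings deterministically (lexicographic), so permutation integrity holds
regardless of coverage.

The first pass ranks by cosine similarity to the target. The second pass
is Rocchio-style pseudo-relevance feedback: feedback vector
`alpha · v(target) + beta · mean(v(top-k))` with defaults
`k = 5, alpha = 1.0, beta = 0.75` — the canonical Rocchio instantiation
and its textbook weights, all CLI-exposed. `beta = 0` reduces exactly to
the plain ranking (asserted). Ties break lexicographically everywhere, so
rankings are total and reproducible; both passes are invariant to positive
rescaling of the vector table (cosine's scale invariance, asserted as a
property).

The embedding world used to test PRF states: 50 unit-norm cluster centers
in `d = 25`; each target's own vector is one noisy observation of its
center (noise `2.5σ` per coordinate) while its true synonyms carry noise
`σ`; candidates are the synonyms plus 20 distractors from other clusters.
The asymmetry is the point: with a noiseless target, plain cosine is
already near-perfect and PRF is vacuous; with a noisy target, averaging
the top-ranked candidates denoises the query — which is the actual
mechanism PRF relies on. At `σ = 0` plain ranking is exactly perfect
(MAP = 1.0, asserted); the PRF-improvement property is stated for
`σ ≤ 0.25`, with the default world at `σ = 0.12`. Real embedding spaces
are not isotropic Gaussian clusters; the green test establishes the
mechanism, not production mining quality.

# Fixture bundles and what "green" means

`gen_bundle()` builds a lexicon/concept-table/config world whose planted
terms cycle through archetypes covering every stage × policy combination,
including terms that must produce *no* annotation (skipped types, shallow
terms reachable only at stage 3, full misses). Note text is template-based
("The patient has <term> today.") so gold spans are exact by construction;
filler vocabulary is disjoint from the concept table so no distractor
windows collide. Every planned gold stage is re-derived at generation time
by a deliberately naive evaluator that walks the lexicon structures
stage by stage, independent of the linker's `lookup()`; a mismatch aborts
generation. The worked real examples (bacteremia, Hecoria, AC, community
acquired pneumonia, normal sinus rhythm) are always included so the
documented micro-behaviors run verbatim.

Synthetic notes do **not** emulate real clinical language: no shorthand,
no misspellings, no ungrammatical fragments, no sentence-boundary
ambiguity. A green end-to-end test establishes that the linker implements
its stated rules exactly, not that recognition would be adequate on real
notes — that is what the external-span import path is for.

# Numerical and degenerate-input choices

- Offsets are 0-based half-open everywhere; `substr(text, start + 1, end)`
  recovers a span.
- Ridge penalty fixed at `lambda = 0.01` for both fits; toy inputs with a
  single feature column are zero-padded to satisfy the solver and the pad
  weight is dropped.
- AUC is the rank-based Mann–Whitney statistic with mid-ranks for ties.
- Cosine of a zero vector is defined as 0 (such candidates rank after all
  genuinely similar ones but before OOV candidates only by score).
- An empty trimmed term skips stage 3; a stage-3 trim equal to the
  original surface skips stage 3 (it would duplicate stage 1).
- Empty lexicons, empty concept tables, empty candidate lists, and
  header-only files are all valid and round-trip.
- Lexicon rows are written sorted by (term key, sense rank) so writes are
  byte-deterministic.
- All generators restore the caller's RNG state (`with_seed`), so they are
  pure functions of their arguments.

# Known limitations

- No word-sense disambiguation: an acronym's most-frequent sense can be
  wrong in context (e.g. a ventilator-mode reading of a chemotherapy
  acronym).
- Exact dictionary matching misses misspellings and inflectional variants
  the concept table does not list.
- Compound terms whose meaning exceeds their parts (the
  "community acquired pneumonia" problem) are only ever partial matches
  unless the lexicon gains a compound entry.
- The shipped semantic-type and modifier defaults fill documented counts
  with conventional choices; deployments should supply curated lists.
- The importance and embedding worlds are stated simulations; their green
  properties do not transfer claims to licensed real-world resources.
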