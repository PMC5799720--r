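# laylink

Clinical notes are written for clinicians. When patients read their own
notes through a portal, jargon like *bacteremia*, drug brand names, and
acronyms get in the way of comprehension. **laylink** is an R toolkit that
annotates note text by linking medical terms to *lay definitions* —
definitions written at or below average adult literacy level — and that
supports building such a definition lexicon in the first place.

## What it does

**Annotation pipeline** (`annotate()`):

1. *Recognition.* A deterministic dictionary tagger finds medical-term
   spans by greedy leftmost-longest matching of normalized token windows
   against a concept table (surface form → concept ID, preferred name,
   semantic types). Precomputed spans from an external tagger can be
   imported instead (`import_external_matches()`).
2. *Semantic-type gating* (`classify_policy()`). Each concept's UMLS-style
   semantic types decide how hard to try: any *prioritized* type (e.g.
   "Disease or Syndrome") → full lookup; all types *deprioritized* (e.g.
   "Temporal Concept") → skip; otherwise a shallow lookup.
3. *Four-stage lookup* (`lookup()`), stopping at the first hit:
   the exact surface (stage 1); the concept's preferred name (stage 2);
   the surface with modifier words like *chronic*, *severe*, *left*
   removed (stage 3); each remaining word individually (stage 4 — a
   *partial match*, displayed as bracketed word labels such as
   `[rhythm]: ...`). Shallow terms stop after stage 2. Lookups are
   memoized across matches.

Display rules: acronyms show only their most-frequent sense; drugs with
several authored senses show all of them; a drug without its own definition
falls back to its drug-class definition. Results serialize to JSON records
and render to hover-definition HTML with full escaping and no hyperlinks.

**Lexicon construction tooling:**

- *Term-importance ranking by adapted distant supervision*
  (`distant_label()`, `train_base()`, `adapt()`, `rank_terms()`): candidate
  terms extracted from a note corpus are labeled positive if they occur in
  a consumer health vocabulary, an L2-regularized logistic model is fit on
  those noisy labels, and a small manually labeled set adapts the model by
  stacking (the base score becomes an extra feature). Ranked probabilities
  prioritize definition authoring.
- *Synonym mining with pseudo-relevance feedback* (`syn_candidates()`,
  `rank_by_similarity()`, `prf_rerank()`): candidate synonyms are a term's
  neighbors in an interwiki-link graph, ranked by word-embedding cosine
  similarity, then reranked with a Rocchio feedback vector
  `alpha * v(target) + beta * mean(v(top-k candidates))`
  (defaults k = 5, alpha = 1.0, beta = 0.75).

**Seeded generators** (`gen_bundle()`, `gen_importance_world()`,
`gen_embedding_world()`) produce every synthetic input the test suite
needs, with gold annotations verified at generation time by an independent
slow evaluator.

## Worked example

```r
library(laylink)

lex <- lexicon(list(
  definition_entry("bacteremia", "TERM", data.frame(
    sense_rank = 1L,
    definition_text = "The presence of bacteria, a type of germ, in the blood",
    source_tag = "demo")),
  definition_entry("community", "TERM", data.frame(
    sense_rank = 1L, definition_text = "A group of people.",
    source_tag = "demo")),
  definition_entry("pneumonia", "TERM", data.frame(
    sense_rank = 1L,
    definition_text = "An infection of the lungs, usually caused by viruses or bacteria.",
    source_tag = "demo")),
  definition_entry("hecoria", "DRUG", empty_senses(),
                   drug_class_key = "calcineurin inhibitors")),
  drug_classes = c("calcineurin inhibitors" =
                     "A drug used to reduce immune response."))

concepts <- concept_table(data.frame(
  surface_form = c("bacteremia", "community acquired pneumonia", "hecoria"),
  concept_id = c("C0004610", "C0694549", "C3265426"),
  preferred_name = c("Bacteremia", "Community-Acquired Pneumonia", "Hecoria"),
  semantic_types = c("Disease or Syndrome", "Disease or Syndrome",
                     "Pharmacologic Substance")))

note <- annotate(
  "Blood cultures confirmed bacteremia. CXR consistent with community acquired pneumonia. Continue Hecoria.",
  concepts, lex, default_semantic_config(), default_modifiers())
print(note)
```

prints

```
laylink: matches by policy: FULL=3 SHALLOW=0 SKIP=0
laylink: results by stage: 1=2 2=0 3=0 4=1
<laylink annotated note> 104 chars, 3 linked term(s)
  [25,35) bacteremia                   stage 1
  [57,85) community acquired pneumonia stage 4 (partial)
  [96,103) Hecoria                      stage 1
```

*bacteremia* and *Hecoria* hit at stage 1 (the drug through its
class-level definition, "A drug used to reduce immune response.").
*community acquired pneumonia* has no entry of its own, so it is a
stage-4 partial match whose items are the defined component words:

```r
r <- note$results[[2]]
cat(sprintf("[%s]: %s\n", r$items$label, r$items$definition_text), sep = "")
#> [community]: A group of people.
#> [pneumonia]: An infection of the lungs, usually caused by viruses or bacteria.
```

`render_html(note)` wraps each span in a highlight element whose hover
title carries the definitions; `serialize_annotations(note)` /
`parse_annotations(record, text)` round-trip the results as JSON.

## Command line

A launcher script is installed at
`system.file("exec", "laylink", package = "laylink")`:

```sh
laylink annotate --text NOTE.txt --concepts C.tsv --lexicon L.tsv \
    --drug-classes D.tsv --config CFG.txt [--format html|records] \
    [--no-cache] --out OUT
laylink rank-terms --corpus DIR --concepts C.tsv --vocab VOCAB.txt \
    [--manual M.tsv] [--seed N] --out ranked.tsv
laylink synonyms --edges E.tsv --vectors V.txt --target "TERM" \
    [--k 5 --alpha 1.0 --beta 0.75] --out ranked.tsv
laylink gen-fixtures --kind bundle|importance|embedding --seed N --out DIR
```

## File formats

All plain UTF-8 text: lexicon TSV
(`term_key, entry_class, sense_rank, definition_text, source_tag,
drug_class_key`), drug-class TSV, concept-table TSV with `|`-joined
semantic types, `[prioritized]`/`[deprioritized]`/`[modifiers]` config
sections, external-span TSV, interwiki edge TSV, and word-vector text
(`n d` header, one token + floats per line).
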