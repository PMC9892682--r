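# medlex

**medlex** is an R toolkit for building and applying a *concept-anchored
medical lexicon* for Spanish clinical and biomedical NLP. Unlike a plain
gazetteer, every entry couples a lemma with its part-of-speech category, its
inflected word forms (with gender/number and, for verbs, person/tense/mood
features), one or more UMLS-style Concept Unique Identifiers (CUIs: `C` +
seven digits), and UMLS semantic types and groups (`ANAT`, `CHEM`, `DISO`,
`PROC`, ...). Synonymous terms — *hígado*/*hepático*, *EV*/*enterovirus*,
*viriasis*/*viriosis* — are clustered under a shared concept, which is what
makes the lexicon usable for concept normalization, PoS tagging,
lemmatization and dictionary pre-annotation rather than string matching
alone.

The package implements the full construction-and-application machinery:

* **Data model and formats** — validated lexical entries with consistency
  indexes; a pipe-delimited six-field distribution format
  (`CUI|lemma|forms|PoS|semantic types|group`, multiple values `;`-joined);
  a lossless Lexical Markup Framework (LMF) XML serialization with per-form
  morphological features; companion Lexical Record tables
  (abbreviation↔full form, affix↔gloss, deverbal noun↔verb,
  adjective↔noun); descriptive statistics.
* **Morphological generation** — Spanish nominal gender/number inflection
  with explicit orthographic accent rules (*pulmón* → *pulmones*), regular
  `-ar`/`-er`/`-ir` verb conjugation with a cell-level exception table,
  word-order variants of multiword terms, and head-word morphology for
  multiwords (*síndrome de Asperger* inherits noun/masculine/singular from
  *síndrome*).
* **Variant linking** — unit-cost Levenshtein lookup of unattested strings
  against the lexicon (distance ≤ 2, never auto-accepted: candidates flow
  through an explicit review file), acronym/abbreviation↔full-form concept
  propagation with ambiguity flagging, and affix/root lookup with CUI
  suggestion (*ampicilina* → *-cilina* → `C0030842`).
* **Embedding-based expansion** — cosine nearest-neighbour retrieval over a
  word-vector model, `cos(s⃗, w⃗) = s⃗·w⃗ / (‖s⃗‖‖w⃗‖)`, at a configurable depth
  (default 50 per seed term), with out-of-vocabulary screening against the
  lexicon and a reproducible concept-mapping step for the OOV candidates.
* **Corpus pre-annotation** — longest-match dictionary matching over all
  lexicon forms (case-folded, except case-sensitive acronyms), preservation
  of concept ambiguity (*radio*: radius bone, radium, or an abbreviation),
  pruning of nested same-group spans (keep the more specific entity) and of
  crossing spans (corrected to independent entities), BRAT standoff output.
* **Tagging and evaluation** — lexicon-backed lemmatization with an
  identity fallback for unknown words (never an invented lemma), a
  PoS-override layer on top of any base tagger, and per-category
  precision/recall/F1 over the open lexical categories (ADJ, ADV, NOUN,
  PROPN, VERB) with lenient (accent-insensitive) lemma comparison.
* **Synthetic fixtures** — deterministic generators for schema-conformant
  toy lexicons, corpora with gold annotations at exact character offsets,
  and vector models with planted synonym neighbourhoods, so the whole
  pipeline is testable without licensed terminology content.

## Worked example

```r
library(medlex)

lines <- c(
  "C0019080|sangrar|sangrar;sangra;sangrando;sangrado|V|Pathologic Function|DISO",
  "C0023884|hígado|hígado;hígados|N|Body Part, Organ, or Organ Component|ANAT",
  "C0030193|dolor|dolor;dolores|N|Sign or Symptom|DISO",
  "C0018681|dolor de cabeza|dolor de cabeza|N|Sign or Symptom|DISO",
  "C0034627;C1279083|radio|radio;radios|N|Body Part, Organ, or Organ Component|ANAT")
path <- tempfile(); writeLines(lines, path)

lx <- read_lexicon(path, "dsv")
lexicon_stats(lx)
#> <medlex_stats> 5 lemmas, 11 forms, 6 CUIs | 0.83 lemmas/CUI, 1.83 forms/CUI
#>  pos count percent
#>    N     4      80
#>    V     1      20

txt <- "Paciente con dolor de cabeza y fractura del radio"
annotate_document(txt, lx = lx, groups = c("ANAT", "DISO"))
#>   start end         surface              cuis group
#> 1    13  28 dolor de cabeza          C0018681  DISO
#> 2    44  49           radio C0034627;C1279083  ANAT

lemmatize_token("sangrando", pos_hint = "VERB", lx = lx)
#> $lemma
#> [1] "sangrar"
#> $source
#> [1] "lexicon"
```

Three things to note: the nested match *dolor* inside *dolor de cabeza* was
pruned in favour of the more specific entity; *radio* keeps both candidate
CUIs of its anatomical sense (disambiguation against the chemical-element
sense is deliberately left to downstream revision); and the gerund
*sangrando* is lemmatized back to the verb infinitive through the lexicon's
form index.

A thin command-line wrapper over the same functions ships at
`inst/cli/medlex.R` (`convert`, `stats`, `validate`, `inflect`, `variants`,
`annotate`, `expand`, `lemmatize`, `eval`, `fixtures`).

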