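---
title: "medlex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{medlex: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medlex)
```

This vignette explains the data model and the procedures medlex implements,
the parameters that matter, the numerical and design choices made where the
design was genuinely open, and what the synthetic fixtures do and do not
demonstrate.

## The lexicon model

A lexical entry is a lemma plus: a part-of-speech category from a nine-way
tagset (`N`, `ADJ`, `NPR`, `ADJ/N`, `AFF`, `V`, `N/NPR`, `ADV`, `ADJ/ADV`;
the slashed categories are context-ambiguous), a set of concept unique
identifiers (CUIs, `C` + 7 digits), semantic types, one semantic group, and
a set of word forms. Each form carries a morphological feature bundle —
gender (`commonGender`/`masculine`/`feminine`), number
(`singular`/`plural`/`singular_and_plural`), and for verb forms
person/tense/mood; `variant_type` marks abbreviations and acronyms.
Invariants enforced at validation: the lemma appears among its own forms as
the citation form; verb features occur only on verb forms; entries without
CUIs are rejected unless explicitly allowed (the main lexicon holds only
concept-mapped terms — that is what makes it a normalization resource
rather than a word list).

All text is normalized to Unicode NFC on load so precomposed and decomposed
accents compare equal. Lookups go through three hash indexes (form, lemma,
CUI), rebuilt after every mutation; a fourth, case-exact form index backs
case-sensitive acronym matching.

### Formats

Two serializations are provided, mirroring a dual-distribution model:

* **Delimited (DSV)** — six pipe-separated fields: CUI(s), lemma, forms,
  PoS, semantic type(s), group. Values within a field are `;`-separated.
  The delimiter and in-field separator are not dictated by any standard;
  pipe/semicolon were chosen (configurable) for proximity to the
  `MRCONSO.RRF` convention of terminology distributions. Six fields cannot
  carry per-form morphology, so DSV is deliberately lossy on morphological
  features; round-trip identity for DSV is therefore defined modulo
  morphology (surfaces, categories, concepts and groups must survive
  exactly).
* **LMF XML** — one `LexicalEntry` element per entry with `feat`
  attribute/value pairs for every morphological attribute, one `WordForm`
  per inflected form and one `Sense` per CUI; affix entries carry an
  `attachment` feature (`prefix`/`suffix`) derived from the hyphen side.
  This serialization is lossless and is the one checked by the full
  round-trip identity property.

Deterministic output order — entries by (first CUI, lemma), forms by
(surface, features), codepoint order throughout — makes files diffable and
regeneration byte-stable.

## Morphological generation

Nominal inflection applies the regular Spanish alternations: feminine
`-o → -a` and `-or → -ora` (adjectives and affixes only; nouns keep their
inherent gender), plural `-s` after vowels, `-es` after consonants with the
written accent dropped on a final `-Vn/-Vs` syllable (*pulmón* →
*pulmones*), `-z → -ces`, and invariance for unstressed `-s` endings. A
lemma marked `singular_and_plural` (e.g. *diabetes*) yields a single
invariant form. Multiword lemmas are not inflected; their analysis comes
from the head word instead (first non-function token resolving to a
noun-like entry; the function-word skip list is the closed set *de, del,
la, el, en, para, por, con, y, los, las, un, una, a, o, al*, reflecting the
head-initial structure of Spanish noun phrases).

Verb conjugation is rule-based over the three regular classes, filling
present/imperfect/preterite/future/conditional indicative, present
subjunctive, second-person imperative, the compound present perfect
(auxiliary *haber* + participle — pronominal clitics are not generated; a
pronominal citation like *te has atragantado* stays out of scope and is a
review item), gerund, and the four gender/number participle variants.
Irregular verbs are handled by a cell-level exception table shipped as a
delimited data file (`inst/extdata/verb_exceptions.dsv`): an exception row
overrides exactly one paradigm cell, and all unlisted cells fall back to
the regular rules. A rule-plus-exception design was preferred over lookup
in an existing tagger lexicon because it has no licensed dependency and is
observably identical on regular verbs; the closure property (every
generated form lemmatizes back to its source lemma) is what the test suite
actually checks, on fixture lexicons of 200 lemmas (~1500 forms).

Concept propagation across derivational pairs (noun↔verb, noun↔adjective)
takes the union of the two entries' CUI sets and copies semantic
types/group to the concept-less side; it is idempotent, and a no-op with a
warning when neither side has a concept.

## Variant discovery and acronym linking

Edit distance is unit-cost Levenshtein on NFC strings, case-sensitive by
default, with spaces and hyphens as ordinary characters — that choice makes
the three tokenization variants of a compound (fused, hyphenated, spaced)
mutually reachable within distance 2, which is precisely the variant class
the procedure targets. An optional accent-folding flag exists but defaults
off: attested variant pairs differ by letters and hyphens, not diacritics.
The distance engine is base R's C implementation (`utils::adist`); the test
suite holds it against an independent memoized-recursion oracle (full
enumeration of all 4-letter-alphabet strings up to length 3 — 7,225 pairs —
plus seeded random pairs up to length 6). Candidate pairs below the
threshold (default 2, the whole string rather than per token) are always
`proposed`, never auto-accepted; status changes only through an explicit
review file, keeping a human-in-the-loop audit trail.

Acronym/abbreviation linking propagates concepts between short and full
forms. The full→short direction always applies, so a short form accumulates
every candidate concept of its expansions; short forms with more than one
distinct expansion are flagged ambiguous, and for those the short→full
direction is withheld — otherwise a second linking pass would leak one
expansion's concept onto another expansion, and linking would not be
idempotent. Unambiguous pairs (e.g. unit symbols invariant across
languages) link in both directions with no flag. Short forms are typed
`acronym` when all-caps/digits, else `abbreviation`, and are matched
case-sensitively by the annotator so that a lowercase look-alike word never
fires them.

## Embedding-based seed expansion

Candidate terms are retrieved as the `k` nearest neighbours of each seed
term by cosine similarity

$$\mathrm{cos}(\vec s, \vec w) = \frac{\vec s \cdot \vec w}{\lVert \vec s\rVert\,\lVert \vec w\rVert},$$

default depth `k = 50` per seed; a shallower depth tends to return mostly
misspellings of the seed itself, while 50 reaches drug-class neighbours and
brand names. Ties are broken by codepoint order (the ranking is otherwise
underdetermined); neighbour retrieval is checked against an
exhaustive-scan oracle. Retrieved candidates are screened against the
lexicon case-folded: candidates matching no lexicon form are the
out-of-vocabulary (OOV) set, the interesting one for terminology growth.
The manual terminology lookup that decides which OOVs denote real concepts
is modelled as an explicit `reference_cuis` mapping, keeping that step
reproducible. The report exposes both raw and deduplicated OOV counts,
since neighbour tokens shared by several seeds can legitimately be counted
either way. Vectors are consumed from the standard plain-text format
(`vocab dim` header, one token + floats per line); no embedding training
happens in this package.

## Pre-annotation

Matching is token-aligned: the document is tokenized exactly like the
corpus normalizer (punctuation split, intra-token hyphens kept), and every
window whose token sequence equals an indexed lexicon form is reported with
*all* candidate CUIs — lexical ambiguity such as *radio* is preserved, not
resolved, because context disambiguation belongs to manual revision.
Offsets are 0-based, end-exclusive character positions, and every returned
surface equals the exact document slice (an invariant tested on all
generated corpora).

Pruning then applies two corrections. Properly nested same-group spans lose
the less specific (shorter) entity. Crossing spans — partial overlaps where
neither contains the other — are corrected to independent entities; the
exact correction algorithm is underdetermined, and the implemented choice
is to keep the earlier-starting span intact and truncate the later one to
begin after it, re-aligned to a token boundary (dropped if nothing
remains). The two rules iterate to a fixed point, after which no properly
nested same-group pair and no crossing pair remains — the property the
suite checks exhaustively on overlap-rich generated corpora. Different-group
nesting (e.g. a CHEM term inside a DISO span) is legitimate and untouched.

## Tagging, lemmatization, evaluation

Lemmatization is lexicon lookup of the case-folded surface; among multiple
candidate entries the PoS hint wins, then the lexicographically smallest
lemma (a deterministic tie-break). Out-of-vocabulary surfaces fall back to
the identity lemma — the surface itself. That fallback is a deliberate
floor: a dictionary lemmatizer must never fabricate a non-word, which is
the characteristic failure mode of seq2seq lemmatizers on compounds.

The tagger is an override layer, not a tagger: any upstream tagger provides
base tags (the package ships a trivial all-`OTHER` base for dependency-free
use), and the lexicon overrides only where it is competent — unambiguous
lexical categories map directly (`N`→NOUN, `NPR`→PROPN, `V`→VERB, `ADJ`,
`ADV`); slashed categories defer to the base tag when it is one of the
listed alternatives (context decides participle/adjective cases) and take
the first alternative otherwise; unknown tokens keep their base tag.

Evaluation is restricted to tokens whose gold tag is an open lexical
category (ADJ, ADV, NOUN, PROPN, VERB) — closed-class words are outside the
lexicon's competence. PoS mode computes one-vs-rest precision/recall/F1 per
category plus a micro aggregate (in this single-label setting micro
precision equals recall equals accuracy; a macro average is also emitted
since published averages rarely say which was used). Lemma mode applies the
lenient criterion: lemmas compare equal after NFD accent stripping and case
folding, nothing broader — "minor variation" is otherwise undefined, so the
implementation keeps the narrowest defensible reading. The metric code is
checked against independently hand-built confusion matrices on all
small-sequence cases in the suite.

## What the fixtures emulate — and what they do not

The generators produce pronounceable pseudo-Spanish stems from CV/CVC
syllable templates so that the real inflection rules apply naturally, and
plant exactly the structures the tests need: multiwords headed by existing
noun entries (→ nested matches), crossing partners (→ crossing matches),
acronym pairs with a consistent abbreviation record, distance-1
misspellings held out of the lexicon, duplicate records for merge testing,
and vector neighbourhoods with synonyms inside cosine 0.95 of their seed
and distractors held below 0.5 against every seed. Everything is a pure
function of a `fixture_spec` (one RNG seed threaded through all steps;
byte-identical regeneration is itself a test).

Default study sizes: corpora of 8–12 documents of 30–60 filler tokens with
2–5 planted entities; expansion experiments with 20 seeds × 5 planted
synonyms at depth 50 over a 2,000-token vocabulary; round trips over 100
random lexicons; closure over a 200-lemma lexicon. These sizes make every
property decidable exactly (exhaustive oracles) in seconds.

Passing on fixtures demonstrates the machinery — offset integrity, pruning
soundness, closure, exact retrieval — not clinical coverage. Real corpora
bring what the generator deliberately omits: genuine sense ambiguity,
misspellings and segmentation errors, morphological irregularity beyond
the exception table, and the skewed frequency distributions of actual
terminology. Headline figures of any full-scale lexicon (coverage rates,
tagging F1 on clinical text) depend on license-gated content and are out of
scope here; the package reports only what its own runs compute.

## Known limitations

* Conjugation covers simple tenses plus the present perfect; no clitics,
  no other compound tenses, no full irregular paradigm tables (the
  exception file is intentionally minimal and user-extensible).
* No context disambiguation anywhere: ambiguous concepts, ambiguous PoS
  and ambiguous acronyms are preserved and flagged, by design.
* The lexicon stores no ontological relations between concepts — it is a
  lexicon, not an ontology.
* Word-order variant generation swaps adjacent post-head content words
  only; all outputs are proposals for review, not attested terms.
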