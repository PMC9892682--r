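# Concept propagation across derivational variants, word-order variants of
# multiword terms, and head-word-based morphology for multiwords.

# Spanish function words skipped when locating the head of a noun phrase.
FUNCTION_WORDS <- c("de", "del", "la", "el", "en", "para", "por", "con", "y",
                    "los", "las", "un", "una", "a", "o", "al")

#' Propagate concept identifiers between derivationally related entries
#'
#' Used to share a concept between a noun and its derived verb (e.g.
#' dialysis/dialyze) or a noun and its relational adjective (liver/hepatic):
#' after propagation both entries carry the union of their CUI sets, and the
#' semantic types/group of the concept-bearing entry are copied to the
#' CUI-less one.  The operation is idempotent.
#'
#' @param entry_a,entry_b two [lexical_entry()] objects, at least one with
#'   CUIs (both CUI-less is a warning no-op).
#' @param relation `"noun_verb"` or `"adj_noun"`; by default inferred from the
#'   categories (a verb on either side means `noun_verb`).
#' @return list with updated `entry_a`, `entry_b`, and `link` — a record of
#'   the derivation (`source_lemma`, `target_lemma`, `relation`,
#'   `shared_cuis`) or `NULL` when nothing was propagated.
#' @export
propagate_concept <- function(entry_a, entry_b, relation = NULL) {
  if (!length(entry_a$cuis) && !length(entry_b$cuis)) {
    warning("neither '", entry_a$lemma, "' nor '", entry_b$lemma,
            "' carries a CUI; nothing to propagate")
    return(list(entry_a = entry_a, entry_b = entry_b, link = NULL))
  }
  if (is.null(relation))
    relation <- if (entry_a$pos == "V" || entry_b$pos == "V")
      "noun_verb" else "adj_noun"
  shared <- sort(union(entry_a$cuis, entry_b$cuis))
  copy_sem <- function(to, from) {
    lexical_entry(to$lemma, to$pos, shared,
                  semantic_types = if (length(to$semantic_types))
                    to$semantic_types else from$semantic_types,
                  semantic_group = if (nzchar(to$semantic_group))
                    to$semantic_group else from$semantic_group,
                  forms = to$forms)
  }
  a2 <- copy_sem(entry_a, entry_b)
  b2 <- copy_sem(entry_b, entry_a)
  list(entry_a = a2, entry_b = b2,
       link = list(source_lemma = entry_a$lemma, target_lemma = entry_b$lemma,
                   relation = relation, shared_cuis = shared))
}

tokenize_term <- function(term) {
  toks <- strsplit(trimws(nfc(term)), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Word-order variants of a multiword term
#'
#' Generates candidate variants by swapping adjacent content-word modifiers
#' after the head (function words are never moved), so e.g. a
#' head-modifier-modifier term yields the variant with the two modifiers
#' exchanged.  The original term is excluded and the token multiset is
#' preserved in every variant.  All candidates are proposals: the procedure
#' that uses them assigns the concept of the original term and queues them
#' for manual review.
#'
#' @param term a multiword string (single-token input yields an empty set).
#' @return character vector of variant strings (possibly empty).
#' @export
#' @examples
#' generate_word_order_variants("virus respiratorio sincitial")
generate_word_order_variants <- function(term) {
  toks <- tokenize_term(term)
  if (length(toks) < 2L) return(character(0))
  content <- which(!tolower(toks) %in% FUNCTION_WORDS)
  head_pos <- if (length(content)) content[1] else 1L
  movable <- content[content > head_pos]
  out <- character(0)
  if (length(movable) >= 2L) {
    for (i in seq_len(length(movable) - 1L)) {
      swapped <- toks
      swapped[c(movable[i], movable[i + 1L])] <-
        swapped[c(movable[i + 1L], movable[i])]
      out <- c(out, paste(swapped, collapse = " "))
    }
  }
  setdiff(unique(out), paste(toks, collapse = " "))
}

#' Head-word morphology for a multiword term
#'
#' The head of a Spanish multiword term determines the analysis of the whole
#' constituent, so the term inherits the part-of-speech and gender/number of
#' its head word: the first token, skipping function words, that resolves in
#' the lexicon to a noun-like entry (`N`, `NPR`, `N/NPR` or `ADJ/N`).
#'
#' @param term multiword string (>= 2 tokens).
#' @param lx a `medlex_lexicon` used to resolve the head.
#' @return list with `pos` and `morph` (the [morph_features()] of the head's
#'   citation form), plus `head` (the head token).
#' @export
assign_multiword_morphology <- function(term, lx) {
  toks <- tokenize_term(term)
  if (length(toks) < 2L)
    stop("'", term, "' is not a multiword term")
  for (tok in toks) {
    if (tolower(tok) %in% FUNCTION_WORDS) next
    hits <- lexicon_lookup(lx, tok, by = "form")
    hits <- Filter(function(e) e$pos %in% c("N", "NPR", "N/NPR", "ADJ/N"), hits)
    if (!length(hits)) next
    e <- hits[[1]]
    row <- match(fold_key(tok), fold_key(e$forms$surface))
    f <- e$forms[row, , drop = FALSE]
    return(list(pos = e$pos, head = tok,
                morph = morph_features(gender = f$gender, number = f$number)))
  }
  stop("unresolved head for '", term, "': none of [",
       paste(toks, collapse = ", "), "] is a known noun")
}
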