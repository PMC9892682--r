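# Acronym/abbreviation <-> full-form linking and affix/root lookup.

is_acronym_shaped <- function(x) grepl("^[[:upper:]0-9.]{2,}$", x)

#' Link acronyms and abbreviations to their full forms
#'
#' For every `(short form, full form)` pair in the abbreviation Lexical
#' Record, concept identifiers are propagated bidirectionally: the full
#' form's entry receives the short form's CUIs and vice versa.  A short form
#' absent from the lexicon is created as a new entry under the full form's
#' concept, with its surface typed `acronym` (all-caps shapes) or
#' `abbreviation`.  Short forms paired with more than one distinct full form
#' (e.g. clinical initialisms with several expansions) keep all candidate
#' CUIs and are flagged ambiguous for manual review; for those, the
#' short-to-full direction is withheld so one expansion's concept never
#' leaks onto another expansion.  Unambiguous pairs (e.g. language-invariant
#' unit symbols) link in both directions without a flag.  The operation is
#' idempotent.
#'
#' @param records a `medlex_records` object with a populated `abbreviations`
#'   table.
#' @param lx a `medlex_lexicon`.
#' @return the updated lexicon, with two attributes: `ambiguous` (character
#'   vector of flagged short forms) and `unresolved` (short forms whose full
#'   form is absent from the lexicon).
#' @export
link_acronyms <- function(records, lx) {
  abbr <- records$abbreviations
  if (!nrow(abbr)) return(lx)
  abbr$short <- nfc(abbr$short); abbr$full <- nfc(abbr$full)

  # a short form paired with more than one distinct full form is ambiguous:
  # all candidate concepts are retained on it, but the short -> full
  # direction is withheld (those pairs go to manual review)
  n_fulls <- tapply(fold_key(abbr$full), abbr$short,
                    function(x) length(unique(x)))
  ambiguous_shorts <- names(n_fulls)[n_fulls > 1L]

  unresolved <- character(0)
  linked_shorts <- character(0)
  for (i in seq_len(nrow(abbr))) {
    short <- abbr$short[i]; full <- abbr$full[i]
    full_hits <- lexicon_lookup(lx, full, by = "form")
    short_hits <- lexicon_lookup(lx, short, by = "form_exact")
    if (!length(full_hits) && !length(short_hits)) {
      unresolved <- c(unresolved, short)
      next
    }
    linked_shorts <- c(linked_shorts, short)
    pair_cuis <- sort(unique(unlist(c(lapply(full_hits, `[[`, "cuis"),
                                      lapply(short_hits, `[[`, "cuis")))))
    vt <- if (is_acronym_shaped(short)) "acronym" else "abbreviation"
    unambiguous <- !short %in% ambiguous_shorts

    template <- if (length(full_hits)) full_hits[[1]] else short_hits[[1]]
    if (!length(short_hits)) {
      # create the short-form entry under the full form's concept
      lx <- lexicon_add(lx, lexical_entry(
        short, template$pos,
        sort(unique(unlist(lapply(full_hits, `[[`, "cuis")))),
        semantic_types = template$semantic_types,
        semantic_group = template$semantic_group,
        lemma_morph = morph_features(variant_type = vt)))
    } else {
      # full -> short: the short form accumulates every candidate concept
      full_cuis <- unlist(lapply(full_hits, `[[`, "cuis"))
      for (id in unique(lx$form_index_exact[[short]])) {
        e <- lx$entries[[id]]
        e$cuis <- sort(union(e$cuis, full_cuis))
        e$forms$variant_type[e$forms$surface == short] <- vt
        lx$entries[[id]] <- e
      }
    }
    # short -> full only for unambiguous short forms
    if (unambiguous && length(full_hits)) {
      for (id in unique(lx$form_index[[fold_key(full)]])) {
        e <- lx$entries[[id]]
        e$cuis <- sort(union(e$cuis, pair_cuis))
        lx$entries[[id]] <- e
      }
    }
    lx <- rebuild_indexes(lx)
  }
  if (length(unresolved))
    message("unresolved short form(s): ", paste(unique(unresolved),
                                                collapse = ", "))
  attr(lx, "ambiguous") <- intersect(ambiguous_shorts, unique(linked_shorts))
  attr(lx, "unresolved") <- unique(unresolved)
  lx
}

#' Look up affixes and roots matching a token
#'
#' Returns every prefix (trailing hyphen, matched at the token start) and
#' suffix (leading hyphen, matched at the token end) of the affix Lexical
#' Record that occurs in the token, longest match first, together with its
#' gloss and concept identifier when one is recorded (e.g. drug-class
#' suffixes mapped to a pharmacological concept).
#'
#' @param token a single word (no hyphen trimming is applied to it).
#' @param records a `medlex_records` object with a populated `affixes` table.
#' @return data.frame with columns `affix`, `gloss`, `cui` (empty string when
#'   unmapped); zero rows when nothing matches.
#' @export
#' @examples
#' recs <- lexical_records(affixes = data.frame(
#'   affix = c("-cilina", "reno-"), gloss = c("penicillins", "kidney"),
#'   cui = c("C0030842", "")))
#' affix_lookup("ampicilina", recs)
affix_lookup <- function(token, records) {
  token <- nfc(token)
  aff <- records$affixes
  out <- aff[0, , drop = FALSE]
  if (!nrow(aff)) return(out)
  stem <- sub("^-", "", sub("-$", "", aff$affix))
  is_suffix <- startsWith(aff$affix, "-")
  is_prefix <- endsWith(aff$affix, "-")
  hit <- (is_suffix & endsWith(token, stem) & nchar(stem) < nchar(token)) |
         (is_prefix & startsWith(token, stem) & nchar(stem) < nchar(token))
  out <- aff[hit, , drop = FALSE]
  out <- out[order(-nchar(out$affix), out$affix, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
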