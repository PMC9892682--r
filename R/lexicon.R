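#' Morphological feature bundle
#'
#' Creates the feature bundle attached to a word form: grammatical gender and
#' number, and (for verb forms) person, tense and mood.  `variant_type` marks
#' short forms (abbreviations/acronyms); fully spelled forms use `"none"`.
#'
#' @param gender one of `commonGender`, `masculine`, `feminine`, `unspecified`.
#' @param number one of `singular`, `plural`, `singular_and_plural`,
#'   `unspecified`.
#' @param person one of `first`, `second`, `third`, `none`.
#' @param tense one of `present`, `imperfect`, `past`, `future`, `conditional`,
#'   `presentPerfect`, `none`.
#' @param mood one of `indicative`, `subjunctive`, `imperative`, `infinitive`,
#'   `gerund`, `participle`, `none`.
#' @param variant_type one of `abbreviation`, `acronym`, `none`.
#' @return a named list of class `medlex_morph`.
#' @export
morph_features <- function(gender = "unspecified", number = "unspecified",
                           person = "none", tense = "none", mood = "none",
                           variant_type = "none") {
  gender <- match.arg(gender, GENDER_VALUES)
  number <- match.arg(number, NUMBER_VALUES)
  person <- match.arg(person, PERSON_VALUES)
  tense  <- match.arg(tense, TENSE_VALUES)
  mood   <- match.arg(mood, MOOD_VALUES)
  variant_type <- match.arg(variant_type, VARIANT_VALUES)
  structure(list(gender = gender, number = number, person = person,
                 tense = tense, mood = mood, variant_type = variant_type),
            class = "medlex_morph")
}

MORPH_COLS <- c("gender", "number", "person", "tense", "mood", "variant_type")
FORM_COLS <- c("surface", MORPH_COLS)

# An empty forms table.
empty_forms <- function() {
  out <- data.frame(surface = character(), gender = character(),
                    number = character(), person = character(),
                    tense = character(), mood = character(),
                    variant_type = character(), stringsAsFactors = FALSE)
  out
}

#' Build a word-form row
#'
#' @param surface the surface string (non-empty after trimming).
#' @param morph a [morph_features()] bundle (defaults to all-unspecified).
#' @return one-row data.frame with columns `surface`, `gender`, `number`,
#'   `person`, `tense`, `mood`, `variant_type`.
#' @export
word_form <- function(surface, morph = morph_features()) {
  surface <- trimws(nfc(surface))
  if (!length(surface) || is.na(surface) || !nzchar(surface))
    stop("word form surface must be non-empty after trimming")
  data.frame(surface = surface, gender = morph$gender, number = morph$number,
             person = morph$person, tense = morph$tense, mood = morph$mood,
             variant_type = morph$variant_type, stringsAsFactors = FALSE)
}

forms_table <- function(...) {
  rows <- list(...)
  if (!length(rows)) return(empty_forms())
  do.call(rbind, rows)
}

# Deduplicate form rows on (surface, morph) keeping first occurrence.
dedup_forms <- function(forms) {
  key <- do.call(paste, c(forms[FORM_COLS], sep = "\r"))
  forms[!duplicated(key), , drop = FALSE]
}

#' Create a lexical entry
#'
#' One lemma with its part-of-speech category, concept identifiers (CUIs),
#' semantic types, semantic group, and inflected forms.  The lemma itself is
#' always present among the forms as the citation form; if `forms` does not
#' contain it, it is added with the supplied `lemma_morph`.
#'
#' @param lemma citation form (non-empty).
#' @param pos one of the nine part-of-speech categories
#'   (`r paste(POS_CATEGORIES, collapse = ", ")`).
#' @param cuis character vector of concept identifiers (`C` + 7 digits).
#' @param semantic_types character vector of semantic type labels.
#' @param semantic_group single group label (e.g. `ANAT`, `CHEM`, `DISO`,
#'   `PROC`).
#' @param forms optional forms table as built by [word_form()] /
#'   `rbind`; duplicates are removed.
#' @param lemma_morph morphology of the citation form when it has to be added.
#' @return object of class `medlex_entry`.
#' @export
lexical_entry <- function(lemma, pos, cuis = character(),
                          semantic_types = character(),
                          semantic_group = "", forms = NULL,
                          lemma_morph = morph_features()) {
  lemma <- trimws(nfc(lemma))
  if (!nzchar(lemma)) stop("lemma must be non-empty")
  if (!pos %in% POS_CATEGORIES)
    stop("unknown part-of-speech tag: '", pos, "'")
  cuis <- sort(unique(trimws(cuis)))
  cuis <- cuis[nzchar(cuis)]
  if (length(cuis) && !all(cui_pattern_ok(cuis)))
    stop("malformed CUI(s): ",
         paste(cuis[!cui_pattern_ok(cuis)], collapse = ", "))
  if (is.null(forms)) forms <- empty_forms()
  forms$surface <- trimws(nfc(forms$surface))
  if (any(!nzchar(forms$surface))) stop("empty surface in forms for '", lemma, "'")
  if (!lemma %in% forms$surface)
    forms <- rbind(word_form(lemma, lemma_morph), forms)
  forms <- dedup_forms(forms)
  rownames(forms) <- NULL
  structure(list(lemma = lemma, pos = pos, cuis = cuis,
                 semantic_types = sort(unique(trimws(semantic_types))),
                 semantic_group = trimws(semantic_group),
                 forms = forms),
            class = "medlex_entry")
}

#' @export
print.medlex_entry <- function(x, ...) {
  cat(sprintf("<medlex_entry> %s [%s] %s | group=%s | %d form(s)\n",
              x$lemma, x$pos,
              if (length(x$cuis)) paste(x$cuis, collapse = ";") else "<no CUI>",
              x$semantic_group, nrow(x$forms)))
  invisible(x)
}

entry_key <- function(e) {
  paste(e$lemma, e$pos, paste(e$cuis, collapse = ";"), sep = "\r")
}

# Merge two entries with equal (lemma, pos, cuis): union of forms and types.
merge_entries <- function(a, b) {
  stopifnot(identical(entry_key(a), entry_key(b)))
  lexical_entry(a$lemma, a$pos, a$cuis,
                semantic_types = union(a$semantic_types, b$semantic_types),
                semantic_group = if (nzchar(a$semantic_group))
                  a$semantic_group else b$semantic_group,
                forms = rbind(a$forms, b$forms))
}

#' Build a lexicon from lexical entries
#'
#' Entries sharing `(lemma, pos, cui-set)` are merged (form-set union);
#' form/lemma/CUI indexes are built on construction and after every mutation
#' through [lexicon_add()].
#'
#' @param entries list of [lexical_entry()] objects.
#' @param allow_no_cui keep entries without CUIs?  By default the main lexicon
#'   only holds concept-mapped terms and CUI-less entries are rejected.
#' @return object of class `medlex_lexicon`.
#' @export
lexicon <- function(entries = list(), allow_no_cui = FALSE) {
  if (inherits(entries, "medlex_entry")) entries <- list(entries)
  lx <- structure(list(entries = list(), n_duplicates = 0L),
                  class = "medlex_lexicon")
  lexicon_add(lx, entries, allow_no_cui = allow_no_cui)
}

#' Add entries to a lexicon
#'
#' @param lx a `medlex_lexicon`.
#' @param entries list of entries (or one entry) to add; entries whose
#'   `(lemma, pos, cuis)` key already exists are merged and counted in
#'   `lx$n_duplicates`.
#' @param allow_no_cui accept CUI-less entries?
#' @return the updated lexicon (indexes rebuilt).
#' @export
lexicon_add <- function(lx, entries, allow_no_cui = FALSE) {
  if (inherits(entries, "medlex_entry")) entries <- list(entries)
  keys <- vapply(lx$entries, entry_key, character(1))
  for (e in entries) {
    stopifnot(inherits(e, "medlex_entry"))
    if (!allow_no_cui && !length(e$cuis))
      stop("entry '", e$lemma,
           "' has no CUI; use allow_no_cui = TRUE to accept it")
    k <- entry_key(e)
    hit <- match(k, keys)
    if (is.na(hit)) {
      lx$entries[[length(lx$entries) + 1L]] <- e
      keys <- c(keys, k)
    } else {
      lx$entries[[hit]] <- merge_entries(lx$entries[[hit]], e)
      lx$n_duplicates <- lx$n_duplicates + 1L
    }
  }
  rebuild_indexes(lx)
}

# Rebuild the three hash indexes: folded form -> entry ids, folded lemma ->
# entry ids, CUI -> entry ids.  Also an exact (unfolded) form index used for
# case-sensitive acronym matching.
rebuild_indexes <- function(lx) {
  form_idx <- new.env(parent = emptyenv())
  form_exact <- new.env(parent = emptyenv())
  lemma_idx <- new.env(parent = emptyenv())
  cui_idx <- new.env(parent = emptyenv())
  push <- function(env, key, id) assign(key, c(env[[key]], id), envir = env)
  for (i in seq_along(lx$entries)) {
    e <- lx$entries[[i]]
    for (s in unique(e$forms$surface)) {
      push(form_idx, fold_key(s), i)
      push(form_exact, nfc(s), i)
    }
    push(lemma_idx, fold_key(e$lemma), i)
    for (cui in e$cuis) push(cui_idx, cui, i)
  }
  lx$form_index <- form_idx
  lx$form_index_exact <- form_exact
  lx$lemma_index <- lemma_idx
  lx$cui_index <- cui_idx
  lx
}

#' Look up entries by surface form, lemma or CUI
#'
#' @param lx a `medlex_lexicon`.
#' @param key the string to look up.
#' @param by one of `"form"` (case-folded surface), `"form_exact"`
#'   (case-sensitive surface), `"lemma"`, `"cui"`.
#' @return list of matching `medlex_entry` objects (possibly empty).
#' @export
lexicon_lookup <- function(lx, key, by = c("form", "form_exact", "lemma", "cui")) {
  by <- match.arg(by)
  idx <- switch(by, form = lx$form_index, form_exact = lx$form_index_exact,
                lemma = lx$lemma_index, cui = lx$cui_index)
  k <- switch(by, form = fold_key(key), form_exact = nfc(key),
              lemma = fold_key(key), cui = key)
  ids <- idx[[k]]
  lapply(unique(ids), function(i) lx$entries[[i]])
}

#' Number of entries in a lexicon
#' @param lx a `medlex_lexicon`.
#' @return integer count.
#' @export
lexicon_size <- function(lx) length(lx$entries)

#' @export
print.medlex_lexicon <- function(x, ...) {
  cat(sprintf("<medlex_lexicon> %d entries, %d CUIs, %d distinct forms\n",
              length(x$entries), length(ls(x$cui_index)),
              length(ls(x$form_index_exact))))
  invisible(x)
}

#' Validate a lexicon
#'
#' Checks every entry against the data-model invariants: lemma among forms,
#' valid PoS, well-formed CUIs (non-empty unless `allow_no_cui`), non-empty
#' surfaces, verb features only on verb forms, and index consistency (every
#' indexed key resolves to entries that actually contain it).
#'
#' @param lx a `medlex_lexicon`.
#' @param allow_no_cui accept CUI-less entries?
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_lexicon <- function(lx, allow_no_cui = FALSE) {
  for (e in lx$entries) {
    if (!e$pos %in% POS_CATEGORIES)
      stop("entry '", e$lemma, "': unknown PoS '", e$pos, "'")
    if (!e$lemma %in% e$forms$surface)
      stop("entry '", e$lemma, "': lemma missing from forms")
    if (!allow_no_cui && !length(e$cuis))
      stop("entry '", e$lemma, "': no CUI")
    if (length(e$cuis) && !all(cui_pattern_ok(e$cuis)))
      stop("entry '", e$lemma, "': malformed CUI")
    if (any(!nzchar(trimws(e$forms$surface))))
      stop("entry '", e$lemma, "': empty surface")
    verbish <- e$pos == "V"
    if (!verbish) {
      bad <- e$forms$person != "none" | e$forms$tense != "none" |
        (!e$forms$mood %in% "none")
      if (any(bad))
        stop("entry '", e$lemma, "': verb features on non-verb form '",
             e$forms$surface[bad][1], "'")
    }
  }
  # index consistency
  for (k in ls(lx$form_index_exact)) {
    for (i in lx$form_index_exact[[k]])
      if (!k %in% lx$entries[[i]]$forms$surface)
        stop("form index inconsistent for key '", k, "'")
  }
  for (k in ls(lx$cui_index)) {
    for (i in lx$cui_index[[k]])
      if (!k %in% lx$entries[[i]]$cuis)
        stop("CUI index inconsistent for key '", k, "'")
  }
  invisible(TRUE)
}

# Canonical serial form used for equality: entries sorted by
# (first CUI, lemma, pos), forms sorted by (surface, morph).
canonical_entries <- function(lx, morphology = TRUE) {
  lapply(sort_entry_ids(lx), function(i) {
    e <- lx$entries[[i]]
    f <- e$forms
    if (!morphology) f <- unique(f["surface"])
    ord <- do.call(order, c(unname(as.list(f)), list(method = "radix")))
    f <- f[ord, , drop = FALSE]
    rownames(f) <- NULL
    list(lemma = e$lemma, pos = e$pos, cuis = e$cuis,
         semantic_types = e$semantic_types,
         semantic_group = e$semantic_group, forms = f)
  })
}

sort_entry_ids <- function(lx) {
  first_cui <- vapply(lx$entries, function(e)
    if (length(e$cuis)) e$cuis[1] else "", character(1))
  lemmas <- vapply(lx$entries, `[[`, character(1), "lemma")
  pos <- vapply(lx$entries, `[[`, character(1), "pos")
  order(first_cui, lemmas, pos, method = "radix")
}

#' Compare two lexicons for equality
#'
#' @param a,b lexicons.
#' @param morphology compare per-form morphological features?  Set `FALSE`
#'   when comparing through the DSV format, which carries surfaces but not
#'   their feature bundles.
#' @return logical.
#' @export
lexicon_equal <- function(a, b, morphology = TRUE) {
  isTRUE(all.equal(canonical_entries(a, morphology),
                   canonical_entries(b, morphology)))
}
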