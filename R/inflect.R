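# Spanish nominal/adjectival inflection: gender alternation and plural
# formation with explicit orthographic accent rewrites.

ACCENTED <- c("á", "é", "í", "ó", "ú")  # á é í ó ú
PLAIN    <- c("a", "e", "i", "o", "u")

# Drop the written accent of a final accented vowel + n/s ending
# (pulmón -> pulmon, before attaching -es).
deaccent_final <- function(w) {
  for (i in seq_along(ACCENTED)) {
    pat <- paste0(ACCENTED[i], "([ns])$")
    if (grepl(pat, w)) return(sub(pat, paste0(PLAIN[i], "\\1"), w))
  }
  w
}

ends_with_any <- function(w, suffixes) {
  any(vapply(suffixes, function(s) endsWith(w, s), logical(1)))
}

#' Pluralize a Spanish word by orthographic rule
#'
#' Vowel-final words take `-s`; `-z` becomes `-ces`; consonant-final words
#' take `-es`, dropping a written accent on a final `-Vn`/`-Vs` syllable
#' (pulmón -> pulmones); words ending in unstressed `-s` are invariant.
#'
#' @param w singular surface (single token).
#' @return plural surface.
#' @export
pluralize <- function(w) {
  if (grepl("[aeiouáéó]$", w)) return(paste0(w, "s"))
  if (grepl("[íú]$", w)) return(paste0(w, "es"))
  if (endsWith(w, "z")) return(paste0(substr(w, 1, nchar(w) - 1), "ces"))
  if (endsWith(w, "s")) {
    # accented final syllable (inglés) pluralizes; unstressed -s is invariant
    if (grepl("[áéíóú]s$", w))
      return(paste0(deaccent_final(w), "es"))
    return(w)
  }
  paste0(deaccent_final(w), "es")
}

# Feminine counterpart of a masculine base, or NULL when the base does not
# alternate (common-gender words in -a/-e/consonant).
feminine_of <- function(w) {
  if (endsWith(w, "o")) return(paste0(substr(w, 1, nchar(w) - 1), "a"))
  if (endsWith(w, "or")) return(paste0(w, "a"))
  NULL
}

#' Generate nominal/adjectival number (and gender) variants
#'
#' Applies the regular gender alternation (`-o` -> `-a`, `-or` -> `-ora`) and
#' plural rules to a nominal lemma.  Nouns keep their inherent gender and only
#' alternate number; adjectives and affixes alternate both gender and number.
#' A lemma marked `singular_and_plural` (e.g. invariant nouns like
#' *diabetes*) yields the single invariant form.  Affix lemmas keep their
#' attachment hyphen.
#'
#' @param lemma citation form.
#' @param pos nominal/adjectival category: `N`, `ADJ`, `NPR`, `ADJ/N`,
#'   `N/NPR`, `ADJ/ADV`, or `AFF`.
#' @param morph [morph_features()] of the citation form; its `gender` is the
#'   inherent gender for nouns and its `number` may be `singular_and_plural`.
#' @return forms table (one row per generated [word_form()]), citation form
#'   included.
#' @export
#' @examples
#' inflect_nominal("pulmón", "N", morph_features(gender = "masculine",
#'                                                    number = "singular"))
inflect_nominal <- function(lemma, pos, morph = morph_features()) {
  if (pos == "V")
    stop("wrong category: '", lemma, "' is a verb; use conjugate_verb()")
  if (!pos %in% setdiff(POS_CATEGORIES, "V"))
    stop("unknown part-of-speech tag: '", pos, "'")
  lemma <- trimws(nfc(lemma))
  if (!nzchar(lemma)) stop("lemma must be non-empty")

  # invariant number: single citation form
  if (morph$number == "singular_and_plural")
    return(word_form(lemma, morph_features(gender = morph$gender,
                                           number = "singular_and_plural",
                                           variant_type = morph$variant_type)))
  # multiword terms are not inflected here (head-based morphology instead)
  if (grepl("\\s", lemma))
    return(word_form(lemma, morph))

  pre <- ""; post <- ""; stem <- lemma
  if (pos == "AFF") {
    if (startsWith(stem, "-")) { pre <- "-"; stem <- substring(stem, 2) }
    if (endsWith(stem, "-")) { post <- "-"; stem <- substr(stem, 1, nchar(stem) - 1) }
  }

  alternates <- pos %in% c("ADJ", "ADJ/N", "ADJ/ADV", "AFF")
  fem <- if (alternates) feminine_of(stem) else NULL
  bases <- if (!is.null(fem)) {
    list(list(stem = stem, gender = "masculine"),
         list(stem = fem, gender = "feminine"))
  } else {
    g <- if (alternates) "commonGender" else morph$gender
    list(list(stem = stem, gender = g))
  }

  rows <- lapply(bases, function(b) {
    sg <- paste0(pre, b$stem, post)
    pl <- paste0(pre, pluralize(b$stem), post)
    out <- word_form(sg, morph_features(gender = b$gender, number = "singular",
                                        variant_type = morph$variant_type))
    if (!identical(pl, sg))
      out <- rbind(out, word_form(pl, morph_features(
        gender = b$gender, number = "plural",
        variant_type = morph$variant_type)))
    out
  })
  forms <- dedup_forms(do.call(rbind, rows))
  rownames(forms) <- NULL
  forms
}
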