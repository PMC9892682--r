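# Rule-based Spanish verb conjugation: regular -ar/-er/-ir paradigms plus a
# cell-level exception table for irregular verbs.

PERSONS <- c("first", "second", "third")
NUMBERS2 <- c("singular", "plural")

# Finite endings per conjugation class, in person order
# (1sg 2sg 3sg 1pl 2pl 3pl).
paradigm_endings <- function(class) {
  switch(class,
    ar = list(
      present_indicative    = c("o", "as", "a", "amos", "áis", "an"),
      imperfect_indicative  = c("aba", "abas", "aba", "ábamos", "abais", "aban"),
      past_indicative       = c("é", "aste", "ó", "amos", "asteis", "aron"),
      present_subjunctive   = c("e", "es", "e", "emos", "éis", "en"),
      imperative            = c(NA, "a", NA, NA, "ad", NA),
      gerund = "ando", participle = "ado"),
    er = list(
      present_indicative    = c("o", "es", "e", "emos", "éis", "en"),
      imperfect_indicative  = c("ía", "ías", "ía", "íamos", "íais", "ían"),
      past_indicative       = c("í", "iste", "ió", "imos", "isteis", "ieron"),
      present_subjunctive   = c("a", "as", "a", "amos", "áis", "an"),
      imperative            = c(NA, "e", NA, NA, "ed", NA),
      gerund = "iendo", participle = "ido"),
    ir = list(
      present_indicative    = c("o", "es", "e", "imos", "ís", "en"),
      imperfect_indicative  = c("ía", "ías", "ía", "íamos", "íais", "ían"),
      past_indicative       = c("í", "iste", "ió", "imos", "isteis", "ieron"),
      present_subjunctive   = c("a", "as", "a", "amos", "áis", "an"),
      imperative            = c(NA, "e", NA, NA, "id", NA),
      gerund = "iendo", participle = "ido")
  )
}

# Future and conditional attach to the full infinitive for all classes.
FUTURE_ENDINGS <- c("é", "ás", "á", "emos", "éis", "án")
CONDITIONAL_ENDINGS <- c("ía", "ías", "ía", "íamos", "íais", "ían")
HABER_PRESENT <- c("he", "has", "ha", "hemos", "habéis", "han")

cell_key <- function(person, number, tense, mood)
  paste(person, number, tense, mood, sep = ".")

#' Default verb exception table
#'
#' Reads the cell-level override table shipped with the package
#' (`verb_exceptions.dsv`: `lemma|cell|surface`, where `cell` is either
#' `person.number.tense.mood` or a non-finite slot name).  Users can maintain
#' their own table in the same format and pass it to [conjugate_verb()].
#'
#' @param path optional path to an alternative table.
#' @return data.frame with columns `lemma`, `cell`, `surface`.
#' @export
verb_exceptions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "verb_exceptions.dsv", package = "medlex")
  if (!nzchar(path) || !file.exists(path))
    return(data.frame(lemma = character(), cell = character(),
                      surface = character(), stringsAsFactors = FALSE))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(nfc(lines), "|", fixed = TRUE)
  data.frame(lemma = vapply(parts, `[`, character(1), 1),
             cell = vapply(parts, `[`, character(1), 2),
             surface = vapply(parts, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' Conjugate a Spanish verb
#'
#' Fills the full finite paradigm (present, imperfect, past/preterite, future
#' and conditional indicative; present subjunctive; second-person imperative;
#' compound present perfect as auxiliary + participle) and the non-finite
#' forms (infinitive, gerund, participle with its four gender/number
#' variants) using the regular `-ar`/`-er`/`-ir` rules.  Cells listed in the
#' exception table override the rule output.
#'
#' @param lemma verb infinitive.
#' @param exceptions exception table as returned by [verb_exceptions()].
#' @return object of class `medlex_conjugation`: list with `lemma`, `cells`
#'   (data.frame `surface`, `person`, `number`, `tense`, `mood`) and
#'   `nonfinite` (list `infinitive`, `gerund`, `participle`).
#' @export
#' @examples
#' ct <- conjugate_verb("sangrar")
#' subset(ct$cells, person == "third" & number == "singular" &
#'                  tense == "present" & mood == "indicative")$surface
conjugate_verb <- function(lemma, exceptions = verb_exceptions()) {
  lemma <- trimws(nfc(lemma))
  exc <- exceptions[exceptions$lemma == lemma, , drop = FALSE]
  class <- if (endsWith(lemma, "ar")) "ar"
           else if (endsWith(lemma, "er")) "er"
           else if (endsWith(lemma, "ir")) "ir"
           else NA_character_
  if (is.na(class) && !nrow(exc))
    stop("cannot conjugate '", lemma,
         "': not an -ar/-er/-ir infinitive and not in the exception table")
  if (is.na(class)) class <- "ar"  # shape for a fully overridden verb
  stem <- substr(lemma, 1, nchar(lemma) - 2)
  para <- paradigm_endings(class)

  override <- function(key, surface) {
    hit <- match(key, exc$cell)
    if (!is.na(hit)) exc$surface[hit] else surface
  }

  rows <- list()
  add <- function(surface, person, number, tense, mood) {
    key <- cell_key(person, number, tense, mood)
    surface <- override(key, surface)
    rows[[length(rows) + 1L]] <<- data.frame(
      surface = surface, person = person, number = number, tense = tense,
      mood = mood, stringsAsFactors = FALSE)
  }

  # endings are indexed 1sg 2sg 3sg 1pl 2pl 3pl
  finite <- function(endings, tense, mood, base = stem) {
    i <- 0L
    for (num in NUMBERS2) for (per in PERSONS) {
      i <- i + 1L
      if (!is.na(endings[i])) add(paste0(base, endings[i]), per, num, tense, mood)
    }
  }

  finite(para$present_indicative, "present", "indicative")
  finite(para$imperfect_indicative, "imperfect", "indicative")
  finite(para$past_indicative, "past", "indicative")
  finite(FUTURE_ENDINGS, "future", "indicative", base = lemma)
  finite(CONDITIONAL_ENDINGS, "conditional", "indicative", base = lemma)
  finite(para$present_subjunctive, "present", "subjunctive")
  finite(para$imperative, "present", "imperative")

  participle <- override("participle", paste0(stem, para$participle))
  gerund <- override("gerund", paste0(stem, para$gerund))
  i <- 0L
  for (num in NUMBERS2) for (per in PERSONS) {
    i <- i + 1L
    add(paste(HABER_PRESENT[i], participle), per, num,
        "presentPerfect", "indicative")
  }

  cells <- do.call(rbind, rows)
  part_forms <- inflect_nominal(participle, "ADJ")  # gender/number variants
  structure(list(lemma = lemma, cells = cells,
                 nonfinite = list(infinitive = lemma, gerund = gerund,
                                  participle = part_forms$surface)),
            class = "medlex_conjugation")
}

#' @export
print.medlex_conjugation <- function(x, ...) {
  cat(sprintf("<medlex_conjugation> %s: %d finite cells; participle %s\n",
              x$lemma, nrow(x$cells), x$nonfinite$participle[1]))
  invisible(x)
}

#' Word forms of a conjugation table
#'
#' Flattens a conjugation into the forms table used by [lexical_entry()]:
#' the infinitive (citation form), every finite cell with person/number/tense/
#' mood features, the gerund, and the participle gender/number variants.
#'
#' @param ct a `medlex_conjugation`.
#' @return forms data.frame.
#' @export
conjugation_forms <- function(ct) {
  rows <- list(word_form(ct$lemma, morph_features(mood = "infinitive")))
  for (i in seq_len(nrow(ct$cells))) {
    rows[[length(rows) + 1L]] <- word_form(
      ct$cells$surface[i],
      morph_features(person = ct$cells$person[i],
                     number = ct$cells$number[i],
                     tense = ct$cells$tense[i],
                     mood = ct$cells$mood[i]))
  }
  rows[[length(rows) + 1L]] <- word_form(ct$nonfinite$gerund,
                                         morph_features(mood = "gerund"))
  part <- ct$nonfinite$participle
  genders <- rep(c("masculine", "feminine"), each = 2)[seq_along(part)]
  numbers <- rep(c("singular", "plural"), 2)[seq_along(part)]
  for (i in seq_along(part)) {
    rows[[length(rows) + 1L]] <- word_form(
      part[i], morph_features(gender = genders[i], number = numbers[i],
                              mood = "participle"))
  }
  out <- dedup_forms(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
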