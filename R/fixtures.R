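# Deterministic synthetic fixtures: toy lexicons, corpora with gold
# annotations/tags/lemmas, and vector models with planted synonym
# neighbourhoods.  The real lexicon distribution is license-gated, so every
# other module is exercised against these schema-conformant stand-ins.

#' Fixture generation parameters
#'
#' A fixture spec fully determines the generated artifacts: the same spec
#' (including `seed`) always regenerates identical outputs.
#'
#' @param n_concepts number of concepts (entries before variants).
#' @param groups semantic groups to draw from.
#' @param n_docs documents in the toy corpus.
#' @param tokens_per_doc range (min, max) of filler tokens per document.
#' @param entities_per_doc range of planted entities per document.
#' @param n_seeds seed terms designated for embedding expansion.
#' @param planted_synonyms_per_seed planted high-similarity neighbours per
#'   seed in the toy vector model.
#' @param vocab_size total vector vocabulary (seeds + synonyms + distractors).
#' @param dim vector dimensionality (>= 2).
#' @param seed RNG seed.
#' @return list of class `medlex_fixture_spec`.
#' @export
fixture_spec <- function(n_concepts = 50L,
                         groups = c("ANAT", "CHEM", "DISO", "PROC"),
                         n_docs = 8L, tokens_per_doc = c(30L, 60L),
                         entities_per_doc = c(2L, 5L),
                         n_seeds = 5L, planted_synonyms_per_seed = 5L,
                         vocab_size = 300L, dim = 25L, seed = 1L) {
  stopifnot(n_concepts > 0, n_docs > 0, dim >= 2, n_seeds > 0,
            planted_synonyms_per_seed > 0, vocab_size > 0)
  structure(list(n_concepts = as.integer(n_concepts), groups = groups,
                 n_docs = as.integer(n_docs),
                 tokens_per_doc = as.integer(tokens_per_doc),
                 entities_per_doc = as.integer(entities_per_doc),
                 n_seeds = as.integer(n_seeds),
                 planted_synonyms_per_seed =
                   as.integer(planted_synonyms_per_seed),
                 vocab_size = as.integer(vocab_size),
                 dim = as.integer(dim), seed = as.integer(seed)),
            class = "medlex_fixture_spec")
}

# Evaluate fn() under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Pronounceable pseudo-Spanish stems from CV/CVC syllables, so the regular
# inflection rules apply naturally.
make_stems <- function(n, min_syll = 2L, max_syll = 3L) {
  onsets <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t",
              "v", "br", "cl", "cr", "fl", "gr", "pl", "tr")
  vowels <- c("a", "e", "i", "o", "u")
  codas <- c("", "", "", "n", "r", "s", "l")
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < n * 50L) {
    guard <- guard + 1L
    k <- sample(min_syll:max_syll, 1L)
    syls <- vapply(seq_len(k), function(i)
      paste0(sample(onsets, 1L), sample(vowels, 1L),
             if (i == k) "" else sample(codas, 1L)), character(1))
    stem <- paste(syls, collapse = "")
    if (!stem %in% out) out <- c(out, stem)
  }
  if (length(out) < n) stop("could not generate enough unique stems")
  out
}

SEM_TYPE_OF <- c(ANAT = "Body Part, Organ, or Organ Component",
                 CHEM = "Pharmacologic Substance",
                 DISO = "Disease or Syndrome",
                 PROC = "Therapeutic or Preventive Procedure",
                 GENE = "Gene or Genome", PHYS = "Physiologic Function")

#' Generate a schema-conformant toy lexicon
#'
#' Builds `n_concepts` concept entries with unique CUIs, categories drawn
#' over the full PoS tagset, and inflected forms produced by
#' [inflect_nominal()] / [conjugate_verb()].  The construction plants the
#' structures downstream tests need:
#'
#' * multiword terms headed by an existing noun entry (same semantic group),
#'   so dictionary matching produces nested spans;
#' * crossing partners (`modifier + new word` entries overlapping a
#'   multiword), so pruning sees crossing spans;
#' * acronym/abbreviation pairs, recorded in the companion abbreviation
#'   Lexical Record;
#' * distance-1 spelling variants left out of the lexicon, listed in the
#'   `planted_variants` attribute for edit-distance discovery;
#' * controlled duplicate records exercising entry merging.
#'
#' Attributes on the returned lexicon: `records` (a `medlex_records`),
#' `planted_variants` (data.frame `candidate`, `known_term`, `cuis`),
#' `seed_terms` (lemmas designated as embedding seeds), `multiwords` and
#' `crossing_pairs` (lemma pairs used by the corpus generator).
#'
#' @param spec a [fixture_spec()].
#' @return a validated `medlex_lexicon`.
#' @export
make_toy_lexicon <- function(spec = fixture_spec()) {
  with_seed(spec$seed, function() {
    n <- spec$n_concepts
    stems <- make_stems(n + ceiling(n / 3) + 8L)
    extra <- tail(stems, ceiling(n / 3) + 8L)
    stems <- head(stems, n)
    pos_pool <- c("N", "ADJ", "V", "NPR", "ADJ/N", "N/NPR", "ADV",
                  "ADJ/ADV", "AFF")
    pos_prob <- c(.50, .16, .10, .06, .06, .04, .04, .02, .02)
    entries <- list()
    abbrev <- list(); affix_rec <- list(); variants <- list()
    noun_heads <- character(0)
    multiwords <- character(0); crossing <- list()
    extra_i <- 0L
    next_extra <- function() {
      extra_i <<- extra_i + 1L
      if (extra_i > length(extra)) stop("stem pool exhausted")
      extra[extra_i]
    }

    for (i in seq_len(n)) {
      cui <- sprintf("C%07d", 1000000L + i)
      pos <- sample(pos_pool, 1L, prob = pos_prob)
      group <- sample(spec$groups, 1L)
      stype <- unname(SEM_TYPE_OF[group])
      if (is.na(stype)) stype <- "Finding"
      stem <- stems[i]
      if (pos == "V") {
        lemma <- paste0(stem, sample(c("ar", "er", "ir"), 1L))
        forms <- conjugation_forms(conjugate_verb(lemma))
      } else if (pos == "ADV") {
        lemma <- paste0(stem, "mente")
        forms <- word_form(lemma, morph_features(number = "singular_and_plural"))
      } else if (pos == "AFF") {
        lemma <- paste0("-", stem, "o")
        forms <- inflect_nominal(lemma, "AFF")
        affix_rec[[length(affix_rec) + 1L]] <-
          data.frame(affix = lemma, gloss = paste0("meaning of ", stem),
                     cui = cui, stringsAsFactors = FALSE)
      } else if (pos == "NPR") {
        lemma <- paste0(toupper(substr(stem, 1, 1)), substring(stem, 2))
        forms <- word_form(lemma, morph_features(number = "singular"))
      } else {
        ending <- sample(c("o", "a", "e"), 1L)
        lemma <- paste0(stem, ending)
        gender <- switch(ending, o = "masculine", a = "feminine",
                         e = "commonGender")
        forms <- inflect_nominal(lemma, pos,
                                 morph_features(gender = gender,
                                                number = "singular"))
      }
      entries[[length(entries) + 1L]] <-
        lexical_entry(lemma, pos, cui, semantic_types = stype,
                      semantic_group = group, forms = forms)
      e_idx <- length(entries)
      if (pos == "N") noun_heads <- c(noun_heads, lemma)

      # multiword headed by an earlier noun entry, same group -> nesting
      if (pos == "N" && length(noun_heads) >= 1L && i %% 6L == 0L) {
        head_lemma <- noun_heads[length(noun_heads)]
        mod <- next_extra()
        mw <- paste(head_lemma, "de", mod)
        mw_cui <- sprintf("C%07d", 2000000L + i)
        entries[[length(entries) + 1L]] <-
          lexical_entry(mw, "N", mw_cui, semantic_types = stype,
                        semantic_group = group,
                        lemma_morph = morph_features(gender = "masculine",
                                                     number = "singular"))
        multiwords <- c(multiwords, mw)
        # crossing partner: "<mod> <new>" overlaps "<head> de <mod>"
        if (i %% 12L == 0L) {
          cross <- paste(mod, next_extra())
          cr_cui <- sprintf("C%07d", 3000000L + i)
          entries[[length(entries) + 1L]] <-
            lexical_entry(cross, "N", cr_cui, semantic_types = stype,
                          semantic_group = group)
          crossing[[length(crossing) + 1L]] <-
            data.frame(multiword = mw, partner = cross,
                       stringsAsFactors = FALSE)
        }
      }
      # acronym pair
      if (i %% 10L == 3L && pos %in% c("N", "ADJ", "ADJ/N")) {
        short <- toupper(paste0(substr(lemma, 1, 1),
                                substr(stem, nchar(stem), nchar(stem)),
                                sample(LETTERS, 1L)))
        abbrev[[length(abbrev) + 1L]] <-
          data.frame(short = short, full = lemma, stringsAsFactors = FALSE)
      }
      # distance-1 spelling variant kept out of the lexicon
      if (i %% 8L == 2L && nchar(lemma) > 3L && !grepl("\\s", lemma)) {
        pos_ch <- sample(seq_len(nchar(lemma) - 1L), 1L)
        ch <- substr(lemma, pos_ch, pos_ch)
        repl <- sample(setdiff(c("a", "e", "i", "o", "u", "x"), ch), 1L)
        cand <- paste0(substr(lemma, 1, pos_ch - 1L), repl,
                       substring(lemma, pos_ch + 1L))
        if (!length(lexicon_lookup_stub(entries, cand)))
          variants[[length(variants) + 1L]] <-
            data.frame(candidate = cand, known_term = lemma, cuis = cui,
                       stringsAsFactors = FALSE)
      }
      # controlled duplicate record (merged on load)
      if (i %% 12L == 5L) {
        entries[[length(entries) + 1L]] <-
          lexical_entry(lemma, pos, cui, semantic_types = stype,
                        semantic_group = group)
      }
    }
    lx <- lexicon(entries)
    validate_lexicon(lx)
    single <- vapply(lx$entries, function(e)
      e$pos %in% c("N", "ADJ") && !grepl("\\s", e$lemma), logical(1))
    seeds <- head(vapply(lx$entries[single], `[[`, character(1), "lemma"),
                  spec$n_seeds)
    attr(lx, "records") <- lexical_records(
      abbreviations = if (length(abbrev)) do.call(rbind, abbrev) else NULL,
      affixes = if (length(affix_rec)) do.call(rbind, affix_rec) else NULL)
    attr(lx, "planted_variants") <-
      if (length(variants)) do.call(rbind, variants) else
        data.frame(candidate = character(), known_term = character(),
                   cuis = character(), stringsAsFactors = FALSE)
    attr(lx, "seed_terms") <- seeds
    attr(lx, "multiwords") <- multiwords
    attr(lx, "crossing_pairs") <-
      if (length(crossing)) do.call(rbind, crossing) else
        data.frame(multiword = character(), partner = character(),
                   stringsAsFactors = FALSE)
    lx
  })
}

# membership check against an entry list while the lexicon is still being
# assembled
lexicon_lookup_stub <- function(entries, surface) {
  hit <- vapply(entries, function(e) surface %in% e$forms$surface, logical(1))
  which(hit)
}

FILLER_WORDS <- c("paciente", "presenta", "con", "sin", "tras", "durante",
                  "estudio", "caso", "control", "grupo", "tratamiento",
                  "semanas", "valores", "datos", "resultado", "analisis",
                  "seguimiento", "historia", "refiere", "tipo", "grado",
                  "nivel", "fase", "dosis", "diaria", "previa", "actual")

#' Generate a toy corpus with gold annotations, tags and lemmas
#'
#' Documents embed known lexicon surfaces at recorded character offsets among
#' filler tokens (the filler vocabulary is disjoint from the lexicon).  Each
#' document's gold annotations are the planted non-overlapping entities; a
#' subset of documents additionally embeds the nested/crossing constructions
#' recorded by [make_toy_lexicon()] to exercise span pruning (those extra
#' spans are listed in `overlaps`, not in `gold`).  Gold tags/lemmas cover
#' every whitespace token: planted forms carry the entry's category (mapped
#' to the evaluation tagset) and source lemma, filler tokens are `OTHER`
#' with identity lemmas.
#'
#' @param lx lexicon from [make_toy_lexicon()].
#' @param spec the same [fixture_spec()].
#' @param dir optional directory: when given, writes `doc<i>.txt`,
#'   `doc<i>.ann` (BRAT standoff) and `doc<i>.conllu` per document.
#' @return list of class `medlex_corpus`: `documents` (character vector),
#'   `gold` (list of annotation data.frames), `gold_tokens` (list of
#'   data.frames `surface`, `tag`, `lemma`), `overlaps` (data.frame `doc`,
#'   `kind`).
#' @export
make_toy_corpus <- function(lx, spec = fixture_spec(), dir = NULL) {
  with_seed(spec$seed + 1L, function() {
    # plantable entities: citation forms plus one inflected variant
    plantable <- list()
    for (e in lx$entries) {
      if (e$pos %in% c("AFF", "ADV")) next
      if (grepl("\\s", e$lemma)) next
      surfaces <- unique(c(e$lemma, head(setdiff(e$forms$surface, e$lemma), 1L)))
      tag <- POS_TO_EVAL[[e$pos]][1]
      for (s in surfaces) {
        if (grepl("\\s", s)) next
        plantable[[length(plantable) + 1L]] <-
          list(surface = s, lemma = e$lemma, tag = tag,
               group = e$semantic_group,
               cuis = paste(e$cuis, collapse = ";"))
      }
    }
    mw <- attr(lx, "multiwords")
    mw_info <- lapply(mw, function(m) {
      e <- lexicon_lookup(lx, m, by = "form")[[1]]
      list(surface = m, lemma = e$lemma, tag = "NOUN",
           group = e$semantic_group, cuis = paste(e$cuis, collapse = ";"))
    })
    crossing <- attr(lx, "crossing_pairs")

    documents <- character(spec$n_docs)
    gold <- vector("list", spec$n_docs)
    gold_tokens <- vector("list", spec$n_docs)
    overlaps <- list()

    for (d in seq_len(spec$n_docs)) {
      n_fill <- sample(spec$tokens_per_doc[1]:spec$tokens_per_doc[2], 1L)
      n_ent <- sample(spec$entities_per_doc[1]:spec$entities_per_doc[2], 1L)
      ents <- sample(plantable, min(n_ent, length(plantable)))
      # nested construction: a multiword (its head is itself an entry)
      if (length(mw_info) && d %% 2L == 0L) {
        ents <- c(ents, mw_info[sample(length(mw_info), 1L)])
        overlaps[[length(overlaps) + 1L]] <-
          data.frame(doc = d, kind = "nested", stringsAsFactors = FALSE)
      }
      # crossing construction: "<head> de <mod> <new>" as raw text
      cross_text <- NULL
      if (nrow(crossing) && d %% 4L == 1L) {
        cr <- crossing[sample(nrow(crossing), 1L), ]
        cross_text <- paste(cr$multiword,
                            sub("^\\S+\\s", "", cr$partner))
        overlaps[[length(overlaps) + 1L]] <-
          data.frame(doc = d, kind = "crossing", stringsAsFactors = FALSE)
      }
      fill <- sample(FILLER_WORDS, n_fill, replace = TRUE)
      slots <- sort(sample(seq_len(n_fill), length(ents) +
                             as.integer(!is.null(cross_text))))
      pieces <- as.list(fill)
      piece_meta <- vector("list", length(fill))
      for (j in seq_along(ents)) {
        pieces[[slots[j]]] <- ents[[j]]$surface
        piece_meta[[slots[j]]] <- ents[[j]]
      }
      if (!is.null(cross_text)) {
        k <- slots[length(ents) + 1L]
        pieces[[k]] <- cross_text
        piece_meta[[k]] <- list(crossing = TRUE)
      }
      # assemble with exact offsets
      text <- ""
      offset <- 0L
      ann_rows <- list()
      tok_rows <- list()
      for (j in seq_along(pieces)) {
        piece <- pieces[[j]]
        if (nzchar(text)) { text <- paste0(text, " "); offset <- offset + 1L }
        start <- offset
        text <- paste0(text, piece)
        offset <- offset + nchar(piece)
        meta <- piece_meta[[j]]
        if (!is.null(meta) && is.null(meta$crossing)) {
          ann_rows[[length(ann_rows) + 1L]] <- data.frame(
            start = start, end = offset, surface = piece,
            cuis = meta$cuis, group = meta$group, lemma = meta$lemma,
            stringsAsFactors = FALSE)
        }
        # token-level gold
        toks <- strsplit(piece, " ", fixed = TRUE)[[1]]
        for (ti in seq_along(toks)) {
          tk <- toks[ti]
          if (!is.null(meta) && is.null(meta$crossing) && ti == 1L) {
            tok_rows[[length(tok_rows) + 1L]] <- data.frame(
              surface = tk, tag = meta$tag,
              lemma = if (grepl("\\s", meta$lemma))
                strsplit(meta$lemma, " ")[[1]][1] else meta$lemma,
              stringsAsFactors = FALSE)
          } else {
            tok_rows[[length(tok_rows) + 1L]] <- data.frame(
              surface = tk, tag = "OTHER", lemma = tk,
              stringsAsFactors = FALSE)
          }
        }
      }
      text <- paste0(text, " .")
      documents[d] <- text
      gold[[d]] <- if (length(ann_rows)) do.call(rbind, ann_rows) else
        data.frame(start = integer(), end = integer(), surface = character(),
                   cuis = character(), group = character(),
                   lemma = character(), stringsAsFactors = FALSE)
      gold_tokens[[d]] <- do.call(rbind, tok_rows)
    }
    out <- structure(list(
      documents = documents, gold = gold, gold_tokens = gold_tokens,
      overlaps = if (length(overlaps)) do.call(rbind, overlaps) else
        data.frame(doc = integer(), kind = character(),
                   stringsAsFactors = FALSE)
    ), class = "medlex_corpus")
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (d in seq_len(spec$n_docs)) {
        writeLines(enc2utf8(documents[d]),
                   file.path(dir, sprintf("doc%03d.txt", d)), useBytes = TRUE)
        g <- gold[[d]]
        g$pos <- "N"
        class(g) <- c("medlex_annotations", "data.frame")
        write_brat(g, file.path(dir, sprintf("doc%03d.ann", d)))
        write_conllu(gold_tokens[[d]],
                     file.path(dir, sprintf("doc%03d.conllu", d)))
      }
    }
    out
  })
}

#' Generate a toy vector model with planted synonym neighbourhoods
#'
#' Each designated seed term receives `planted_synonyms_per_seed` synonym
#' tokens whose vectors lie within a small angle of the seed vector
#' (cosine > 0.95); distractor tokens are resampled until their similarity
#' to every seed is below 0.5.  Planted synonyms therefore always outrank
#' every distractor for their seed.  Synonym tokens are spelled as
#' `<seed>` with a numeric suffix separated by `x` so they stay outside the
#' lexicon (out-of-vocabulary by construction).
#'
#' @param lx lexicon from [make_toy_lexicon()] (provides the seed terms).
#' @param spec the same [fixture_spec()].
#' @return a `medlex_vectors` model with attributes `seed_terms`,
#'   `planted_synonyms` (named list seed -> synonym tokens) and
#'   `reference_cuis` (named vector synonym token -> the seed's first CUI).
#' @export
make_toy_vectors <- function(lx, spec = fixture_spec()) {
  with_seed(spec$seed + 2L, function() {
    seeds <- attr(lx, "seed_terms")
    if (is.null(seeds) || !length(seeds)) stop("lexicon has no seed terms")
    d <- spec$dim
    unit <- function(v) v / sqrt(sum(v^2))
    max_abs_cos <- function(v, mat) max(abs(mat %*% v))

    seed_mat <- matrix(0, nrow = length(seeds), ncol = d)
    for (i in seq_along(seeds)) {
      repeat {
        v <- unit(rnorm(d))
        if (i == 1L ||
            max_abs_cos(v, seed_mat[seq_len(i - 1L), , drop = FALSE]) < 0.4)
          break
      }
      seed_mat[i, ] <- v
    }
    rownames(seed_mat) <- seeds

    syn_rows <- list(); syn_names <- character(0)
    planted <- list()
    ref_cuis <- character(0)
    for (i in seq_along(seeds)) {
      s <- seed_mat[i, ]
      entry <- lexicon_lookup(lx, seeds[i], by = "lemma")[[1]]
      toks <- character(spec$planted_synonyms_per_seed)
      for (j in seq_len(spec$planted_synonyms_per_seed)) {
        repeat {
          theta <- runif(1, 0.05, 0.25)          # cos(theta) in (0.969, 0.999)
          noise <- rnorm(d); noise <- noise - sum(noise * s) * s
          v <- unit(s * cos(theta) + unit(noise) * sin(theta))
          if (sum(v * s) > 0.95) break
        }
        tok <- paste0(seeds[i], "x", j)
        toks[j] <- tok
        syn_rows[[length(syn_rows) + 1L]] <- v
        syn_names <- c(syn_names, tok)
        ref_cuis[tok] <- entry$cuis[1]
      }
      planted[[seeds[i]]] <- toks
    }

    n_distract <- max(spec$vocab_size - length(seeds) - length(syn_names), 0L)
    distract <- matrix(0, nrow = n_distract, ncol = d)
    i <- 0L
    while (i < n_distract) {
      v <- unit(rnorm(d))
      if (max_abs_cos(v, seed_mat) < 0.5) {
        i <- i + 1L
        distract[i, ] <- v
      }
    }
    if (n_distract > 0)
      rownames(distract) <- paste0("w", sprintf("%05d", seq_len(n_distract)))

    mat <- rbind(seed_mat,
                 if (length(syn_rows)) {
                   m <- do.call(rbind, syn_rows); rownames(m) <- syn_names; m
                 },
                 if (n_distract > 0) distract)
    model <- vector_model(mat)
    attr(model, "seed_terms") <- seeds
    attr(model, "planted_synonyms") <- planted
    attr(model, "reference_cuis") <- ref_cuis
    model
  })
}
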