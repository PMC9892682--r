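# Lexicon-backed lemmatization and PoS assignment, and the evaluation
# protocol over open lexical categories with lenient lemma comparison.

# lexicon PoS -> evaluation tagset; slashed categories are ambiguous and
# resolved against the base tagger's tag.
POS_TO_EVAL <- list(N = "NOUN", NPR = "PROPN", V = "VERB", ADJ = "ADJ",
                    ADV = "ADV", AFF = "OTHER",
                    `ADJ/N` = c("ADJ", "NOUN"),
                    `N/NPR` = c("NOUN", "PROPN"),
                    `ADJ/ADV` = c("ADJ", "ADV"))

# evaluation tag -> compatible lexicon categories (for lemma pos_hint)
EVAL_TO_POS <- list(NOUN = c("N", "ADJ/N", "N/NPR"),
                    PROPN = c("NPR", "N/NPR"),
                    VERB = "V",
                    ADJ = c("ADJ", "ADJ/N", "ADJ/ADV"),
                    ADV = c("ADV", "ADJ/ADV"))

#' Lemmatize one token against the lexicon
#'
#' Looks the case-folded surface up in the form index and returns the lemma
#' of the matching entry.  When several entries share the form, the entry
#' whose category is compatible with `pos_hint` is preferred, then the
#' lexicographically smallest lemma (deterministic tie-break).  An
#' out-of-vocabulary surface falls back to the identity lemma — the surface
#' itself, never an invented string.
#'
#' @param surface token surface (non-empty).
#' @param pos_hint optional evaluation tag (`NOUN`, `PROPN`, `VERB`, `ADJ`,
#'   `ADV`) used to rank candidate entries.
#' @param lx a `medlex_lexicon`.
#' @return list with `lemma` and `source` (`"lexicon"` or `"fallback"`).
#' @export
lemmatize_token <- function(surface, pos_hint = NULL, lx) {
  surface <- nfc(surface)
  if (!nzchar(trimws(surface))) stop("empty surface")
  hits <- lexicon_lookup(lx, surface, by = "form")
  if (!length(hits))
    return(list(lemma = surface, source = "fallback"))
  if (length(hits) > 1L && !is.null(pos_hint) && pos_hint %in% names(EVAL_TO_POS)) {
    compatible <- Filter(function(e) e$pos %in% EVAL_TO_POS[[pos_hint]], hits)
    if (length(compatible)) hits <- compatible
  }
  lemmas <- sort(vapply(hits, `[[`, character(1), "lemma"), method = "radix")
  list(lemma = lemmas[1], source = "lexicon")
}

#' Tag tokens with the lexicon as an override layer
#'
#' The lexicon is layered over the output of any upstream tagger: when a
#' surface is a lexicon form with an unambiguous lexical category, the
#' lexicon tag (mapped to the evaluation tagset) overrides the base tag;
#' a context-ambiguous lexicon category (`ADJ/N`, `N/NPR`, `ADJ/ADV`) defers
#' to the base tag when that tag is one of the listed alternatives and takes
#' the first alternative otherwise; out-of-lexicon tokens keep their base
#' tag.  Lemmas come from [lemmatize_token()] with the resolved tag as hint.
#'
#' @param tokens data.frame with columns `surface` and `base_tag` (tags from
#'   an upstream tagger, possibly all `"OTHER"`), or a character vector of
#'   surfaces (base tags default to `"OTHER"`).
#' @param lx a `medlex_lexicon`.
#' @return data.frame of class `medlex_tagged`: `surface`, `pos`, `lemma`,
#'   `source` (`lexicon`/`fallback`).
#' @export
tag_tokens <- function(tokens, lx) {
  if (is.character(tokens))
    tokens <- data.frame(surface = tokens, base_tag = "OTHER",
                         stringsAsFactors = FALSE)
  if (!all(c("surface", "base_tag") %in% names(tokens)))
    stop("tokens must have columns 'surface' and 'base_tag'")
  if (anyNA(tokens$surface) || anyNA(tokens$base_tag))
    stop("length mismatch: every token needs a surface and a base tag")
  n <- nrow(tokens)
  pos <- character(n); lemma <- character(n); source <- character(n)
  for (i in seq_len(n)) {
    surface <- tokens$surface[i]; base <- tokens$base_tag[i]
    hits <- lexicon_lookup(lx, surface, by = "form")
    if (!length(hits)) {
      pos[i] <- base
    } else {
      cats <- unique(vapply(hits, `[[`, character(1), "pos"))
      mapped <- unique(unlist(POS_TO_EVAL[cats]))
      if (length(mapped) == 1L) {
        pos[i] <- mapped
      } else if (base %in% mapped) {
        pos[i] <- base          # context decides among the alternatives
      } else {
        pos[i] <- mapped[1]
      }
    }
    lem <- lemmatize_token(surface, pos_hint = pos[i], lx = lx)
    lemma[i] <- lem$lemma
    source[i] <- lem$source
  }
  out <- data.frame(surface = tokens$surface, pos = pos, lemma = lemma,
                    source = source, stringsAsFactors = FALSE)
  class(out) <- c("medlex_tagged", "data.frame")
  out
}

f1_of <- function(p, r) if ((p + r) > 0) 2 * p * r / (p + r) else 0

#' Evaluate tagging or lemmatization against a gold standard
#'
#' Token-aligned comparison restricted to the open lexical categories
#' (`ADJ`, `ADV`, `NOUN`, `PROPN`, `VERB`) of the gold standard.  In `pos`
#' mode, per-category precision/recall/F1 are computed one-vs-rest over the
#' restricted token set, with micro and macro aggregates.  In `lemma` mode
#' the lenient criterion applies: lemmas are compared after accent stripping
#' and case folding, so diacritic-only differences are not errors; the
#' per-category score is the proportion of tokens with a matching lemma
#' (precision = recall per category in this single-label setting).
#'
#' @param pred data.frame with columns `surface`, `pos`, `lemma`
#'   (e.g. from [tag_tokens()]).
#' @param gold data.frame with columns `surface`, `tag`, `lemma`, aligned
#'   token-by-token with `pred`.
#' @param mode `"pos"` or `"lemma"`.
#' @return object of class `medlex_eval`: list with `per_category`
#'   (data.frame `category`, `precision`, `recall`, `f1`, `n`), `aggregate`
#'   (micro), `macro`, and `n_tokens` (evaluated tokens).
#' @export
evaluate <- function(pred, gold, mode = c("pos", "lemma")) {
  mode <- match.arg(mode)
  if (nrow(pred) != nrow(gold))
    stop("misaligned sequences: pred has ", nrow(pred), " tokens, gold has ",
         nrow(gold))
  mism <- which(fold_key(pred$surface) != fold_key(gold$surface))
  if (length(mism))
    stop("misaligned sequences: first surface mismatch at position ",
         mism[1], " ('", pred$surface[mism[1]], "' vs '",
         gold$surface[mism[1]], "')")
  keep <- gold$tag %in% LEXICAL_TAGS
  p <- pred[keep, , drop = FALSE]
  g <- gold[keep, , drop = FALSE]
  n <- nrow(g)
  if (!n) stop("no tokens in the open lexical categories to evaluate")
  cats <- intersect(LEXICAL_TAGS, unique(c(g$tag, p$pos)))

  if (mode == "pos") {
    rows <- lapply(cats, function(cat) {
      tp <- sum(p$pos == cat & g$tag == cat)
      fp <- sum(p$pos == cat & g$tag != cat)
      fn <- sum(p$pos != cat & g$tag == cat)
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      data.frame(category = cat, precision = prec, recall = rec,
                 f1 = f1_of(prec, rec), n = sum(g$tag == cat),
                 stringsAsFactors = FALSE)
    })
    correct <- sum(p$pos == g$tag)
    micro_p <- correct / n  # single-label: micro precision = recall
    aggregate <- c(precision = micro_p, recall = micro_p,
                   f1 = f1_of(micro_p, micro_p))
  } else {
    ok <- fold_accent_key(p$lemma) == fold_accent_key(g$lemma)
    rows <- lapply(cats, function(cat) {
      in_cat <- g$tag == cat
      acc <- if (any(in_cat)) mean(ok[in_cat]) else 0
      data.frame(category = cat, precision = acc, recall = acc,
                 f1 = f1_of(acc, acc), n = sum(in_cat),
                 stringsAsFactors = FALSE)
    })
    micro <- mean(ok)
    aggregate <- c(precision = micro, recall = micro, f1 = f1_of(micro, micro))
  }
  per_category <- do.call(rbind, rows)
  macro <- c(precision = mean(per_category$precision),
             recall = mean(per_category$recall),
             f1 = mean(per_category$f1))
  structure(list(per_category = per_category, aggregate = aggregate,
                 macro = macro, n_tokens = n, mode = mode),
            class = "medlex_eval")
}

#' @export
print.medlex_eval <- function(x, ...) {
  cat(sprintf("<medlex_eval> mode=%s, %d tokens | micro P=%.3f R=%.3f F1=%.3f\n",
              x$mode, x$n_tokens, x$aggregate["precision"],
              x$aggregate["recall"], x$aggregate["f1"]))
  print(x$per_category, row.names = FALSE)
  invisible(x)
}

#' Read a CoNLL-U file (FORM, UPOS, LEMMA columns)
#'
#' @param path file path.
#' @return data.frame `surface`, `tag`, `lemma` (comment lines and multiword
#'   range lines skipped).
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(nfc(ln), "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L || grepl("[-.]", f[1])) return(NULL)
    data.frame(surface = f[2], tag = f[4], lemma = f[3],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(surface = character(), tag = character(),
                      lemma = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write tokens in CoNLL-U format
#'
#' @param tokens data.frame with `surface`, `lemma` and a tag column (`pos`
#'   or `tag`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(tokens, path) {
  tag <- if ("pos" %in% names(tokens)) tokens$pos else tokens$tag
  lines <- vapply(seq_len(nrow(tokens)), function(i)
    paste(i, tokens$surface[i], tokens$lemma[i], tag[i],
          "_", "_", "_", "_", "_", "_", sep = "\t"), character(1))
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}
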