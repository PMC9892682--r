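# Independent oracles used across the suite.  These deliberately take the
# slow, obviously-correct route (memoized recursion, exhaustive scans) and
# share no code with the implementation paths they check.

# Levenshtein distance by memoized recursion on the textbook definition.
lev_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- if (a[i] == b[j]) 0 else 1
    val <- min(rec(i - 1, j) + 1, rec(i, j - 1) + 1, rec(i - 1, j - 1) + cost)
    memo[[key]] <- val
    val
  }
  rec(length(a), length(b))
}

# Cosine by direct formula on raw (un-normalized) vectors.
cos_oracle <- function(s, w) sum(s * w) / sqrt(sum(s^2) * sum(w^2))

# Nearest neighbours by an explicit per-token loop over the raw vectors.
nn_oracle <- function(model, term, k) {
  vocab <- setdiff(model$vocab, term)
  sims <- vapply(vocab, function(tok)
    cos_oracle(model$vectors[term, ], model$vectors[tok, ]), numeric(1))
  ord <- order(-sims, vocab, method = "radix")
  top <- ord[seq_len(min(k, length(vocab)))]
  data.frame(token = vocab[top], similarity = unname(sims[top]),
             stringsAsFactors = FALSE)
}

# Positional brute-force dictionary matcher: try every lexicon form at every
# token-boundary position of the document.
match_oracle <- function(text, lx, groups = NULL) {
  text <- medlex::nfc(text)
  spans <- medlex:::token_spans(text)
  rows <- list()
  for (i in seq_along(lx$entries)) {
    e <- lx$entries[[i]]
    if (!is.null(groups) && !e$semantic_group %in% groups) next
    for (r in seq_len(nrow(e$forms))) {
      surface <- e$forms$surface[r]
      exact <- e$forms$variant_type[r] %in% c("acronym", "abbreviation")
      ftoks <- medlex:::token_spans(surface)$token
      if (!length(ftoks)) next
      L <- length(ftoks)
      for (p in seq_len(max(nrow(spans) - L + 1L, 0))) {
        window <- spans$token[p:(p + L - 1L)]
        ok <- if (exact) identical(medlex::nfc(window), medlex::nfc(ftoks))
              else identical(medlex:::fold_key(window), medlex:::fold_key(ftoks))
        if (ok)
          rows[[length(rows) + 1L]] <- data.frame(
            start = spans$start[p], end = spans$end[p + L - 1L],
            group = e$semantic_group, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(start = integer(), end = integer(), group = character())
  out[order(out$start, out$end, out$group, method = "radix"), , drop = FALSE]
}

# Per-category precision/recall/F1 from an explicitly built confusion matrix.
eval_oracle <- function(pred_tags, gold_tags, categories) {
  keep <- gold_tags %in% categories
  p <- pred_tags[keep]; g <- gold_tags[keep]
  out <- list()
  for (cat in intersect(categories, unique(c(g, p)))) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(g)) {
      if (p[i] == cat && g[i] == cat) tp <- tp + 1
      if (p[i] == cat && g[i] != cat) fp <- fp + 1
      if (p[i] != cat && g[i] == cat) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out[[cat]] <- c(precision = prec, recall = rec, f1 = f1)
  }
  out
}

# No-crossing / no-same-group-nesting audit of an annotation set.
overlap_violations <- function(ann) {
  n <- nrow(ann); bad <- 0L
  if (n > 1) for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    si <- ann$start[i]; ei <- ann$end[i]
    sj <- ann$start[j]; ej <- ann$end[j]
    nested <- identical(ann$group[i], ann$group[j]) &&
      ((si <= sj && ej <= ei && (ei - si) > (ej - sj)) ||
       (sj <= si && ei <= ej && (ej - sj) > (ei - si)))
    crossing <- (si < sj && sj < ei && ei < ej) ||
                (sj < si && si < ej && ej < ei)
    if (nested || crossing) bad <- bad + 1L
  }
  bad
}

# Forms table from bare surfaces.
forms_rows <- function(surfaces)
  do.call(rbind, lapply(surfaces, medlex::word_form))

# Small handcrafted Spanish lexicon used by annotator/tagger examples.
spanish_demo_lexicon <- function() {
  lexicon(list(
    lexical_entry("radio", "N", c("C0034627", "C1279083"),
                  semantic_types = "Body Part, Organ, or Organ Component",
                  semantic_group = "ANAT",
                  lemma_morph = morph_features(gender = "masculine",
                                               number = "singular")),
    lexical_entry("radio", "N", "C0034625",
                  semantic_types = "Element, Ion, or Isotope",
                  semantic_group = "CHEM"),
    lexical_entry("dolor", "N", "C0030193", semantic_group = "DISO",
                  forms = word_form("dolores", morph_features(
                    gender = "masculine", number = "plural"))),
    lexical_entry("dolor de cabeza", "N", "C0018681",
                  semantic_group = "DISO"),
    lexical_entry("fractura", "N", "C0016658", semantic_group = "DISO"),
    lexical_entry("hematíe", "N", "C0014792", semantic_group = "ANAT",
                  forms = word_form("hematíes", morph_features(
                    gender = "masculine", number = "plural"))),
    lexical_entry("páncreas", "N", "C0030274", semantic_group = "ANAT",
                  lemma_morph = morph_features(gender = "masculine",
                                               number = "singular_and_plural")),
    lexical_entry("corticoide", "N", "C0001617", semantic_group = "CHEM",
                  forms = word_form("corticoides", morph_features(
                    gender = "masculine", number = "plural"))),
    lexical_entry("UCI", "N", "C0021708", semantic_group = "PROC",
                  lemma_morph = morph_features(variant_type = "acronym")),
    lexical_entry("úrico", "ADJ", "C0041980", semantic_group = "CHEM"),
    lexical_entry("administración de vacunas", "N", "C0042196",
                  semantic_group = "PROC"),
    lexical_entry("vacunas vivas", "N", "C0042210", semantic_group = "CHEM"),
    lexical_entry("síndrome", "N", "C0039082", semantic_group = "DISO",
                  lemma_morph = morph_features(gender = "masculine",
                                               number = "singular")),
    lexical_entry("enfermedad", "N", "C0012634", semantic_group = "DISO",
                  lemma_morph = morph_features(gender = "feminine",
                                               number = "singular"))
  ))
}
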