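# Seed-term expansion: corpus text normalization, OOV filtering against the
# lexicon, and the aggregate nearest-neighbour report.

#' Normalize corpus text into a token stream
#'
#' Applies the pre-processing used before training/querying word vectors:
#' URLs and non-printable/undecodable characters are removed, punctuation is
#' split from adjacent tokens, and (optionally) the text is lowercased.
#' Intra-token hyphens are preserved so that hyphenated terms (e.g. disease
#' names with numerals) survive as single tokens.
#'
#' @param raw character scalar (may span lines).
#' @param lowercase lowercase the tokens (uncased models)?
#' @return character vector of tokens (possibly empty).
#' @export
#' @examples
#' normalize_text("COVID-19, grave.")
normalize_text <- function(raw, lowercase = FALSE) {
  if (!length(raw)) return(character(0))
  x <- nfc(paste(raw, collapse = " "))
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x)
  x <- stringi::stri_replace_all_regex(x, "[\\p{C}�]", " ")
  # split punctuation off tokens; keep hyphens between alphanumerics
  x <- stringi::stri_replace_all_regex(
    x, "(?<![\\p{L}\\p{N}])-|-(?![\\p{L}\\p{N}])", " - ")
  x <- stringi::stri_replace_all_regex(x, "([\\p{P}\\p{S}--[-]])", " $1 ")
  if (lowercase) x <- stringi::stri_trans_tolower(x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Filter tokens that are out of vocabulary with respect to the lexicon
#'
#' A token is out of vocabulary (OOV) when its surface matches no lexicon
#' form under NFC normalization and case folding.  Input order is preserved
#' and duplicates are kept (deduplication happens only in the aggregate
#' expansion report).
#'
#' @param tokens character vector.
#' @param lx a `medlex_lexicon`.
#' @return the OOV subset of `tokens`.
#' @export
filter_oov <- function(tokens, lx) {
  if (!length(tokens)) return(character(0))
  known <- vapply(tokens, function(t)
    length(lexicon_lookup(lx, t, by = "form")) > 0, logical(1))
  unname(tokens[!known])
}

#' Expand seed terms by embedding nearest neighbours
#'
#' For each seed term, retrieves the `k` most cosine-similar vocabulary
#' tokens, then screens the retrieved candidates against the lexicon:
#' candidates already attested as lexicon forms are in-vocabulary, the rest
#' are out-of-vocabulary (OOV) candidates for manual concept lookup.  An
#' explicit `reference_cuis` map (token -> CUI) stands in for that manual
#' terminology lookup and determines which OOV candidates are mappable to a
#' concept.
#'
#' @param model a `medlex_vectors`.
#' @param seeds character vector of seed terms; seeds missing from the
#'   vocabulary are reported and skipped (all missing is an error).
#' @param k retrieval depth per seed (default 50).
#' @param lx a `medlex_lexicon` used for the OOV screen.
#' @param reference_cuis optional named character vector token -> CUI.
#' @return object of class `medlex_expansion`: list with `per_seed` (named
#'   list of neighbour data.frames), `skipped_seeds`, `n_candidates` (total
#'   retrieved, duplicates across seeds counted), `oov` (deduplicated OOV
#'   tokens in first-retrieval order), `n_oov_raw`, `oov_fraction` (percent
#'   of retrieved candidates that are OOV), `mappable` (data.frame `token`,
#'   `cui`), and `mappable_fraction_of_oov` (percent of deduplicated OOVs
#'   with a reference concept).
#' @export
expand_seed_terms <- function(model, seeds, k = 50L, lx,
                              reference_cuis = NULL) {
  seeds <- nfc(seeds)
  usable <- seeds[seeds %in% model$vocab]
  skipped <- setdiff(seeds, usable)
  if (length(skipped))
    message("seed(s) not in vocabulary, skipped: ",
            paste(skipped, collapse = ", "))
  if (!length(usable)) stop("no usable seed terms")
  per_seed <- lapply(usable, nearest_neighbors, model = model, k = k)
  names(per_seed) <- usable
  retrieved <- unlist(lapply(per_seed, `[[`, "token"), use.names = FALSE)
  n_candidates <- length(retrieved)
  oov_raw <- filter_oov(retrieved, lx)
  oov <- unique(oov_raw)
  mappable <- if (!is.null(reference_cuis)) {
    hit <- oov[oov %in% names(reference_cuis)]
    data.frame(token = hit, cui = unname(reference_cuis[hit]),
               stringsAsFactors = FALSE)
  } else data.frame(token = character(), cui = character(),
                    stringsAsFactors = FALSE)
  structure(list(
    per_seed = per_seed, skipped_seeds = skipped,
    n_candidates = n_candidates,
    oov = oov, n_oov_raw = length(oov_raw),
    oov_fraction = round(100 * length(oov_raw) / n_candidates, 2),
    mappable = mappable,
    mappable_fraction_of_oov = if (length(oov))
      round(100 * nrow(mappable) / length(oov), 2) else 0
  ), class = "medlex_expansion")
}

#' @export
print.medlex_expansion <- function(x, ...) {
  cat(sprintf(paste0("<medlex_expansion> %d seeds, %d candidates | ",
                     "OOV %.2f%% (%d unique) | %.2f%% of OOVs mappable\n"),
              length(x$per_seed), x$n_candidates, x$oov_fraction,
              length(x$oov), x$mappable_fraction_of_oov))
  invisible(x)
}

#' Write an expansion report as a delimited table
#'
#' One row per retrieved candidate: seed, rank, token, similarity, OOV flag
#' and reference CUI (when mappable).  Deterministic ordering (seed order,
#' then rank).
#'
#' @param report a `medlex_expansion`.
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_expansion_report <- function(report, path, delim = "\t") {
  rows <- c(paste("seed", "rank", "token", "similarity", "oov", "cui",
                  sep = delim))
  cui_of <- setNames(report$mappable$cui, report$mappable$token)
  for (seed in names(report$per_seed)) {
    nn <- report$per_seed[[seed]]
    for (i in seq_len(nrow(nn))) {
      tok <- nn$token[i]
      rows <- c(rows, paste(seed, i, tok,
                            formatC(nn$similarity[i], digits = 4, format = "f"),
                            as.integer(tok %in% report$oov),
                            if (tok %in% names(cui_of)) cui_of[[tok]] else "",
                            sep = delim))
    }
  }
  writeLines(enc2utf8(rows), path, useBytes = TRUE)
  invisible(path)
}
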