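#' Descriptive statistics of a lexicon
#'
#' Counts lemmas (entries), word forms (distinct `(lemma, surface)` pairs) and
#' CUIs, the mean number of lemmas and forms per CUI (2 decimals), and the
#' part-of-speech and semantic-group distributions.
#'
#' @param lx a non-empty `medlex_lexicon`.
#' @return object of class `medlex_stats` with fields `n_lemmas`, `n_forms`,
#'   `n_cuis`, `mean_lemmas_per_cui`, `mean_forms_per_cui`,
#'   `pos_distribution` (data.frame `pos`, `count`, `percent`) and
#'   `group_distribution` (data.frame `group`, `percent`).
#' @export
lexicon_stats <- function(lx) {
  if (!lexicon_size(lx))
    stop("empty lexicon: no statistics to report")
  lemmas <- vapply(lx$entries, `[[`, character(1), "lemma")
  pos <- vapply(lx$entries, `[[`, character(1), "pos")
  groups <- vapply(lx$entries, `[[`, character(1), "semantic_group")
  n_lemmas <- length(lx$entries)
  n_forms <- sum(vapply(lx$entries, function(e)
    length(unique(e$forms$surface)), integer(1)))
  n_cuis <- length(unique(unlist(lapply(lx$entries, `[[`, "cuis"))))
  means <- stats_from_counts(n_lemmas, n_forms, n_cuis)
  pos_tab <- sort(table(pos), decreasing = TRUE)
  pos_df <- data.frame(pos = names(pos_tab), count = as.integer(pos_tab),
                       percent = round(100 * as.integer(pos_tab) / n_lemmas, 2),
                       stringsAsFactors = FALSE)
  grp_tab <- sort(table(groups[nzchar(groups)]), decreasing = TRUE)
  grp_df <- data.frame(group = names(grp_tab),
                       percent = round(100 * as.integer(grp_tab) /
                                         sum(grp_tab), 2),
                       stringsAsFactors = FALSE)
  structure(list(n_lemmas = n_lemmas, n_forms = n_forms, n_cuis = n_cuis,
                 mean_lemmas_per_cui = means$mean_lemmas_per_cui,
                 mean_forms_per_cui = means$mean_forms_per_cui,
                 pos_distribution = pos_df, group_distribution = grp_df),
            class = "medlex_stats")
}

#' Lemma/form-per-CUI ratios from raw counts
#'
#' The per-concept density statistics computed from total counts alone, so
#' that published lexicon-scale tallies can be summarized without the entries
#' themselves.
#'
#' @param n_lemmas,n_forms,n_cuis positive counts.
#' @return list with `mean_lemmas_per_cui` and `mean_forms_per_cui`,
#'   each rounded to 2 decimals.
#' @export
#' @examples
#' stats_from_counts(100887, 302543, 42958)  # 2.35 lemmas, 7.04 forms per CUI
stats_from_counts <- function(n_lemmas, n_forms, n_cuis) {
  if (n_cuis <= 0) stop("n_cuis must be positive")
  list(mean_lemmas_per_cui = round(n_lemmas / n_cuis, 2),
       mean_forms_per_cui = round(n_forms / n_cuis, 2))
}

#' @export
print.medlex_stats <- function(x, ...) {
  cat(sprintf(paste0("<medlex_stats> %d lemmas, %d forms, %d CUIs | ",
                     "%.2f lemmas/CUI, %.2f forms/CUI\n"),
              x$n_lemmas, x$n_forms, x$n_cuis,
              x$mean_lemmas_per_cui, x$mean_forms_per_cui))
  print(x$pos_distribution, row.names = FALSE)
  invisible(x)
}
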