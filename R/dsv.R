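#' Parse one record of the delimited lexicon format
#'
#' The distribution format is a UTF-8 delimiter-separated file with six
#' fields: concept identifier(s), lemma, variant forms, part-of-speech,
#' semantic type(s), semantic group.  Multiple CUIs, forms and semantic types
#' within a field are separated by `;`.  The format carries surfaces only:
#' per-form morphological features live in the LMF serialization.
#'
#' @param line one line of text.
#' @param delim field delimiter (default `"|"`).
#' @param line_number used in error messages.
#' @param allow_no_cui accept a record with an empty CUI field?
#' @return a [lexical_entry()].
#' @export
#' @examples
#' parse_dsv_record(
#'   "C0019080|sangrar|sangrar;sangra;sangrando;sangrado|V|Pathologic Function|DISO")
parse_dsv_record <- function(line, delim = "|", line_number = NA,
                             allow_no_cui = FALSE) {
  fields <- strsplit(nfc(line), delim, fixed = TRUE)[[1]]
  # a trailing empty field (e.g. "a|b|c|d|e|") is preserved by padding
  if (length(fields) == 5L && endsWith(line, delim)) fields <- c(fields, "")
  if (length(fields) != 6L)
    stop(sprintf("malformed record%s: expected 6 fields, got %d",
                 if (is.na(line_number)) "" else paste0(" at line ", line_number),
                 length(fields)))
  split_multi <- function(x) {
    parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    parts[nzchar(parts)]
  }
  cuis <- split_multi(fields[1])
  lemma <- trimws(fields[2])
  surfaces <- unique(split_multi(fields[3]))
  pos <- trimws(fields[4])
  if (!pos %in% POS_CATEGORIES)
    stop(sprintf("unknown part-of-speech tag '%s'%s", pos,
                 if (is.na(line_number)) "" else paste0(" at line ", line_number)))
  types <- split_multi(fields[5])
  group <- trimws(fields[6])
  forms <- if (length(surfaces))
    do.call(rbind, lapply(surfaces, word_form)) else NULL
  lexical_entry(lemma, pos, cuis, semantic_types = types,
                semantic_group = group, forms = forms)
}

format_dsv_record <- function(e, delim = "|") {
  surfaces <- unique(e$forms$surface)
  # citation form first, remaining forms in codepoint order
  rest <- sort(setdiff(surfaces, e$lemma), method = "radix")
  paste(paste(e$cuis, collapse = ";"), e$lemma,
        paste(c(e$lemma, rest), collapse = ";"), e$pos,
        paste(e$semantic_types, collapse = ";"), e$semantic_group,
        sep = delim)
}

#' Read a lexicon file
#'
#' @param path file path (UTF-8).
#' @param format `"dsv"` (delimited, six fields) or `"lmf"` (LMF XML).
#' @param delim DSV field delimiter.
#' @param allow_no_cui accept CUI-less entries?
#' @return a `medlex_lexicon`.  Records sharing `(lemma, pos, cui-set)` are
#'   merged with form-set union; the number of merged duplicates is kept in
#'   the `n_duplicates` field.  An empty file yields an empty lexicon with a
#'   warning.
#' @export
read_lexicon <- function(path, format = c("dsv", "lmf"), delim = "|",
                         allow_no_cui = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "lmf") return(read_lexicon_lmf(path, allow_no_cui))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty lexicon file: ", path)
    return(lexicon())
  }
  entries <- lapply(seq_along(lines), function(i)
    parse_dsv_record(lines[i], delim = delim, line_number = i,
                     allow_no_cui = allow_no_cui))
  lx <- lexicon(entries, allow_no_cui = allow_no_cui)
  if (lx$n_duplicates > 0L)
    message(lx$n_duplicates, " duplicate record(s) merged")
  lx
}

#' Write a lexicon file
#'
#' Output is deterministic: entries are sorted by (first CUI, lemma) in
#' codepoint order.  The LMF serialization encodes every morphological
#' attribute of every form as feature name/value pairs and is lossless; the
#' DSV serialization carries surfaces only.
#'
#' @param lx a validated `medlex_lexicon`.
#' @param path output file path.
#' @param format `"dsv"` or `"lmf"`.
#' @param delim DSV field delimiter.
#' @param allow_no_cui validate with CUI-less entries allowed?
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lx, path, format = c("dsv", "lmf"), delim = "|",
                          allow_no_cui = FALSE) {
  format <- match.arg(format)
  validate_lexicon(lx, allow_no_cui = allow_no_cui)
  ord <- sort_entry_ids(lx)
  if (format == "dsv") {
    lines <- vapply(lx$entries[ord], format_dsv_record, character(1),
                    delim = delim)
    writeLines(enc2utf8(lines), path, useBytes = TRUE)
  } else {
    write_lexicon_lmf(lx$entries[ord], path)
  }
  invisible(path)
}
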