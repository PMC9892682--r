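#' Read companion Lexical Record (LR) tables
#'
#' Lexical Records are small two- or three-column delimited tables that
#' accompany the lexicon: abbreviation/acronym to full form, affix to
#' gloss (optionally with a CUI), deverbal noun to verb, and
#' denominal adjective to noun.
#'
#' @param paths named list/character vector mapping record kinds
#'   (`abbreviations`, `affixes`, `deverbal`, `denominal_adj`) to file paths;
#'   kinds may be omitted.
#' @param delim field delimiter (default `"|"`).
#' @return object of class `medlex_records`: a list of data.frames
#'   `abbreviations` (`short`, `full`), `affixes` (`affix`, `gloss`, `cui`),
#'   `deverbal` (`noun`, `verb`), `denominal_adj` (`adjective`, `noun`),
#'   with per-table counts in the `counts` attribute.
#' @export
read_lexical_records <- function(paths, delim = "|") {
  kinds <- c("abbreviations", "affixes", "deverbal", "denominal_adj")
  unknown <- setdiff(names(paths), kinds)
  if (length(unknown)) stop("unknown record kind(s): ",
                            paste(unknown, collapse = ", "))
  read_table <- function(path, n_min, n_max, cols) {
    empty <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
    if (is.null(path)) return(empty)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(empty)
    rows <- lapply(seq_along(lines), function(i) {
      f <- trimws(nfc(strsplit(lines[i], delim, fixed = TRUE)[[1]]))
      if (length(f) < n_min || length(f) > n_max)
        stop(sprintf("malformed record at row %d of '%s': %d field(s)",
                     i, path, length(f)))
      length(f) <- length(cols)          # pad optional columns with NA
      f[is.na(f)] <- ""
      f
    })
    out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(out) <- cols
    out
  }
  rec <- structure(list(
    abbreviations = read_table(paths[["abbreviations"]], 2, 2,
                               c("short", "full")),
    affixes = read_table(paths[["affixes"]], 2, 3,
                         c("affix", "gloss", "cui")),
    deverbal = read_table(paths[["deverbal"]], 2, 2, c("noun", "verb")),
    denominal_adj = read_table(paths[["denominal_adj"]], 2, 2,
                               c("adjective", "noun"))
  ), class = "medlex_records")
  # affixes must mark their attachment side with a hyphen
  aff <- rec$affixes$affix
  bad <- aff[!grepl("^-|-$", aff)]
  if (length(bad))
    stop("affix without leading/trailing hyphen: ", paste(bad, collapse = ", "))
  attr(rec, "counts") <- vapply(rec[kinds], nrow, integer(1))
  rec
}

#' Construct Lexical Records in code
#'
#' Programmatic constructor used by the fixture generator and tests; the same
#' container [read_lexical_records()] builds from files.
#'
#' @param abbreviations data.frame with columns `short`, `full`.
#' @param affixes data.frame with columns `affix`, `gloss`, `cui`.
#' @param deverbal data.frame with columns `noun`, `verb`.
#' @param denominal_adj data.frame with columns `adjective`, `noun`.
#' @return a `medlex_records` object.
#' @export
lexical_records <- function(abbreviations = NULL, affixes = NULL,
                            deverbal = NULL, denominal_adj = NULL) {
  df <- function(x, cols) {
    if (is.null(x))
      return(as.data.frame(setNames(rep(list(character()), length(cols)), cols)))
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    for (cl in setdiff(cols, names(x))) x[[cl]] <- ""
    x[cols]
  }
  rec <- structure(list(
    abbreviations = df(abbreviations, c("short", "full")),
    affixes = df(affixes, c("affix", "gloss", "cui")),
    deverbal = df(deverbal, c("noun", "verb")),
    denominal_adj = df(denominal_adj, c("adjective", "noun"))
  ), class = "medlex_records")
  attr(rec, "counts") <- vapply(rec, nrow, integer(1))
  rec
}

#' @export
print.medlex_records <- function(x, ...) {
  cts <- attr(x, "counts")
  cat("<medlex_records>",
      paste(sprintf("%s=%d", names(cts), cts), collapse = ", "), "\n")
  invisible(x)
}

#' Write Lexical Record tables to delimited files
#'
#' @param records a `medlex_records` object.
#' @param dir output directory.
#' @param delim field delimiter.
#' @return named vector of written paths, invisibly.
#' @export
write_lexical_records <- function(records, dir, delim = "|") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fname <- c(abbreviations = "LR_abr.dsv", affixes = "LR_affix.dsv",
             deverbal = "LR_n_v.dsv", denominal_adj = "LR_adj_n.dsv")
  paths <- character(0)
  for (kind in names(fname)) {
    tab <- records[[kind]]
    p <- file.path(dir, fname[[kind]])
    lines <- if (nrow(tab))
      do.call(paste, c(unname(as.list(tab)), list(sep = delim))) else character()
    # drop trailing empty optional column
    lines <- sub(paste0("\\", delim, "$"), "", lines)
    writeLines(enc2utf8(lines), p, useBytes = TRUE)
    paths[kind] <- p
  }
  invisible(paths)
}
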