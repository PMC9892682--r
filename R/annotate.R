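# Dictionary-based pre-annotation: token-aligned multiword matching over the
# lexicon's surface forms, nested/crossing span pruning, BRAT standoff
# output and corpus term-frequency counts.

# Token spans of a document: start/end are 0-based, end-exclusive character
# offsets.  Tokens are maximal runs of letters/digits/underscore, keeping
# intra-token hyphens; every other non-space character is its own token
# (consistent with normalize_text()).
token_spans <- function(text) {
  text <- nfc(text)
  m <- stringi::stri_locate_all_regex(
    text, "[\\p{L}\\p{N}_]+(-[\\p{L}\\p{N}_]+)*|[^\\p{L}\\p{N}_\\s]")[[1]]
  if (is.null(dim(m)) || nrow(m) == 0 || is.na(m[1, 1]))
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  data.frame(token = stringi::stri_sub(text, m[, 1], m[, 2]),
             start = m[, 1] - 1L, end = m[, 2],
             stringsAsFactors = FALSE)
}

#' Build a matcher index over lexicon forms
#'
#' Indexes every surface form of the selected entries as a normalized token
#' sequence.  Non-acronym forms are matched case-insensitively (NFC +
#' case-folding); forms typed `acronym` or `abbreviation` keep their exact
#' casing so that a lowercased look-alike word does not fire the short form.
#'
#' @param lx a non-empty `medlex_lexicon`.
#' @param groups optional character vector of semantic groups to index (e.g.
#'   `c("ANAT", "CHEM", "DISO", "PROC")`); an empty selection is an error.
#' @return object of class `medlex_matcher`.
#' @export
build_matcher_index <- function(lx, groups = NULL) {
  if (!lexicon_size(lx)) stop("empty lexicon")
  ids <- seq_along(lx$entries)
  if (!is.null(groups)) {
    ids <- ids[vapply(lx$entries, function(e)
      e$semantic_group %in% groups, logical(1))]
    if (!length(ids))
      stop("group filter removed every entry: ",
           paste(groups, collapse = ", "))
  }
  index <- new.env(parent = emptyenv())
  max_len <- 1L
  for (i in ids) {
    e <- lx$entries[[i]]
    for (r in seq_len(nrow(e$forms))) {
      surface <- e$forms$surface[r]
      exact <- e$forms$variant_type[r] %in% c("acronym", "abbreviation")
      toks <- token_spans(surface)$token
      if (!length(toks)) next
      key <- paste(if (exact) nfc(toks) else fold_key(toks), collapse = " ")
      key <- paste0(if (exact) "E\r" else "F\r", key)
      index[[key]] <- unique(c(index[[key]], i))
      max_len <- max(max_len, length(toks))
    }
  }
  structure(list(index = index, max_len = max_len, lexicon = lx,
                 groups = groups), class = "medlex_matcher")
}

#' All dictionary matches in a text
#'
#' Slides over the document's token sequence and reports every span whose
#' token sequence equals an indexed lexicon form (folded for ordinary forms,
#' exact-case for acronyms/abbreviations).  All candidate concepts of the
#' matched form are attached — lexical ambiguity is preserved for later
#' (manual) disambiguation — and overlapping matches are all returned;
#' [prune_annotations()] resolves the overlaps.
#'
#' @param text document string.
#' @param matcher a `medlex_matcher`.
#' @return data.frame of class `medlex_annotations`: `start`, `end` (0-based,
#'   end-exclusive character offsets), `surface`, `cuis` (`;`-joined),
#'   `group`, `lemma`, `pos`; sorted by (start, end).
#' @export
match_all <- function(text, matcher) {
  text <- nfc(text)
  spans <- token_spans(text)
  lx <- matcher$lexicon
  rows <- list()
  n <- nrow(spans)
  for (i in seq_len(max(n, 0))) {
    for (len in seq_len(min(matcher$max_len, n - i + 1L))) {
      toks <- spans$token[i:(i + len - 1L)]
      ids <- c(matcher$index[[paste0("F\r", paste(fold_key(toks), collapse = " "))]],
               matcher$index[[paste0("E\r", paste(nfc(toks), collapse = " "))]])
      if (is.null(ids)) next
      start <- spans$start[i]; end <- spans$end[i + len - 1L]
      surface <- stringi::stri_sub(text, start + 1L, end)
      for (id in unique(ids)) {
        e <- lx$entries[[id]]
        rows[[length(rows) + 1L]] <- data.frame(
          start = start, end = end, surface = surface,
          cuis = paste(e$cuis, collapse = ";"),
          group = e$semantic_group, lemma = e$lemma, pos = e$pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), surface = character(),
               cuis = character(), group = character(), lemma = character(),
               pos = character(), stringsAsFactors = FALSE)
  # one annotation per span+group: merge concept candidates of co-extensive
  # matches from different entries of the same group
  if (nrow(out)) {
    key <- paste(out$start, out$end, out$group, sep = "\r")
    merged <- lapply(split(seq_len(nrow(out)), key), function(ii) {
      first <- out[ii[1], , drop = FALSE]
      first$cuis <- paste(sort(unique(unlist(
        strsplit(out$cuis[ii], ";", fixed = TRUE)))), collapse = ";")
      first$lemma <- out$lemma[ii[1]]
      first
    })
    out <- do.call(rbind, merged)
    out <- out[order(out$start, out$end, out$group, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("medlex_annotations", "data.frame")
  out
}

# does a properly contain b?
properly_contains <- function(a_start, a_end, b_start, b_end) {
  a_start <= b_start && b_end <= a_end &&
    (a_end - a_start) > (b_end - b_start)
}

#' Prune nested and crossing annotations
#'
#' Applies the two span-correction rules used when cleaning dictionary
#' pre-annotations: (1) an annotation properly contained in a longer
#' annotation of the same semantic group is removed — the less specific of
#' the two entities; (2) two partially overlapping (crossing) annotations
#' are corrected to independent entities by truncating the later-starting
#' span to begin after the earlier span ends (re-aligned to the next token,
#' with the surface re-sliced from the document).  The output is sorted by
#' `(start, end)` and contains no properly nested same-group pair and no
#' crossing pair.
#'
#' @param annotations a `medlex_annotations` data.frame for one document.
#' @param text the document the annotations belong to (needed to re-slice
#'   truncated surfaces).
#' @return pruned `medlex_annotations`.
#' @export
prune_annotations <- function(annotations, text) {
  text <- nfc(text)
  ann <- as.data.frame(annotations)
  repeat {
    n <- nrow(ann)
    if (n <= 1L) break
    ann <- ann[order(ann$start, -ann$end, method = "radix"), , drop = FALSE]
    rownames(ann) <- NULL
    changed <- FALSE
    drop <- rep(FALSE, n)
    for (i in seq_len(n - 1L)) {
      if (drop[i]) next
      for (j in seq((i + 1L), n)) {
        if (drop[i] || drop[j]) next
        si <- ann$start[i]; ei <- ann$end[i]
        sj <- ann$start[j]; ej <- ann$end[j]
        if (sj >= ei) break  # sorted: no further overlap with i
        same_group <- identical(ann$group[i], ann$group[j])
        if (same_group && properly_contains(si, ei, sj, ej)) {
          drop[j] <- TRUE; changed <- TRUE
        } else if (same_group && properly_contains(sj, ej, si, ei)) {
          drop[i] <- TRUE; changed <- TRUE
        } else if (si == sj && ei == ej && same_group) {
          drop[j] <- TRUE; changed <- TRUE
        } else if (sj > si && sj < ei && ej > ei) {
          # crossing: truncate the later-starting span to begin at ei
          new_start <- ei
          slice <- stringi::stri_sub(text, new_start + 1L, ej)
          lead_ws <- nchar(slice) - nchar(sub("^\\s+", "", slice))
          new_start <- new_start + lead_ws
          if (new_start >= ej) {
            drop[j] <- TRUE
          } else {
            ann$start[j] <- new_start
            ann$surface[j] <- stringi::stri_sub(text, new_start + 1L, ej)
          }
          changed <- TRUE
        }
      }
    }
    ann <- ann[!drop, , drop = FALSE]
    if (!changed) break
  }
  ann <- ann[order(ann$start, ann$end, method = "radix"), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("medlex_annotations", "data.frame")
  ann
}

#' Pre-annotate a document with the lexicon
#'
#' The composition build-index, match, prune: deterministic given
#' `(text, lexicon, groups)`.  Per-term match counts (by lemma) are attached
#' as the `term_frequencies` attribute; they support frequency-based term
#' prioritization over a corpus.
#'
#' @param text document string.
#' @param lx a `medlex_lexicon`.
#' @param groups optional semantic-group filter.
#' @param matcher optional pre-built `medlex_matcher` (saves rebuilding the
#'   index for every document of a corpus).
#' @return pruned `medlex_annotations` for the document.
#' @export
annotate_document <- function(text, lx = NULL, groups = NULL, matcher = NULL) {
  if (is.null(matcher)) matcher <- build_matcher_index(lx, groups)
  ann <- prune_annotations(match_all(text, matcher), text)
  tf <- table(ann$lemma)
  attr(ann, "term_frequencies") <-
    data.frame(lemma = names(tf), count = as.integer(tf),
               stringsAsFactors = FALSE)
  ann
}

#' Term frequencies over a corpus
#'
#' Counts pre-annotation matches per lemma across documents; used to rank
#' which thesaurus terms are worth manual revision first.
#'
#' @param texts character vector of documents.
#' @param lx a `medlex_lexicon`.
#' @param groups optional semantic-group filter.
#' @return data.frame `lemma`, `count`, sorted by decreasing count then
#'   lemma.
#' @export
term_frequencies <- function(texts, lx, groups = NULL) {
  matcher <- build_matcher_index(lx, groups)
  counts <- list()
  for (txt in texts) {
    ann <- annotate_document(txt, matcher = matcher)
    for (lm in ann$lemma) counts[[lm]] <- (counts[[lm]] %||% 0L) + 1L
  }
  out <- data.frame(lemma = names(counts),
                    count = as.integer(unlist(counts)),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$lemma, method = "radix"), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write annotations in BRAT standoff format
#'
#' Emits `T<n>\t<GROUP> <start> <end>\t<surface>` entity lines plus one
#' `N<n>` normalization line per entity carrying its candidate CUIs.
#'
#' @param annotations a `medlex_annotations` data.frame.
#' @param path output `.ann` path.
#' @return `path`, invisibly.
#' @export
write_brat <- function(annotations, path) {
  lines <- character(0)
  for (i in seq_len(nrow(annotations))) {
    lines <- c(lines, sprintf("T%d\t%s %d %d\t%s", i, annotations$group[i],
                              annotations$start[i], annotations$end[i],
                              annotations$surface[i]))
    if (nzchar(annotations$cuis[i]))
      lines <- c(lines, sprintf("N%d\tReference T%d UMLS:%s\t%s", i, i,
                                annotations$cuis[i], annotations$surface[i]))
  }
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read BRAT standoff entity annotations
#'
#' @param path `.ann` file path.
#' @return `medlex_annotations`-shaped data.frame (`cuis` from `N` lines when
#'   present).
#' @export
read_brat <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  t_lines <- grep("^T", lines, value = TRUE)
  rows <- lapply(t_lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    meta <- strsplit(f[2], " ", fixed = TRUE)[[1]]
    data.frame(id = f[1], group = meta[1],
               start = as.integer(meta[2]), end = as.integer(meta[3]),
               surface = f[3], cuis = "", stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), group = character(), start = integer(),
               end = integer(), surface = character(), cuis = character(),
               stringsAsFactors = FALSE)
  for (ln in grep("^N", lines, value = TRUE)) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    meta <- strsplit(f[2], " ", fixed = TRUE)[[1]]
    tid <- meta[2]
    out$cuis[out$id == tid] <- sub("^UMLS:", "", meta[3])
  }
  out$id <- NULL
  class(out) <- c("medlex_annotations", "data.frame")
  out
}
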