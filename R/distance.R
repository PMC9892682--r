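# Edit-distance variant discovery: unit-cost Levenshtein lookup of unattested
# strings against the lexicon's surface forms.

#' Unit-cost Levenshtein distance
#'
#' Insertions, deletions and substitutions all cost 1.  Strings are
#' NFC-normalized first, so precomposed and decomposed accents compare equal;
#' comparison is case-sensitive by default.  Spaces and hyphens count as
#' ordinary characters, which keeps tokenization variants of the same term
#' (hyphenated, spaced, fused) within small distances of each other.
#'
#' @param a,b character vectors: if either is a scalar it is compared against
#'   every element of the other; two vectors of equal length are compared
#'   elementwise.
#' @param fold_accents also strip accents and case before comparing?
#' @return integer vector of distances.
#' @export
#' @examples
#' edit_distance("viriasis", "viriosis")             # 1
#' edit_distance("betabloqueante", "beta-bloqueante") # 1
edit_distance <- function(a, b, fold_accents = FALSE) {
  norm <- if (isTRUE(fold_accents)) fold_accent_key else nfc
  a <- norm(a); b <- norm(b)
  costs <- list(ins = 1, del = 1, sub = 1)
  if (length(a) == 1L || length(b) == 1L)
    return(as.integer(utils::adist(a, b, costs = costs)))
  if (length(a) != length(b))
    stop("a and b must have equal lengths (or one must be a scalar)")
  vapply(seq_along(a), function(i)
    as.integer(utils::adist(a[i], b[i], costs = costs)), integer(1))
}

#' Find spelling-variant candidates for unattested strings
#'
#' For each unattested string, every lexicon surface form within `max_dist`
#' edits is returned as a proposed candidate pair carrying the known form's
#' CUIs.  Distance-0 pairs are exact matches (the base-list concept
#' assignment); pairs at distance 1-2 are the character-level, hyphenation
#' and tokenization variants.  No pair is auto-accepted: `status` is always
#' `"proposed"` and acceptance happens through an explicit review step.
#'
#' @param lx a non-empty `medlex_lexicon`.
#' @param unattested character vector of strings absent from thesauri.
#' @param max_dist maximum edit distance (default 2).
#' @return data.frame of class `medlex_candidates` with columns `candidate`,
#'   `known_term`, `distance`, `cuis` (`;`-joined), `status`; sorted by
#'   (candidate, distance, known_term).
#' @export
find_variant_candidates <- function(lx, unattested, max_dist = 2L) {
  stopifnot(max_dist >= 0)
  if (!lexicon_size(lx)) stop("empty lexicon")
  surfaces <- sort(ls(lx$form_index_exact), method = "radix")
  rows <- list()
  for (cand in nfc(unattested)) {
    d <- edit_distance(cand, surfaces)
    keep <- which(d <= max_dist)
    for (i in keep) {
      entries <- lexicon_lookup(lx, surfaces[i], by = "form_exact")
      cuis <- sort(unique(unlist(lapply(entries, `[[`, "cuis"))))
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = cand, known_term = surfaces[i], distance = d[i],
        cuis = paste(cuis, collapse = ";"), status = "proposed",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(candidate = character(), known_term = character(),
               distance = integer(), cuis = character(),
               status = character(), stringsAsFactors = FALSE)
  out <- out[order(out$candidate, out$distance, out$known_term,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("medlex_candidates", "data.frame")
  out
}

#' Apply a manual review file to candidate pairs
#'
#' Candidate pairs are never auto-accepted; decisions come from a delimited
#' review file (`known_term|candidate|distance|status`) whose `status` column
#' is `accepted` or `rejected`.
#'
#' @param candidates a `medlex_candidates` data.frame.
#' @param review_path path to the review file.
#' @param delim field delimiter.
#' @return the candidates with `status` updated from the review file.
#' @export
apply_review <- function(candidates, review_path, delim = "|") {
  lines <- readLines(review_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  for (ln in lines) {
    f <- trimws(strsplit(nfc(ln), delim, fixed = TRUE)[[1]])
    if (length(f) != 4L) stop("malformed review line: ", ln)
    if (!f[4] %in% c("proposed", "accepted", "rejected"))
      stop("unknown review status: ", f[4])
    hit <- candidates$known_term == f[1] & candidates$candidate == f[2]
    candidates$status[hit] <- f[4]
  }
  candidates
}
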