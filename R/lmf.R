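# LMF (Lexical Markup Framework) XML serialization.
#
# Layout: LexicalResource > Lexicon > LexicalEntry, each entry holding
# feat[partOfSpeech], Lemma > feat[writtenForm], one WordForm per inflected
# form with its morphological feats, and one Sense per CUI carrying the
# semantic type(s) and group.  Affix entries additionally carry an
# `attachment` feat (prefix/suffix) derived from the hyphen side.

lmf_feat <- function(parent, att, val) {
  xml2::xml_add_child(parent, "feat", att = att, val = val)
}

write_lexicon_lmf <- function(entries, path) {
  doc <- xml2::xml_new_root("LexicalResource", dtdVersion = "16")
  lex <- xml2::xml_add_child(doc, "Lexicon")
  lmf_feat(lex, "language", "es")
  for (e in entries) {
    node <- xml2::xml_add_child(lex, "LexicalEntry")
    lmf_feat(node, "partOfSpeech", e$pos)
    if (e$pos == "AFF") {
      side <- if (startsWith(e$lemma, "-")) "suffix" else "prefix"
      lmf_feat(node, "attachment", side)
    }
    lemma_node <- xml2::xml_add_child(node, "Lemma")
    lmf_feat(lemma_node, "writtenForm", e$lemma)
    f <- e$forms
    ord <- do.call(order, c(unname(as.list(f)), list(method = "radix")))
    for (i in ord) {
      wf <- xml2::xml_add_child(node, "WordForm")
      lmf_feat(wf, "writtenForm", f$surface[i])
      if (f$gender[i] != "unspecified")
        lmf_feat(wf, "grammaticalGender", f$gender[i])
      if (f$number[i] != "unspecified")
        lmf_feat(wf, "grammaticalNumber", f$number[i])
      if (f$person[i] != "none") lmf_feat(wf, "person", f$person[i])
      if (f$tense[i] != "none") lmf_feat(wf, "grammaticalTense", f$tense[i])
      if (f$mood[i] != "none") lmf_feat(wf, "verbFormMood", f$mood[i])
      if (f$variant_type[i] != "none")
        lmf_feat(wf, "variantType", f$variant_type[i])
    }
    for (cui in e$cuis) {
      sense <- xml2::xml_add_child(node, "Sense")
      lmf_feat(sense, "CUI", cui)
      for (st in e$semantic_types) lmf_feat(sense, "semanticType", st)
      if (nzchar(e$semantic_group))
        lmf_feat(sense, "semanticGroup", e$semantic_group)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

feat_val <- function(node, att) {
  hits <- xml2::xml_find_all(node, sprintf("./feat[@att='%s']", att))
  xml2::xml_attr(hits, "val")
}

read_lexicon_lmf <- function(path, allow_no_cui = FALSE) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed LMF XML in '", path,
                                           "': ", conditionMessage(e)))
  entry_nodes <- xml2::xml_find_all(doc, "//LexicalEntry")
  if (!length(entry_nodes)) {
    warning("empty LMF lexicon: ", path)
    return(lexicon())
  }
  entries <- lapply(entry_nodes, function(node) {
    pos <- feat_val(node, "partOfSpeech")[1]
    lemma <- feat_val(xml2::xml_find_first(node, "./Lemma"), "writtenForm")[1]
    wf_nodes <- xml2::xml_find_all(node, "./WordForm")
    forms <- if (length(wf_nodes)) do.call(rbind, lapply(wf_nodes, function(wf) {
      one <- function(att, default) {
        v <- feat_val(wf, att)
        if (length(v)) v[1] else default
      }
      word_form(one("writtenForm", ""),
                morph_features(gender = one("grammaticalGender", "unspecified"),
                               number = one("grammaticalNumber", "unspecified"),
                               person = one("person", "none"),
                               tense = one("grammaticalTense", "none"),
                               mood = one("verbFormMood", "none"),
                               variant_type = one("variantType", "none")))
    })) else NULL
    sense_nodes <- xml2::xml_find_all(node, "./Sense")
    cuis <- unlist(lapply(sense_nodes, feat_val, "CUI"))
    types <- unique(unlist(lapply(sense_nodes, feat_val, "semanticType")))
    group <- unlist(lapply(sense_nodes, feat_val, "semanticGroup"))
    lexical_entry(lemma, pos, cuis = cuis, semantic_types = types,
                  semantic_group = if (length(group)) group[1] else "",
                  forms = forms)
  })
  lexicon(entries, allow_no_cui = allow_no_cui)
}
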