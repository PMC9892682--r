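test_that("DSV records parse into entries with CUIs, forms and categories", {
  e <- parse_dsv_record(
    "C0019080|sangrar|sangrar;sangra;sangrando;sangrado|V|Pathologic Function|DISO")
  expect_equal(e$lemma, "sangrar")
  expect_equal(e$pos, "V")
  expect_equal(e$cuis, "C0019080")
  expect_equal(nrow(e$forms), 4L)
  expect_equal(e$semantic_group, "DISO")

  e2 <- parse_dsv_record(
    "C0023884|hígado|hígado;hígados|N|Body Part, Organ, or Organ Component|ANAT")
  expect_equal(e2$lemma, "hígado")
  expect_equal(nrow(e2$forms), 2L)
  expect_equal(e2$semantic_types, "Body Part, Organ, or Organ Component")

  # duplicated forms are deduplicated, whitespace trimmed
  e3 <- parse_dsv_record("C0000001| tos | tos; tos ;toses |N|Finding|DISO")
  expect_equal(e3$forms$surface, c("tos", "toses"))
})

test_that("malformed records and unknown tags are rejected with position info", {
  expect_error(parse_dsv_record("C0000001|only|five|fields|here", line_number = 7),
               "malformed record at line 7")
  expect_error(parse_dsv_record("C0000001|x|x|XYZ|t|G"),
               "unknown part-of-speech tag 'XYZ'")
  expect_error(parse_dsv_record("notacui|x|x|N|t|G"), "malformed CUI")
})

test_that("reading a DSV lexicon merges duplicate records and warns on empty files", {
  lines <- c(
    "C0000001|alfa|alfa;alfas|N|Finding|DISO",
    "C0000002|beta|beta|N|Finding|DISO",
    "C0000003|gama|gama|ADJ|Finding|DISO",
    "C0000004|delta|delta|N|Finding|ANAT",
    "C0000005|epsilon|epsilon|N|Finding|CHEM",
    "C0000001|alfa|alfa;alfeta|N|Finding|DISO",   # duplicate of line 1
    "C0000006|zeta|zeta|V|Finding|PROC",
    "C0000007|eta|eta|N|Finding|DISO",
    "C0000002|beta|betas|N|Finding|DISO",         # duplicate of line 2
    "C0000008|teta|teta|N|Finding|ANAT")
  path <- withr::local_tempfile(fileext = ".dsv")
  writeLines(lines, path)
  expect_message(lx <- read_lexicon(path, "dsv"), "2 duplicate")
  expect_equal(lexicon_size(lx), 8L)
  # merged entry holds the union of forms
  e <- lexicon_lookup(lx, "alfa", by = "lemma")[[1]]
  expect_setequal(e$forms$surface, c("alfa", "alfas", "alfeta"))

  empty <- withr::local_tempfile(fileext = ".dsv")
  writeLines(character(0), empty)
  expect_warning(lx0 <- read_lexicon(empty, "dsv"), "empty")
  expect_equal(lexicon_size(lx0), 0L)
})

test_that("CUI-less entries are rejected unless explicitly allowed", {
  expect_error(lexicon(lexical_entry("x", "N")), "no CUI")
  lx <- lexicon(lexical_entry("x", "N"), allow_no_cui = TRUE)
  expect_equal(lexicon_size(lx), 1L)
})

test_that("DSV and LMF round trips preserve the lexicon", {
  spec <- fixture_spec(n_concepts = 25, seed = 11)
  lx <- make_toy_lexicon(spec)
  dsv <- withr::local_tempfile(fileext = ".dsv")
  lmf <- withr::local_tempfile(fileext = ".xml")
  write_lexicon(lx, dsv, "dsv")
  write_lexicon(lx, lmf, "lmf")
  expect_true(lexicon_equal(lx, read_lexicon(dsv, "dsv"), morphology = FALSE))
  expect_true(lexicon_equal(lx, read_lexicon(lmf, "lmf"), morphology = TRUE))
})

test_that("LMF serialization carries category, variant-type and attachment features", {
  # one concept realized as adjective, noun and acronym short form
  dm <- lexicon(list(
    lexical_entry("diabético", "ADJ", "C0011849", semantic_group = "DISO",
                  forms = inflect_nominal("diabético", "ADJ")),
    lexical_entry("diabetes mellitus", "N", "C0011849",
                  semantic_group = "DISO"),
    lexical_entry("dm", "N", "C0011849", semantic_group = "DISO",
                  lemma_morph = morph_features(variant_type = "acronym")),
    lexical_entry("-cilina", "AFF", "C0030842", semantic_group = "CHEM",
                  forms = inflect_nominal("-cilina", "AFF"))
  ))
  path <- withr::local_tempfile(fileext = ".xml")
  write_lexicon(dm, path, "lmf")
  doc <- xml2::read_xml(path)
  entries <- xml2::xml_find_all(doc, "//LexicalEntry")
  expect_length(entries, 4L)
  expect_setequal(
    xml2::xml_attr(xml2::xml_find_all(doc, "//LexicalEntry/feat[@att='partOfSpeech']"), "val"),
    c("ADJ", "N", "AFF"))
  expect_equal(
    xml2::xml_attr(xml2::xml_find_first(doc, "//feat[@att='variantType']"), "val"),
    "acronym")
  expect_equal(
    xml2::xml_attr(xml2::xml_find_first(doc, "//feat[@att='attachment']"), "val"),
    "suffix")
  expect_true(lexicon_equal(dm, read_lexicon(path, "lmf")))
})

test_that("lexical record tables load with counts and reject malformed rows", {
  abr <- withr::local_tempfile(); writeLines(c("Dr.|doctor", "EV|enterovirus"), abr)
  aff <- withr::local_tempfile(); writeLines(character(0), aff)
  rec <- read_lexical_records(list(abbreviations = abr, affixes = aff))
  expect_equal(attr(rec, "counts")[["abbreviations"]], 2L)
  expect_equal(attr(rec, "counts")[["affixes"]], 0L)
  expect_equal(rec$abbreviations$full[rec$abbreviations$short == "Dr."],
               "doctor")

  bad <- withr::local_tempfile(); writeLines("toomany|fields|in|row", bad)
  expect_error(read_lexical_records(list(abbreviations = bad)), "row 1")
  expect_error(read_lexical_records(list(unknown_kind = abr)), "unknown record kind")

  nohyphen <- withr::local_tempfile(); writeLines("cilina|penicillins", nohyphen)
  expect_error(read_lexical_records(list(affixes = nohyphen)), "hyphen")
})

test_that("lexicon statistics count lemmas, forms and concepts correctly", {
  # 4 lemmas, 10 distinct (lemma, surface) forms, 2 CUIs
  lx <- lexicon(list(
    lexical_entry("ala", "N", "C0000001", semantic_group = "ANAT",
                  forms = forms_rows(c("ala", "alas", "alita"))),
    lexical_entry("ola", "N", "C0000001", semantic_group = "ANAT",
                  forms = forms_rows(c("ola", "olas"))),
    lexical_entry("ila", "N", "C0000002", semantic_group = "DISO",
                  forms = forms_rows(c("ila", "ilas", "ilita"))),
    lexical_entry("ula", "N", "C0000002", semantic_group = "DISO",
                  forms = forms_rows(c("ula", "ulas")))
  ))
  st <- lexicon_stats(lx)
  expect_equal(st$n_lemmas, 4L)
  expect_equal(st$n_forms, 10L)
  expect_equal(st$n_cuis, 2L)
  expect_equal(st$mean_lemmas_per_cui, 2.00)
  expect_equal(st$mean_forms_per_cui, 5.00)
  expect_equal(sum(st$pos_distribution$count), st$n_lemmas)
  expect_lt(abs(sum(st$pos_distribution$percent) - 100), 0.1)
  expect_lt(abs(sum(st$group_distribution$percent) - 100), 0.1)

  one <- lexicon(lexical_entry("uno", "N", "C0000009"))
  st1 <- lexicon_stats(one)
  expect_equal(st1$mean_lemmas_per_cui, 1.00)
  expect_equal(st1$mean_forms_per_cui, 1.00)

  expect_error(lexicon_stats(lexicon()), "empty lexicon")
})

test_that("published-scale totals yield the expected per-concept means", {
  m <- stats_from_counts(100887, 302543, 42958)
  expect_equal(m$mean_lemmas_per_cui, 2.35)
  expect_equal(m$mean_forms_per_cui, 7.04)
})

test_that("every form of every entry is reachable through the form index", {
  for (s in c(3, 17)) {
    lx <- make_toy_lexicon(fixture_spec(n_concepts = 20, seed = s))
    for (e in lx$entries) for (surf in e$forms$surface) {
      hits <- lexicon_lookup(lx, surf, by = "form")
      expect_true(any(vapply(hits, function(h)
        surf %in% h$forms$surface, logical(1))),
        label = paste("form reachable:", surf))
    }
    expect_silent(validate_lexicon(lx))
  }
})

test_that("merging equal-key entries is idempotent and commutative", {
  a <- lexical_entry("tos", "N", "C0010200", semantic_group = "DISO",
                     forms = forms_rows(c("tos", "toses")))
  b <- lexical_entry("tos", "N", "C0010200", semantic_group = "DISO",
                     forms = forms_rows(c("tos", "tosecilla")))
  ab <- lexicon(list(a, b))
  ba <- lexicon(list(b, a))
  aa <- lexicon(list(a, b, b))
  expect_equal(lexicon_size(ab), 1L)
  expect_setequal(ab$entries[[1]]$forms$surface,
                  c("tos", "toses", "tosecilla"))
  expect_setequal(ab$entries[[1]]$forms$surface, ba$entries[[1]]$forms$surface)
  expect_true(lexicon_equal(ab, aa))
})
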