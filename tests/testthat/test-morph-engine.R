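test_that("nominal inflection produces gender/number variants by rule", {
  pulm <- inflect_nominal("pulmón", "N",
                          morph_features(gender = "masculine",
                                         number = "singular"))
  expect_setequal(pulm$surface, c("pulmón", "pulmones"))
  expect_equal(pulm$number[pulm$surface == "pulmones"], "plural")
  # the written accent drops when -es attaches

  diab <- inflect_nominal("diabetes", "N",
                          morph_features(gender = "feminine",
                                         number = "singular_and_plural"))
  expect_equal(diab$surface, "diabetes")
  expect_equal(diab$number, "singular_and_plural")

  aff <- inflect_nominal("-scópico", "AFF")
  expect_setequal(aff$surface,
                  c("-scópico", "-scópica", "-scópicos", "-scópicas"))

  expect_error(inflect_nominal("sangrar", "V"), "wrong category")
})

test_that("plural orthography handles accent, -z and invariant -s endings", {
  expect_equal(pluralize("vacuna"), "vacunas")
  expect_equal(pluralize("pulmón"), "pulmones")
  expect_equal(pluralize("vez"), "veces")
  expect_equal(pluralize("análisis"), "análisis")   # unstressed -s: invariant
  expect_equal(pluralize("inglés"), "ingleses")
})

test_that("regular conjugation fills the published paradigm cells", {
  sang <- conjugate_verb("sangrar")
  cell <- function(ct, p, n, t, m)
    ct$cells$surface[ct$cells$person == p & ct$cells$number == n &
                     ct$cells$tense == t & ct$cells$mood == m]
  expect_equal(cell(sang, "third", "singular", "present", "indicative"),
               "sangra")
  expect_equal(sang$nonfinite$gerund, "sangrando")
  expect_equal(sang$nonfinite$participle[1], "sangrado")

  tos <- conjugate_verb("toser")
  expect_equal(cell(tos, "third", "singular", "present", "indicative"), "tose")
  expect_equal(cell(tos, "third", "singular", "present", "subjunctive"), "tosa")
  expect_equal(cell(tos, "third", "singular", "past", "indicative"), "tosió")
  expect_equal(cell(tos, "third", "singular", "future", "indicative"), "toserá")
  expect_equal(cell(tos, "third", "singular", "conditional", "indicative"),
               "tosería")
  expect_equal(cell(tos, "third", "plural", "imperfect", "indicative"),
               "tosían")
  expect_equal(tos$nonfinite$gerund, "tosiendo")
  expect_equal(tos$nonfinite$participle[1], "tosido")

  sud <- conjugate_verb("sudar")
  expect_equal(cell(sud, "first", "singular", "present", "indicative"), "sudo")
  expect_equal(cell(sud, "second", "singular", "present", "indicative"),
               "sudas")
  expect_equal(cell(sud, "third", "singular", "present", "indicative"), "suda")
  # compound present perfect: auxiliary + participle
  expect_equal(cell(sud, "second", "singular", "presentPerfect", "indicative"),
               "has sudado")

  expect_error(conjugate_verb("pulmón"), "cannot conjugate")
})

test_that("the exception table overrides individual irregular cells", {
  mor <- conjugate_verb("morir")
  cell <- function(p, n, t, m)
    mor$cells$surface[mor$cells$person == p & mor$cells$number == n &
                      mor$cells$tense == t & mor$cells$mood == m]
  expect_equal(cell("third", "singular", "past", "indicative"), "murió")
  expect_equal(cell("third", "singular", "present", "indicative"), "muere")
  expect_equal(mor$nonfinite$gerund, "muriendo")
  expect_equal(mor$nonfinite$participle,
               c("muerto", "muertos", "muerta", "muertas"))
  # regular cells are untouched by the exception table
  expect_equal(cell("third", "singular", "future", "indicative"), "morirá")
})

test_that("concept identifiers propagate across derivational variants", {
  higado <- lexical_entry("hígado", "N", "C0023884",
                          semantic_types = "Body Part, Organ, or Organ Component",
                          semantic_group = "ANAT")
  hepatico <- lexical_entry("hepático", "ADJ")
  out <- propagate_concept(higado, hepatico)
  expect_equal(out$entry_a$cuis, "C0023884")
  expect_equal(out$entry_b$cuis, "C0023884")
  expect_equal(out$entry_b$semantic_group, "ANAT")
  expect_equal(out$link$relation, "adj_noun")

  dialisis <- lexical_entry("diálisis", "N", "C4551529",
                            semantic_group = "PROC")
  dializar <- lexical_entry("dializar", "V")
  out2 <- propagate_concept(dialisis, dializar)
  expect_equal(out2$entry_a$cuis, "C4551529")
  expect_equal(out2$entry_b$cuis, "C4551529")
  expect_equal(out2$link$relation, "noun_verb")

  # idempotent: propagating again changes nothing
  out3 <- propagate_concept(out2$entry_a, out2$entry_b)
  expect_equal(out3$entry_a, out2$entry_a)
  expect_equal(out3$entry_b, out2$entry_b)

  a <- lexical_entry("uno", "N"); b <- lexical_entry("otro", "ADJ")
  expect_warning(res <- propagate_concept(a, b), "nothing to propagate")
  expect_equal(res$entry_a, a)
  expect_null(res$link)
})

test_that("word-order variants swap post-head modifiers and keep the token multiset", {
  v <- generate_word_order_variants("virus respiratorio sincitial")
  expect_true("virus sincitial respiratorio" %in% v)
  expect_false("virus respiratorio sincitial" %in% v)

  expect_equal(generate_word_order_variants("dolor"), character(0))

  terms <- c("virus respiratorio sincitial", "insuficiencia renal aguda grave",
             "cáncer de pulmón microcítico", "enfermedad pulmonar obstructiva")
  for (term in terms) {
    for (variant in generate_word_order_variants(term)) {
      expect_false(identical(variant, term))
      expect_equal(sort(strsplit(variant, " ")[[1]]),
                   sort(strsplit(term, " ")[[1]]))
    }
  }
  # function words are never displaced
  expect_equal(generate_word_order_variants("administración de vacunas"),
               character(0))
})

test_that("multiword terms inherit category and gender/number from the head", {
  lx <- spanish_demo_lexicon()
  asp <- assign_multiword_morphology("síndrome de Asperger", lx)
  expect_equal(asp$pos, "N")
  expect_equal(asp$head, "síndrome")
  expect_equal(asp$morph$gender, "masculine")
  expect_equal(asp$morph$number, "singular")

  lyme <- assign_multiword_morphology("enfermedad de Lyme", lx)
  expect_equal(lyme$pos, "N")
  expect_equal(lyme$morph$gender, "feminine")

  expect_error(assign_multiword_morphology("de la", lx), "unresolved head")
})

test_that("generated inflections and conjugations lemmatize back to their lemma", {
  spec <- fixture_spec(n_concepts = 35, seed = 23)
  lx <- make_toy_lexicon(spec)
  checked <- 0L
  for (e in lx$entries) {
    if (e$pos %in% c("AFF")) next
    for (surf in e$forms$surface) {
      if (grepl("\\s", surf)) next
      hint <- switch(e$pos, V = "VERB", N = "NOUN", NPR = "PROPN",
                     ADJ = "ADJ", ADV = "ADV", NULL)
      got <- lemmatize_token(surf, pos_hint = hint, lx = lx)
      expect_equal(got$source, "lexicon", label = paste("in lexicon:", surf))
      expect_equal(got$lemma, e$lemma, label = paste("lemma of", surf))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 100L)
})
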