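test_that("lexicon lemmatization maps inflected clinical forms to their lemmas", {
  lx <- spanish_demo_lexicon()
  expect_equal(lemmatize_token("hematíes", lx = lx),
               list(lemma = "hematíe", source = "lexicon"))
  expect_equal(lemmatize_token("páncreas", lx = lx)$lemma, "páncreas")
  expect_equal(lemmatize_token("corticoides", lx = lx)$lemma, "corticoide")
  # out-of-vocabulary: identity fallback, never an invented lemma
  expect_equal(lemmatize_token("uretra-neovejiga", lx = lx),
               list(lemma = "uretra-neovejiga", source = "fallback"))
  expect_error(lemmatize_token("  ", lx = lx), "empty surface")
})

test_that("ambiguous surfaces defer to the part-of-speech hint then sort order", {
  lx <- lexicon(list(
    lexical_entry("evidencia", "N", "C3887511", semantic_group = "PROC"),
    lexical_entry("evidenciar", "V", "C3887511", semantic_group = "PROC",
                  forms = conjugation_forms(conjugate_verb("evidenciar")))))
  expect_equal(lemmatize_token("evidencia", pos_hint = "NOUN", lx = lx)$lemma,
               "evidencia")
  expect_equal(lemmatize_token("evidencia", pos_hint = "VERB", lx = lx)$lemma,
               "evidenciar")
  # no hint: deterministic lexicographic tie-break
  expect_equal(lemmatize_token("evidencia", lx = lx)$lemma, "evidencia")
})

test_that("the lexicon overrides base tags only where it is competent", {
  lx <- spanish_demo_lexicon()
  toks <- data.frame(
    surface = c("UCI", "úrico", "inventadísimo", "radio"),
    base_tag = c("PROPN", "NOUN", "VERB", "NOUN"))
  tagged <- tag_tokens(toks, lx)
  # acronym mis-tagged as proper noun by the base tagger: lexicon says noun
  expect_equal(tagged$pos[1], "NOUN")
  # adjective mis-tagged as noun: lexicon says adjective
  expect_equal(tagged$pos[2], "ADJ")
  # out-of-lexicon token keeps its base tag, identity lemma
  expect_equal(tagged$pos[3], "VERB")
  expect_equal(tagged$lemma[3], "inventadísimo")
  expect_equal(tagged$source[3], "fallback")
  # unambiguous N entries: NOUN
  expect_equal(tagged$pos[4], "NOUN")

  # ambiguous lexicon category defers to a compatible base tag
  amb <- lexicon(lexical_entry("neonato", "ADJ/N", "C0021289",
                               semantic_group = "DISO"))
  expect_equal(tag_tokens(data.frame(surface = "neonato",
                                     base_tag = "NOUN"), amb)$pos, "NOUN")
  expect_equal(tag_tokens(data.frame(surface = "neonato",
                                     base_tag = "ADJ"), amb)$pos, "ADJ")
  # incompatible base tag: first listed alternative
  expect_equal(tag_tokens(data.frame(surface = "neonato",
                                     base_tag = "VERB"), amb)$pos, "ADJ")

  expect_error(tag_tokens(data.frame(surface = "x", base_tag = NA), lx),
               "length mismatch")
})

test_that("evaluation scores per-category one-vs-rest on lexical tokens only", {
  # 10 gold NOUN: 8 predicted NOUN, 2 predicted ADJ; 1 gold ADJ -> NOUN;
  # plus gold OTHER tokens that must be excluded from scoring
  gold <- data.frame(
    surface = paste0("w", 1:13),
    tag = c(rep("NOUN", 10), "ADJ", "OTHER", "OTHER"),
    lemma = paste0("w", 1:13))
  pred <- data.frame(
    surface = paste0("w", 1:13),
    pos = c(rep("NOUN", 8), "ADJ", "ADJ", "NOUN", "VERB", "NOUN"),
    lemma = paste0("w", 1:13))
  ev <- evaluate(pred, gold, mode = "pos")
  noun <- ev$per_category[ev$per_category$category == "NOUN", ]
  expect_equal(noun$precision, 8 / 9)
  expect_equal(noun$recall, 8 / 10)
  expect_equal(noun$f1, 0.8421, tolerance = 1e-4)
  expect_equal(ev$n_tokens, 11L)

  # perfect prediction scores 1 everywhere
  perfect <- data.frame(surface = gold$surface, pos = gold$tag,
                        lemma = gold$lemma)
  evp <- evaluate(perfect, gold, mode = "pos")
  expect_true(all(evp$per_category$precision == 1))
  expect_true(all(evp$per_category$recall == 1))
  expect_equal(unname(evp$aggregate["f1"]), 1)

  # misalignment is caught with the first offending position
  bad <- pred; bad$surface[3] <- "intruso"
  expect_error(evaluate(bad, gold, mode = "pos"), "position 3")
  expect_error(evaluate(pred[1:5, ], gold, mode = "pos"), "misaligned")
})

test_that("lenient lemma comparison ignores accents and case", {
  gold <- data.frame(surface = c("cardiaco", "Alta"),
                     tag = c("ADJ", "NOUN"),
                     lemma = c("cardíaco", "alta"))
  pred <- data.frame(surface = c("cardiaco", "Alta"),
                     pos = c("ADJ", "NOUN"),
                     lemma = c("cardiaco", "Alta"))
  ev <- evaluate(pred, gold, mode = "lemma")
  expect_equal(unname(ev$aggregate["f1"]), 1)   # diacritic-only differences pass
  pred2 <- pred; pred2$lemma[1] <- "cardiología"
  ev2 <- evaluate(pred2, gold, mode = "lemma")
  expect_equal(unname(ev2$aggregate["precision"]), 0.5)
})

test_that("evaluation agrees with explicit confusion-matrix computation", {
  set.seed(11)
  cats <- c("ADJ", "ADV", "NOUN", "PROPN", "VERB", "OTHER")
  for (trial in 1:15) {
    n <- sample(5:20, 1)
    gold <- data.frame(surface = paste0("t", 1:n),
                       tag = sample(cats, n, replace = TRUE),
                       lemma = paste0("t", 1:n))
    pred <- data.frame(surface = gold$surface,
                       pos = sample(cats, n, replace = TRUE),
                       lemma = gold$lemma)
    if (!any(gold$tag %in% c("ADJ", "ADV", "NOUN", "PROPN", "VERB"))) next
    ev <- evaluate(pred, gold, mode = "pos")
    want <- eval_oracle(pred$pos, gold$tag,
                        c("ADJ", "ADV", "NOUN", "PROPN", "VERB"))
    for (cat in ev$per_category$category) {
      row <- ev$per_category[ev$per_category$category == cat, ]
      expect_equal(row$precision, unname(want[[cat]]["precision"]))
      expect_equal(row$recall, unname(want[[cat]]["recall"]))
      expect_equal(row$f1, unname(want[[cat]]["f1"]))
    }
  }
})

test_that("tagging and lemmatizing the fixture corpus against gold is perfect", {
  spec <- fixture_spec(n_concepts = 40, seed = 7)
  lx <- make_toy_lexicon(spec)
  corp <- make_toy_corpus(lx, spec)
  for (d in seq_along(corp$documents)) {
    g <- corp$gold_tokens[[d]]
    pred <- tag_tokens(data.frame(surface = g$surface, base_tag = "OTHER"), lx)
    if (!any(g$tag %in% c("ADJ", "ADV", "NOUN", "PROPN", "VERB"))) next
    expect_equal(unname(evaluate(pred, g, "pos")$aggregate[["f1"]]), 1,
                 label = paste("pos F1 in doc", d))
    expect_equal(unname(evaluate(pred, g, "lemma")$aggregate[["f1"]]), 1,
                 label = paste("lemma F1 in doc", d))
  }
})

test_that("CoNLL-U files round-trip surfaces, tags and lemmas", {
  toks <- data.frame(surface = c("dolor", "de", "cabeza"),
                     pos = c("NOUN", "OTHER", "NOUN"),
                     lemma = c("dolor", "de", "cabeza"))
  path <- withr::local_tempfile(fileext = ".conllu")
  write_conllu(toks, path)
  back <- read_conllu(path)
  expect_equal(back$surface, toks$surface)
  expect_equal(back$tag, toks$pos)
  expect_equal(back$lemma, toks$lemma)
})
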