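test_that("sentence splitting and tokenization produce ordered in-bounds spans", {
  s <- split_sentences("No pain. Asthma persists.")
  expect_identical(nrow(s), 2L)
  expect_identical(s$text, c("No pain.", "Asthma persists."))
  expect_identical(substring("No pain. Asthma persists.", s$start + 1, s$end),
                   s$text)

  toks <- tokenize("Asthma persists.")
  expect_identical(toks$text, c("Asthma", "persists", "."))
  expect_true(all(toks$start < toks$end))

  expect_identical(nrow(split_sentences("")), 0L)
  expect_identical(nrow(tokenize("")), 0L)
})

test_that("token texts reconstruct the sentence modulo whitespace", {
  txts <- c("Patient presents with Diabetes Mellitus, Type 1.",
            "No pain!  Follow-up (weekly); ok?")
  for (tx in txts) {
    for (k in seq_len(nrow(split_sentences(tx)))) {
      s <- split_sentences(tx)[k, ]
      toks <- tokenize(s$text)
      expect_identical(gsub("[[:space:]]", "", paste(toks$text, collapse = "")),
                       gsub("[[:space:]]", "", s$text))
    }
  }
})

test_that("greedy longest match wins over nested sub-terms and respects the branch filter", {
  th <- mesh_thesaurus(list(
    mesh_descriptor("D003920", "Diabetes Mellitus", character(),
                    "C18.452.394.750"),
    mesh_descriptor("D003922", "Diabetes Mellitus, Type 1", character(),
                    "C18.452.394.750.124"),
    mesh_descriptor("D010406", "Penicillins", "Penicillin",
                    "D02.065.589")))
  text <- "Patient has Diabetes Mellitus, Type 1 and Penicillin allergy."
  toks <- tokenize(text)
  allowed_all <- names(th$descriptors)
  m <- match_terms(toks, text, th, allowed_all)
  expect_true("D003922" %in% m$descriptor)
  expect_false("D003920" %in% m$descriptor)  # shadowed by the longer term
  expect_true("D010406" %in% m$descriptor)

  # Penicillin lives in branch D only: a C-restricted scan must not match it
  allowed_c <- descriptors_in_branches(th, "C")
  m_c <- match_terms(toks, text, th, allowed_c)
  expect_false("D010406" %in% m_c$descriptor)
  expect_true("D003922" %in% m_c$descriptor)
})

test_that("negation triggers within the window, same sentence, and not beyond it", {
  th <- toy_thesaurus()
  text <- "No Pain. Pain in chest. No family history of asthma."
  sents <- split_sentences(text)
  allowed <- names(th$descriptors)

  t1 <- tokenize(sents$text[1], sents$start[1])
  m1 <- match_terms(t1, text, th, allowed)
  expect_true(is_negated(t1, m1[m1$descriptor == "D010146", ]))

  t2 <- tokenize(sents$text[2], sents$start[2])
  m2 <- match_terms(t2, text, th, allowed)
  expect_false(is_negated(t2, m2[m2$descriptor == "D010146", ]))

  # "no" is four tokens before "asthma": outside the default window of 3
  t3 <- tokenize(sents$text[3], sents$start[3])
  m3 <- match_terms(t3, text, th, allowed)
  asthma <- m3[m3$descriptor == "D001249", ]
  expect_identical(nrow(asthma), 1L)
  expect_false(is_negated(t3, asthma, window = 3))
  expect_true(is_negated(t3, asthma, window = 4))
})

test_that("identify_keywords applies section relevance, branch restriction and negation flags", {
  th <- toy_thesaurus()
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".xml")
  toy_cda_xml(path, sections = list(
    list(title = "History of Present Illness", code = "10164-2",
         text = "Patient reports Asthma and Hypertension. No Pain."),
    list(title = "Allergies", code = "48765-2",
         text = "Penicillin allergy suspected."),
    list(title = "Appointment", code = NULL,
         text = "Asthma mentioned here should not count.")))
  doc <- parse_cda(path)
  kw <- identify_keywords(doc, th, cfg)

  expect_setequal(kw$descriptor[!kw$negated],
                  c("D001249", "D006973", "D010406"))
  pain <- kw[kw$descriptor == "D010146", ]
  expect_identical(nrow(pain), 1L)
  expect_true(pain$negated)
  # nothing came from the rule-less Appointment section
  expect_true(all(kw$section_index < 2))
  # spans index the section text
  for (r in seq_len(nrow(kw))) {
    sec <- doc$sections[[kw$section_index[r] + 1L]]
    expect_identical(substr(sec$text, kw$start[r] + 1L, kw$end[r]),
                     kw$surface[r])
  }
  # candidate qualifiers are a subset of the descriptor's allowable set
  for (r in seq_len(nrow(kw))) {
    expect_true(all(kw$candidate_qualifiers[[r]] %in%
                      allowable_qualifiers_for(th, kw$descriptor[r])$abbreviation))
  }
  # deterministic ordering
  expect_identical(order(kw$section_index, kw$start), seq_len(nrow(kw)))
})

test_that("the baseline scans every section and branch and keeps negated mentions", {
  th <- toy_thesaurus()
  path <- withr::local_tempfile(fileext = ".xml")
  toy_cda_xml(path, sections = list(
    list(title = "Appointment", code = NULL, text = "No Pain today.")))
  doc <- parse_cda(path)
  expect_identical(nrow(identify_keywords(doc, th, default_config())), 0L)
  base <- identify_baseline(doc, th)
  expect_identical(base$descriptor, "D010146")
  expect_true(base$negated)
})

test_that("baseline concepts are a superset of configured concepts on generated documents", {
  spec <- generator_spec(seed = 13, n_descriptors = 40, n_docs = 4)
  th <- make_mini_mesh(spec)
  cda <- make_cda_set(spec, th)
  for (doc in cda$docs) {
    conf_set <- unique(identify_keywords(doc, th, default_config())$descriptor)
    base_set <- unique(identify_baseline(doc, th)$descriptor)
    expect_true(all(conf_set %in% base_set))
  }
})

test_that("identification equals the brute-force n-gram oracle on generated fixtures", {
  for (seed in c(21, 22)) {
    spec <- generator_spec(seed = seed, n_descriptors = 40, n_docs = 3)
    th <- make_mini_mesh(spec)
    cda <- make_cda_set(spec, th)
    cfg <- default_config()
    for (doc in cda$docs) {
      got <- identify_keywords(doc, th, cfg)
      want <- oracle_identify(doc, th, cfg)
      expect_identical(got$descriptor, want$descriptor)
      expect_identical(got$start, want$start)
      expect_identical(got$end, want$end)
      expect_identical(got$negated, want$negated)
    }
  }
})

test_that("shrinking the branch set never adds keywords", {
  spec <- generator_spec(seed = 31, n_descriptors = 50, n_docs = 3)
  th <- make_mini_mesh(spec)
  cda <- make_cda_set(spec, th)
  cfg_wide <- default_config()
  cfg_narrow <- cfg_wide
  cfg_narrow$rules <- lapply(cfg_narrow$rules, function(r) {
    r$branches <- c("C", "D")
    r
  })
  for (doc in cda$docs) {
    wide <- unique(identify_keywords(doc, th, cfg_wide)$descriptor)
    narrow <- unique(identify_keywords(doc, th, cfg_narrow)$descriptor)
    expect_true(all(narrow %in% wide))
  }
})

test_that("standoff output round-trips the annotation columns", {
  th <- toy_thesaurus()
  path <- withr::local_tempfile(fileext = ".xml")
  toy_cda_xml(path, sections = list(
    list(title = "Allergies", code = "48765-2", text = "Asthma noted.")))
  kw <- identify_keywords(parse_cda(path), th, default_config())
  out <- withr::local_tempfile(fileext = ".tsv")
  write_standoff(kw, "toy", out)
  got <- utils::read.table(out, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expect_identical(got$descriptor, kw$descriptor)
  expect_identical(got$doc_id, rep("toy", nrow(kw)))
})
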