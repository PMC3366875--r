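test_that("queries build by iteration: start, AND-extension, deduplication", {
  th <- toy_thesaurus()
  q1 <- initial_query(th, "D003922", "D001249")
  expect_identical(q1$iteration, 1L)
  expect_length(q1$clauses, 1)

  q2 <- add_term(q1, th, "D006973")
  expect_identical(q2$iteration, 2L)
  expect_identical(q1$iteration, 1L)  # input value unchanged
  # three MeSH keywords in total, counting the disease
  expect_identical(length(q2$clauses) + 1L, 3L)

  expect_identical(add_term(q2, th, "D001249"), q2)   # duplicate: no-op
  expect_identical(add_term(q2, th, "D003922"), q2)   # disease: no-op
})

test_that("negated keywords and non-C diseases are rejected", {
  th <- toy_thesaurus()
  kw <- data.frame(descriptor = "D010146", negated = TRUE)
  expect_error(initial_query(th, "D003922", kw), "negated")
  q <- initial_query(th, "D003922")
  expect_error(add_term(q, th, kw), "negated")
  # D010406 Penicillins has no C tree number
  expect_error(initial_query(th, "D010406"), "branch C")
  expect_s3_class(initial_query(th, "D010406", strict = FALSE), "mesh_query")
})

test_that("rendering follows the [mh] conjunct grammar with the disease last", {
  th <- toy_thesaurus()
  q <- add_term(initial_query(th, "D003922", "D001249"), th, "D006973")
  expect_identical(
    render_query(q),
    "(Asthma[mh]) AND (Hypertension[mh]) AND (Diabetes Mellitus, Type 1[mh])")
  # the zero-clause "general query"
  expect_identical(render_query(initial_query(th, "D003922")),
                   "(Diabetes Mellitus, Type 1[mh])")
})

test_that("qualified clauses render one conjunct per qualifier with full subheading names", {
  th <- mesh_thesaurus(list(
    mesh_descriptor("D003920", "Diabetes Mellitus", character(),
                    "C18.452.394.750", c("EP", "DI")),
    mesh_descriptor("D003922", "Diabetes Mellitus, Type 1", character(),
                    "C18.452.394.750.124", "EP")))
  q <- initial_query(th, "D003922", "D003920")
  q <- attach_qualifier(q, th, "D003920", "EP")
  q <- attach_qualifier(q, th, "D003920", "DI")
  expect_identical(
    render_query(q),
    paste0("(Diabetes Mellitus/epidemiology[mh]) AND ",
           "(Diabetes Mellitus/diagnosis[mh]) AND ",
           "(Diabetes Mellitus, Type 1[mh])"))
})

test_that("qualifier admissibility is checked on both descriptor and section sides", {
  th <- toy_thesaurus()
  q <- initial_query(th, "D003922", "D001249")
  # TH is not allowable for Asthma in the toy thesaurus
  expect_error(attach_qualifier(q, th, "D001249", "TH"),
               "not allowable for descriptor")
  # EP allowable for the descriptor but excluded by the section rule
  rule <- section_rule(titles = "Allergies", qualifiers = "DI")
  expect_error(attach_qualifier(q, th, "D001249", "EP", rule = rule),
               "section rule")
  # allowable on both sides; attaching twice is idempotent
  rule2 <- section_rule(titles = "Allergies", qualifiers = c("EP", "DI"))
  q1 <- attach_qualifier(q, th, "D001249", "EP", rule = rule2)
  q2 <- attach_qualifier(q1, th, "D001249", "EP", rule = rule2)
  expect_identical(q1, q2)
  expect_error(attach_qualifier(q, th, "D006973", "EP"), "not in the query")
})

test_that("rendering is injective over distinct clause structures", {
  th <- toy_thesaurus()
  qs <- list(
    initial_query(th, "D003922"),
    initial_query(th, "D003922", "D001249"),
    add_term(initial_query(th, "D003922", "D001249"), th, "D006973"),
    add_term(initial_query(th, "D003922", "D006973"), th, "D001249"),
    attach_qualifier(initial_query(th, "D003922", "D001249"), th,
                     "D001249", "EP"))
  rendered <- vapply(qs, render_query, "")
  expect_identical(anyDuplicated(rendered), 0L)
})

test_that("relatedness is the size of the index/EHR-term intersection", {
  cit <- list(index = data.frame(
    descriptor = c("D001249", "D006973", "D003922"),
    qualifier = NA_character_))
  expect_identical(relevance(cit, c("D001249", "D006973"), "D003922"), 3L)
  expect_identical(relevance(cit, character(), "D999"), 0L)
  expect_identical(
    relevance(list(index = data.frame(descriptor = "D1",
                                      qualifier = NA_character_)),
              c("D2", "D3"), "D4"), 0L)
})

test_that("every citation retrieved by the n-th query is related by at least n + 1 keywords", {
  for (seed in c(41, 42, 43)) {
    spec <- generator_spec(seed = seed, n_descriptors = 30, n_docs = 2,
                           n_citations = 80)
    th <- make_mini_mesh(spec)
    corpus <- make_corpus(spec, th)
    be <- local_backend(corpus)
    ids <- names(th$descriptors)
    dzs <- descriptors_in_branches(th, "C")
    if (!length(dzs)) next
    withr::with_seed(seed, {
      dz <- sample(dzs, 1)
      terms <- sample(setdiff(ids, dz), 4)
    })
    q <- initial_query(th, dz)
    for (n in seq_along(terms)) {
      q <- add_term(q, th, terms[n])
      for (cit in backend_search(be, q)) {
        expect_gte(relevance(cit, terms[seq_len(n)], dz), n + 1)
      }
    }
  }
})

test_that("annotate_counts fills candidate counts that honor AND monotonicity", {
  spec <- generator_spec(seed = 51, n_descriptors = 30, n_docs = 2,
                         n_citations = 60)
  th <- make_mini_mesh(spec)
  cda <- make_cda_set(spec, th)
  corpus <- make_corpus(spec, th,
                        favored = unique(cda$gold$descriptor))
  be <- local_backend(corpus)
  doc <- cda$docs[[1]]
  kw <- identify_keywords(doc, th)
  dz <- descriptors_in_branches(th, "C")[1]
  q <- initial_query(th, dz, strict = FALSE)
  base_count <- backend_count(be, q)
  kw <- annotate_counts(kw, q, be, th)
  for (r in seq_len(nrow(kw))) {
    if (kw$negated[r] || kw$descriptor[r] == dz) {
      expect_true(is.na(kw$candidate_count[r]))
    } else {
      expect_false(is.na(kw$candidate_count[r]))
      expect_lte(kw$candidate_count[r], base_count)
      # oracle: brute-force predicate count for the extended query
      expect_identical(kw$candidate_count[r],
                       oracle_count(corpus,
                                    add_term(q, th, kw$descriptor[r])))
    }
  }
  # keyword already in the query gets no count
  q2 <- add_term(q, th, kw$descriptor[!kw$negated][1])
  kw2 <- annotate_counts(kw, q2, be, th)
  expect_true(all(is.na(
    kw2$candidate_count[kw2$descriptor %in% kw$descriptor[!kw$negated][1]])))
})
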