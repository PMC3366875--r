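mini_corpus <- function() {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(
    "PM1\tToy one\t2010-01-01\tD001249/EP|D006973",
    "PM2\tToy two\t2011-05-01\tD001249|D006973|D003922",
    "PM3\tToy three\t2009-03-01\tD003922"), path)
  load_corpus(path, "fixture-tsv")
}

test_that("the fixture TSV corpus dialect parses descriptor/qualifier pairs", {
  corpus <- mini_corpus()
  expect_length(corpus$citations, 3)
  idx <- corpus$citations[["PM1"]]$index
  expect_identical(idx$descriptor, c("D001249", "D006973"))
  expect_identical(idx$qualifier, c("EP", NA))
})

test_that("conjunctive counting: every clause must be satisfied", {
  th <- toy_thesaurus()
  be <- local_backend(mini_corpus())
  q <- add_term(initial_query(th, "D003922", "D001249"), th, "D006973")
  expect_identical(backend_count(be, q), 1L)
  m <- backend_search(be, q)
  expect_identical(unname(vapply(m, `[[`, "", "citation_id")), "PM2")
})

test_that("qualified clauses require the explicit descriptor/qualifier pair", {
  th <- toy_thesaurus()
  be <- local_backend(mini_corpus())
  q <- attach_qualifier(initial_query(th, "D003922", "D001249"),
                        th, "D001249", "EP")
  # PM2 has unqualified D001249: does not satisfy Asthma/EP; PM1 lacks D003922
  expect_identical(backend_count(be, q), 0L)
  q2 <- attach_qualifier(initial_query(th, "D006973", strict = FALSE,
                                       term = "D001249"),
                         th, "D001249", "EP")
  expect_identical(backend_count(be, q2), 1L)  # only PM1
})

test_that("search orders citations by date descending with id tie-break", {
  th <- toy_thesaurus()
  be <- local_backend(mini_corpus())
  q <- initial_query(th, "D003922")
  got <- unname(vapply(backend_search(be, q), `[[`, "", "citation_id"))
  expect_identical(got, c("PM2", "PM3"))
})

test_that("counts equal brute-force predicate evaluation on random corpora", {
  for (seed in c(61, 62)) {
    spec <- generator_spec(seed = seed, n_descriptors = 25, n_citations = 70)
    th <- make_mini_mesh(spec)
    corpus <- make_corpus(spec, th)
    be <- local_backend(corpus)
    ids <- names(th$descriptors)
    withr::with_seed(seed, {
      for (r in 1:15) {
        dz <- sample(ids, 1)
        q <- initial_query(th, dz, strict = FALSE)
        for (t in sample(setdiff(ids, dz), sample(0:3, 1))) {
          q <- add_term(q, th, t)
        }
        expect_identical(backend_count(be, q), oracle_count(corpus, q))
      }
    })
  }
})

test_that("the backend is deterministic and the cache is transparent", {
  spec <- generator_spec(seed = 71, n_descriptors = 20, n_citations = 50)
  th <- make_mini_mesh(spec)
  corpus <- make_corpus(spec, th)
  cached <- local_backend(corpus, cache = TRUE)
  uncached <- local_backend(corpus, cache = FALSE)
  ids <- names(th$descriptors)
  withr::with_seed(71, picks <- replicate(10, sample(ids, 2), simplify = FALSE))
  for (p in picks) {
    q <- add_term(initial_query(th, p[1], strict = FALSE), th, p[2])
    c1 <- backend_count(cached, q)
    expect_identical(c1, backend_count(cached, q))  # repeated call identical
    expect_identical(c1, backend_count(uncached, q))
  }
})

test_that("corpus fixtures round-trip through the TSV writer", {
  spec <- generator_spec(seed = 81, n_descriptors = 20, n_citations = 40)
  th <- make_mini_mesh(spec)
  corpus <- make_corpus(spec, th)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus_tsv(corpus, path)
  expect_equal(load_corpus(path, "fixture-tsv"), corpus)
})

test_that("empty corpora count zero; duplicate ids are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), path)
  be <- local_backend(load_corpus(path, "fixture-tsv"))
  th <- toy_thesaurus()
  expect_identical(backend_count(be, initial_query(th, "D003922")), 0L)

  writeLines(c("PM1\tA\t2010-01-01\tD1", "PM1\tB\t2010-01-01\tD2"), path)
  expect_error(load_corpus(path, "fixture-tsv"), "duplicate")
})

test_that("the MEDLINE XML subset reader extracts PMID, title and headings", {
  xml <- '<PubmedArticleSet><PubmedArticle>
    <MedlineCitation><PMID>123</PMID>
      <Article><ArticleTitle>A title</ArticleTitle>
        <Journal><JournalIssue><PubDate><Year>2010</Year></PubDate>
        </JournalIssue></Journal></Article>
      <MeshHeadingList>
        <MeshHeading><DescriptorName UI="D001249">Asthma</DescriptorName>
          <QualifierName UI="EP">epidemiology</QualifierName></MeshHeading>
        <MeshHeading><DescriptorName UI="D003922">Diabetes Mellitus, Type 1</DescriptorName></MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle></PubmedArticleSet>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  corpus <- load_corpus(path, "medline-xml")
  cit <- corpus$citations[["123"]]
  expect_identical(cit$title, "A title")
  expect_identical(cit$date, "2010-01-01")
  expect_identical(cit$index$descriptor, c("D001249", "D003922"))
  expect_identical(cit$index$qualifier, c("EP", NA))
})

test_that("the live-client configuration defaults to 1,000 queries per minute", {
  be <- entrez_backend()
  expect_identical(be$rate_limit_per_min, 1000L)
})

test_that("cached live queries are served without touching the network", {
  th <- toy_thesaurus()
  be <- entrez_backend(base_url = "http://127.0.0.1:1/unreachable")
  q <- initial_query(th, "D003922", "D001249")
  ehrlit:::seed_entrez_cache(be, q, 6L)
  expect_identical(backend_count(be, q), 6L)
  # an uncached query against the unreachable endpoint fails as retryable
  be$wait <- FALSE
  q2 <- initial_query(th, "D003922")
  expect_error(backend_count(be, q2), "retryable|failed")
})

test_that("the rate limiter blocks or errors once the window is exhausted", {
  be <- entrez_backend(rate_limit_per_min = 2L, wait = FALSE)
  expect_true(ehrlit:::rate_limit_gate(be))
  expect_true(ehrlit:::rate_limit_gate(be))
  expect_error(ehrlit:::rate_limit_gate(be), "rate limit")
})
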