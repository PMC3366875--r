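# Citation backends: a deterministic local corpus implementing the query
# semantics exactly, a query cache, and an optional NCBI E-utilities client.

#' Load a citation corpus
#'
#' Dialects: `"fixture-tsv"` (columns: id, title, ISO date, pipe-joined
#' `descriptor[/QUALIFIER]` index terms; no header) and `"medline-xml"`, a
#' subset of MEDLINE/PubMed XML (`PubmedArticle` with `PMID`, `ArticleTitle`
#' and `MeshHeadingList`).
#'
#' @param source path to the corpus file.
#' @param dialect `"fixture-tsv"` or `"medline-xml"`.
#' @return an object of class `citation_corpus`: a list of citations, each
#'   with `citation_id`, `title`, `date` and an `index` data.frame
#'   (`descriptor`, `qualifier`, with `NA` for unqualified terms).
#' @export
load_corpus <- function(source, dialect = c("fixture-tsv", "medline-xml")) {
  dialect <- match.arg(dialect)
  cits <- if (dialect == "fixture-tsv") load_corpus_tsv(source)
          else load_corpus_xml(source)
  ids <- vapply(cits, `[[`, "", "citation_id")
  if (anyDuplicated(ids)) {
    stop("duplicate citation id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(cits) <- ids
  structure(list(citations = cits), class = "citation_corpus")
}

parse_index_terms <- function(s) {
  if (!nzchar(s)) {
    return(data.frame(descriptor = character(), qualifier = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], "/", fixed = TRUE)
  data.frame(descriptor = vapply(parts, `[`, "", 1),
             qualifier = vapply(parts, function(p)
               if (length(p) > 1L) toupper(p[2]) else NA_character_, ""),
             stringsAsFactors = FALSE)
}

load_corpus_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || length(f) > 4L) {
      stop("malformed corpus TSV at line ", i)
    }
    idx <- parse_index_terms(if (length(f) == 4L) f[4] else "")
    if (!nrow(idx)) stop("corpus TSV line ", i, ": citation has no index terms")
    list(citation_id = f[1], title = f[2], date = f[3], index = idx)
  })
}

load_corpus_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  lapply(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    y <- xml2::xml_text(xml2::xml_find_first(a, ".//PubDate/Year"))
    headings <- xml2::xml_find_all(a, ".//MeshHeadingList/MeshHeading")
    idx <- do.call(rbind, lapply(headings, function(h) {
      dn <- xml2::xml_find_first(h, "./DescriptorName")
      ui <- xml2::xml_attr(dn, "UI")
      desc <- if (!is.na(ui)) ui else xml2::xml_text(dn)
      qn <- xml2::xml_find_all(h, "./QualifierName")
      if (!length(qn)) {
        data.frame(descriptor = desc, qualifier = NA_character_,
                   stringsAsFactors = FALSE)
      } else {
        qa <- xml2::xml_attr(qn, "UI")
        qv <- ifelse(is.na(qa), toupper(xml2::xml_text(qn)), qa)
        data.frame(descriptor = desc, qualifier = qv, stringsAsFactors = FALSE)
      }
    }))
    if (is.null(idx) || !nrow(idx)) {
      stop("citation ", pmid, " has no MeSH index terms")
    }
    list(citation_id = pmid, title = title,
         date = if (is.na(y)) "1900-01-01" else paste0(y, "-01-01"),
         index = idx)
  })
}

#' Write a corpus in the fixture TSV dialect
#'
#' @param corpus a `citation_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus_tsv <- function(corpus, path) {
  rows <- vapply(corpus$citations, function(c) {
    terms <- ifelse(is.na(c$index$qualifier), c$index$descriptor,
                    paste0(c$index$descriptor, "/", c$index$qualifier))
    paste(c$citation_id, c$title, c$date, paste(terms, collapse = "|"),
          sep = "\t")
  }, "")
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.citation_corpus <- function(x, ...) {
  cat("citation corpus:", length(x$citations), "citations\n")
  invisible(x)
}

#' Local citation backend over an in-memory corpus
#'
#' A pure function of (corpus, query) implementing the clause semantics
#' exactly: a citation matches a clause without qualifiers iff some index
#' term carries the clause descriptor; a clause with qualifiers requires, for
#' each selected qualifier, the explicit `(descriptor, qualifier)` pair among
#' the index terms. The disease clause is treated identically. Optional tree
#' explosion (a descriptor matching its tree descendants, as live PubMed
#' `[mh]` does) is off by default; the n + 1 relatedness guarantee holds only
#' without it.
#'
#' @param corpus a `citation_corpus` from [load_corpus()].
#' @param cache cache results keyed on the canonical rendered query string.
#' @param explode match tree descendants of each clause descriptor (requires
#'   `thesaurus`).
#' @param thesaurus a [mesh_thesaurus], needed only when `explode = TRUE`.
#' @return an object of class `local_backend`.
#' @export
local_backend <- function(corpus, cache = TRUE, explode = FALSE,
                          thesaurus = NULL) {
  if (explode && is.null(thesaurus)) {
    stop("explode = TRUE requires a thesaurus")
  }
  structure(list(corpus = corpus, explode = explode, thesaurus = thesaurus,
                 cache = if (cache) new.env(parent = emptyenv()) else NULL),
            class = "local_backend")
}

clause_descriptor_set <- function(backend, id) {
  if (!backend$explode) return(id)
  th <- backend$thesaurus
  trees <- th$descriptors[[id]]$tree_numbers
  if (is.null(trees) || !length(trees)) return(id)
  ids <- names(th$descriptors)
  desc <- vapply(ids, function(other) {
    tn <- th$descriptors[[other]]$tree_numbers
    any(vapply(trees, function(t) any(tn == t | startsWith(tn, paste0(t, "."))),
               NA))
  }, NA)
  ids[desc]
}

citation_matches_query <- function(backend, citation, query) {
  clauses <- c(query$clauses,
               list(list(id = query$disease$id, qualifiers = character())))
  idx <- citation$index
  for (cl in clauses) {
    ids <- clause_descriptor_set(backend, cl$id)
    if (!length(cl$qualifiers)) {
      if (!any(idx$descriptor %in% ids)) return(FALSE)
    } else {
      for (q in cl$qualifiers) {
        if (!any(idx$descriptor %in% ids & !is.na(idx$qualifier) &
                 idx$qualifier == q)) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Count / list citations matching a query
#'
#' `backend_count()` returns the number of matching citations;
#' `backend_search()` returns the matching citations sorted by date
#' descending, ties broken by id. With caching enabled, results equal the
#' uncached backend's (cache transparency).
#'
#' @param backend a backend object ([local_backend()] or [entrez_backend()]).
#' @param query a [mesh_query].
#' @param ... passed to methods.
#' @return `backend_count()`: an integer; `backend_search()`: a list of
#'   citation records.
#' @export
backend_count <- function(backend, query, ...) UseMethod("backend_count")

#' @rdname backend_count
#' @export
backend_search <- function(backend, query, ...) UseMethod("backend_search")

local_eval <- function(backend, query) {
  key <- render_query(query)
  if (!is.null(backend$cache) && !is.null(backend$cache[[key]])) {
    return(backend$cache[[key]])
  }
  hit <- vapply(backend$corpus$citations, citation_matches_query,
                NA, backend = backend, query = query)
  matches <- backend$corpus$citations[hit]
  if (length(matches)) {
    dates <- vapply(matches, `[[`, "", "date")
    ids <- vapply(matches, `[[`, "", "citation_id")
    matches <- matches[order(dates, ids, decreasing = c(TRUE, FALSE),
                             method = "radix")]
  }
  res <- list(count = length(matches), matches = matches,
              timestamp = Sys.time())
  if (!is.null(backend$cache)) backend$cache[[key]] <- res
  res
}

#' @export
backend_count.local_backend <- function(backend, query, ...) {
  local_eval(backend, query)$count
}

#' @export
backend_search.local_backend <- function(backend, query, ...) {
  local_eval(backend, query)$matches
}

#' NCBI E-utilities (ESearch) backend
#'
#' Live client for PubMed citation counts via ESearch with `retmax=0`.
#' Requests are cached on the canonical query string and throttled by a
#' sliding-window rate limiter (default 1,000 queries per minute; modern NCBI
#' guidance is stricter, so a conservative limit can be configured). Every
#' issued request is logged. Requires network access; the local backend is
#' the deterministic stand-in for offline work.
#'
#' @param email,tool identification parameters sent to NCBI.
#' @param rate_limit_per_min maximum requests in any 60-second window.
#' @param base_url ESearch endpoint.
#' @param wait if `TRUE`, sleep until the rate limiter permits; if `FALSE`,
#'   raise an error when the limit is exhausted.
#' @return an object of class `entrez_backend`.
#' @export
entrez_backend <- function(email = NULL, tool = "ehrlit",
                           rate_limit_per_min = 1000L,
                           base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi",
                           wait = TRUE) {
  state <- new.env(parent = emptyenv())
  state$cache <- new.env(parent = emptyenv())
  state$issued <- numeric()   # request timestamps (seconds)
  state$log <- list()
  structure(list(email = email, tool = tool,
                 rate_limit_per_min = as.integer(rate_limit_per_min),
                 base_url = base_url, wait = wait, state = state),
            class = "entrez_backend")
}

rate_limit_gate <- function(backend) {
  st <- backend$state
  repeat {
    now <- as.numeric(Sys.time())
    st$issued <- st$issued[st$issued > now - 60]
    if (length(st$issued) < backend$rate_limit_per_min) {
      st$issued <- c(st$issued, now)
      return(invisible(TRUE))
    }
    if (!backend$wait) stop("rate limit exhausted (",
                            backend$rate_limit_per_min, "/min)")
    Sys.sleep(min(st$issued) + 60 - now + 0.01)
  }
}

#' @export
backend_count.entrez_backend <- function(backend, query, ...) {
  key <- render_query(query)
  st <- backend$state
  if (!is.null(st$cache[[key]])) return(st$cache[[key]]$count)
  rate_limit_gate(backend)
  url <- paste0(backend$base_url, "?db=pubmed&retmax=0&term=",
                utils::URLencode(key, reserved = TRUE),
                "&tool=", utils::URLencode(backend$tool, reserved = TRUE),
                if (!is.null(backend$email)) {
                  paste0("&email=", utils::URLencode(backend$email,
                                                     reserved = TRUE))
                } else "")
  st$log[[length(st$log) + 1L]] <- list(time = Sys.time(), query = key)
  resp <- tryCatch(suppressWarnings(xml2::read_xml(url)), error = function(e) {
    stop("E-utilities request failed (retryable): ", conditionMessage(e))
  })
  n <- as.integer(xml2::xml_text(xml2::xml_find_first(resp, "//Count")))
  st$cache[[key]] <- list(count = n, ids = character(),
                          timestamp = Sys.time())
  n
}

#' @export
backend_search.entrez_backend <- function(backend, query, ...) {
  stop("entrez backend supports counts only; use the local backend for ",
       "citation lists")
}

# test/maintenance hook: pre-seed the entrez cache without a network call
seed_entrez_cache <- function(backend, query, count) {
  backend$state$cache[[render_query(query)]] <-
    list(count = as.integer(count), ids = character(), timestamp = Sys.time())
  invisible(backend)
}
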