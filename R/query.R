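# Boolean query model: MeSH clauses + disease, PubMed-style rendering,
# relatedness measure, candidate-count annotation.

query_term <- function(thesaurus, id) {
  d <- thesaurus$descriptors[[id]]
  if (is.null(d)) stop("unknown descriptor id: ", id)
  list(id = d$id, name = d$preferred_name)
}

check_term_arg <- function(term) {
  # term may be a descriptor id or a row of identified keywords
  if (is.data.frame(term) || (is.list(term) && !is.null(term$descriptor))) {
    if (isTRUE(any(term$negated))) {
      stop("negated keywords cannot be added to a query: ",
           paste(unique(term$descriptor), collapse = ", "))
    }
    as.character(term$descriptor[1])
  } else {
    as.character(term)[1]
  }
}

#' Start a query: one EHR keyword AND the disease
#'
#' The disease anchors every query and must (in strict mode) carry at least
#' one tree number in the disease branch (C by default). The first iteration
#' renders as `(term1[mh]) AND (disease[mh])`; the n-th query retrieves
#' citations sharing at least n + 1 MeSH keywords with the record.
#'
#' @param thesaurus a [mesh_thesaurus].
#' @param disease descriptor id of the disease.
#' @param term descriptor id of a non-negated identified keyword, or a row of
#'   an `identified_keywords` data.frame (negated rows are rejected); `NULL`
#'   for the disease-only "general query".
#' @param strict enforce the disease-branch invariant.
#' @param disease_branch branch letter the disease must belong to.
#' @return an object of class `mesh_query`.
#' @export
initial_query <- function(thesaurus, disease, term = NULL, strict = TRUE,
                          disease_branch = "C") {
  dz <- query_term(thesaurus, check_term_arg(disease))
  if (strict) {
    tn <- thesaurus$descriptors[[dz$id]]$tree_numbers
    if (!any(substr(tn, 1, 1) == disease_branch)) {
      stop("disease ", dz$id, " has no tree number in branch ", disease_branch)
    }
  }
  q <- structure(list(disease = dz, clauses = list(), iteration = 0L),
                 class = "mesh_query")
  if (!is.null(term)) q <- add_term(q, thesaurus, term)
  q
}

#' AND-extend a query with another keyword
#'
#' Returns a new query value; the input is unchanged. Adding a descriptor
#' already present (or the disease itself) is a no-op, so clauses stay
#' deduplicated and `iteration` always equals the clause count.
#'
#' @param query a [mesh_query] (see [initial_query()]).
#' @param thesaurus a [mesh_thesaurus].
#' @param term descriptor id or `identified_keywords` row; negated rows are
#'   rejected.
#' @return a new `mesh_query`.
#' @export
add_term <- function(query, thesaurus, term) {
  id <- check_term_arg(term)
  if (id == query$disease$id ||
      id %in% vapply(query$clauses, `[[`, "", "id")) {
    return(query)
  }
  t <- query_term(thesaurus, id)
  query$clauses[[length(query$clauses) + 1L]] <-
    list(id = t$id, name = t$name, qualifiers = character())
  query$iteration <- length(query$clauses)
  query
}

#' Attach a subheading qualifier to a query clause
#'
#' The qualifier must be admissible on both sides: allowable for the MeSH
#' descriptor and admitted by the originating section's rule (its effective
#' qualifier set). Attaching the same qualifier twice is idempotent; a clause
#' with q qualifiers renders as q conjuncts.
#'
#' @param query a [mesh_query].
#' @param thesaurus a [mesh_thesaurus].
#' @param descriptor id of a descriptor already present among the clauses.
#' @param qualifier qualifier abbreviation (e.g. `"EP"`).
#' @param rule optional [section_rule]; when given (with `config`), the
#'   section side of admissibility is checked against its effective
#'   qualifiers.
#' @param config the [app_config] the rule came from (for defaults).
#' @return a new `mesh_query`.
#' @export
attach_qualifier <- function(query, thesaurus, descriptor, qualifier,
                             rule = NULL, config = NULL) {
  qualifier <- toupper(qualifier)
  idx <- which(vapply(query$clauses, `[[`, "", "id") == descriptor)
  if (!length(idx)) stop("descriptor ", descriptor, " is not in the query")
  allowed <- thesaurus$descriptors[[descriptor]]$qualifiers
  if (!qualifier %in% allowed) {
    stop("qualifier ", qualifier, " is not allowable for descriptor ",
         descriptor)
  }
  if (!is.null(rule) && !qualifier %in% effective_qualifiers(rule, thesaurus)) {
    stop("qualifier ", qualifier,
         " is not admitted by the section rule for this keyword")
  }
  cl <- query$clauses[[idx[1]]]
  if (!qualifier %in% cl$qualifiers) {
    cl$qualifiers <- c(cl$qualifiers, qualifier)
  }
  query$clauses[[idx[1]]] <- cl
  query
}

#' Render a query in PubMed syntax
#'
#' Each clause without qualifiers renders as `(Name[mh])`; a clause with q
#' qualifiers renders as q conjuncts `(Name/qualifier name[mh])`; the disease
#' renders last. Conjuncts are joined by `" AND "`. Rendering is
#' deterministic and injective on canonicalized queries.
#'
#' @param query a [mesh_query].
#' @param thesaurus optional [mesh_thesaurus] used to resolve qualifier
#'   abbreviations to full subheading names.
#' @return a single query string.
#' @export
render_query <- function(query, thesaurus = NULL) {
  conjunct <- function(name, quals) {
    if (!length(quals)) return(sprintf("(%s[mh])", name))
    vapply(quals, function(q) {
      sprintf("(%s/%s[mh])", name, qualifier_name(q, thesaurus))
    }, "")
  }
  parts <- unlist(lapply(query$clauses,
                         function(cl) conjunct(cl$name, cl$qualifiers)))
  parts <- c(parts, sprintf("(%s[mh])", query$disease$name))
  paste(parts, collapse = " AND ")
}

#' @export
print.mesh_query <- function(x, ...) {
  cat("query (iteration ", x$iteration, "): ", render_query(x), "\n", sep = "")
  invisible(x)
}

#' Relatedness degree between a citation and an EHR
#'
#' The number of MeSH descriptors shared between the citation's index terms
#' and the union of the EHR-derived terms and the disease. Every citation
#' retrieved by the n-th query has relatedness at least n + 1.
#'
#' @param citation a citation record (see [load_corpus()]); its `index`
#'   data.frame's `descriptor` column is used.
#' @param ehr_terms descriptor ids identified in the record.
#' @param disease descriptor id of the disease.
#' @return a non-negative integer.
#' @export
relevance <- function(citation, ehr_terms, disease) {
  length(intersect(unique(citation$index$descriptor),
                   union(ehr_terms, disease)))
}

#' Annotate keywords with candidate citation counts
#'
#' For every non-negated keyword whose descriptor is not already in the query
#' (nor the disease), fills `candidate_count` with the number of citations
#' the backend would return if the keyword were AND-concatenated to the
#' current query. Negated or already-present keywords keep `NA`. A backend
#' failure marks that keyword count-unavailable (`NA`) and leaves the others
#' unaffected.
#'
#' @param keywords an `identified_keywords` data.frame.
#' @param query the current [mesh_query].
#' @param backend a backend (see [local_backend()]).
#' @param thesaurus a [mesh_thesaurus].
#' @return `keywords` with `candidate_count` filled.
#' @export
annotate_counts <- function(keywords, query, backend, thesaurus) {
  present <- c(query$disease$id, vapply(query$clauses, `[[`, "", "id"))
  keywords$candidate_count <- NA_integer_
  for (i in seq_len(nrow(keywords))) {
    if (keywords$negated[i] || keywords$descriptor[i] %in% present) next
    keywords$candidate_count[i] <- tryCatch(
      backend_count(backend, add_term(query, thesaurus,
                                      keywords$descriptor[i])),
      error = function(e) NA_integer_)
  }
  keywords
}
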