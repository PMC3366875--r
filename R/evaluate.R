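# Evaluation: concept-level precision/recall against gold annotations,
# branch-configuration sweeps, and citation-reduction trajectories.

as_doc_sets <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("doc_id", "descriptor") %in% names(x)))
    return(lapply(split(x$descriptor, x$doc_id), unique))
  }
  lapply(x, unique)
}

#' Concept-level precision and recall
#'
#' Matching unit is the MeSH descriptor, per document: tp = identified
#' intersect gold, fp = identified minus gold, fn = gold minus identified.
#' Macro averaging (the default) takes the mean of per-document precision and
#' recall; micro pools the counts. A document with empty gold and empty
#' identified scores P = R = 100; an empty identified set against non-empty
#' gold scores R = 0 and (vacuously) P = 100.
#'
#' @param identified named list of descriptor-id vectors keyed by doc id, or
#'   a data.frame with columns `doc_id`, `descriptor` (non-negated
#'   identifications only).
#' @param gold gold annotations in the same two forms.
#' @param averaging `"macro"` (mean of per-doc rates) or `"micro"` (pooled).
#' @param empty_gold `"perfect"` (P = R = 100 for empty/empty documents) or
#'   `"exclude"` (drop such documents from macro averaging).
#' @return an object of class `eval_result` with elements `precision`,
#'   `recall` (percentages), `averaging`, and `per_doc` (doc_id, tp, fp, fn,
#'   precision, recall).
#' @export
precision_recall <- function(identified, gold,
                             averaging = c("macro", "micro"),
                             empty_gold = c("perfect", "exclude")) {
  averaging <- match.arg(averaging)
  empty_gold <- match.arg(empty_gold)
  identified <- as_doc_sets(identified)
  gold <- as_doc_sets(gold)
  docs <- sort(union(names(identified), names(gold)))
  per_doc <- do.call(rbind, lapply(docs, function(d) {
    i <- identified[[d]] %||% character()
    g <- gold[[d]] %||% character()
    tp <- length(intersect(i, g))
    fp <- length(setdiff(i, g))
    fn <- length(setdiff(g, i))
    data.frame(doc_id = d, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp == 0L) 100 else 100 * tp / (tp + fp),
               recall = if (tp + fn == 0L) 100 else 100 * tp / (tp + fn),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_doc)) {
    per_doc <- data.frame(doc_id = character(), tp = integer(),
                          fp = integer(), fn = integer(),
                          precision = numeric(), recall = numeric())
  }
  scored <- per_doc
  if (empty_gold == "exclude") {
    scored <- scored[!(scored$tp + scored$fp + scored$fn == 0L), , drop = FALSE]
  }
  if (averaging == "macro") {
    p <- if (nrow(scored)) mean(scored$precision) else 100
    r <- if (nrow(scored)) mean(scored$recall) else 100
  } else {
    tp <- sum(scored$tp); fp <- sum(scored$fp); fn <- sum(scored$fn)
    p <- if (tp + fp == 0L) 100 else 100 * tp / (tp + fp)
    r <- if (tp + fn == 0L) 100 else 100 * tp / (tp + fn)
  }
  structure(list(precision = p, recall = r, averaging = averaging,
                 per_doc = per_doc),
            class = "eval_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s-averaged over %d document(s): P = %.1f%%, R = %.1f%%\n",
              x$averaging, nrow(x$per_doc), x$precision, x$recall))
  invisible(x)
}

keyword_concept_sets <- function(docs, thesaurus, config = NULL,
                                 baseline = FALSE, keep_negated = baseline) {
  out <- list()
  for (doc in docs) {
    kw <- if (baseline) identify_baseline(doc, thesaurus)
          else identify_keywords(doc, thesaurus, config)
    if (!keep_negated) kw <- kw[!kw$negated, , drop = FALSE]
    out[[doc$doc_id]] <- unique(kw$descriptor)
  }
  out
}

#' Precision/recall sweep over branch configurations
#'
#' Evaluates keyword identification under several branch restrictions (every
#' rule's branch set is overridden by the sweep's set) plus, optionally, the
#' baseline method (all sections, all branches, negated mentions retained).
#'
#' @param docs list of [cda_document] objects.
#' @param gold gold annotations (data.frame `doc_id`, `descriptor`, or named
#'   list).
#' @param thesaurus a [mesh_thesaurus].
#' @param config template [app_config] supplying the section rules.
#' @param branch_sets named list of branch-letter vectors, e.g.
#'   `list("A-G" = LETTERS[1:7])`.
#' @param baseline add a `"baseline"` row using [identify_baseline()].
#' @param averaging passed to [precision_recall()].
#' @return data.frame with columns `config`, `precision`, `recall`.
#' @export
branch_sweep <- function(docs, gold, thesaurus, config = default_config(),
                         branch_sets = list(
                           "A-Z" = mesh_branches(),
                           "A-G,N,Z" = c("A", "B", "C", "D", "E", "F", "G",
                                         "N", "Z"),
                           "A-G" = c("A", "B", "C", "D", "E", "F", "G"),
                           "A-D,F" = c("A", "B", "C", "D", "F")),
                         baseline = TRUE, averaging = "macro") {
  rows <- lapply(names(branch_sets), function(lab) {
    cfg <- config
    cfg$rules <- lapply(cfg$rules, function(r) {
      r$branches <- branch_sets[[lab]]
      r
    })
    res <- precision_recall(keyword_concept_sets(docs, thesaurus, cfg),
                            gold, averaging = averaging)
    data.frame(config = lab, precision = res$precision, recall = res$recall,
               stringsAsFactors = FALSE)
  })
  if (baseline) {
    res <- precision_recall(
      keyword_concept_sets(docs, thesaurus, baseline = TRUE),
      gold, averaging = averaging)
    rows <- c(rows, list(data.frame(config = "baseline",
                                    precision = res$precision,
                                    recall = res$recall,
                                    stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}

#' Citation-reduction trajectory across query iterations
#'
#' Starting from the disease-only general query (iteration 0), AND-adds one
#' identified keyword per iteration according to the selection policy and
#' records the backend count. Counts are non-increasing; iteration stops when
#' the count drops to `stop_count` or fewer, candidates run out, or
#' `max_iter` is reached.
#'
#' @param doc a [cda_document].
#' @param thesaurus a [mesh_thesaurus].
#' @param config an [app_config].
#' @param disease descriptor id of the disease.
#' @param backend a citation backend.
#' @param policy `"by-span-order"` (first occurrence order),
#'   `"by-smallest-count"` (greedy most-restrictive next), or `"scripted"`
#'   (take `terms` in the given order, reproducing a recorded session).
#' @param terms descriptor ids for the scripted policy.
#' @param stop_count stop once the count is at or below this (default 10, a
#'   typical first page of search results).
#' @param max_iter maximum number of keyword additions.
#' @param strict passed to [initial_query()].
#' @return data.frame with columns `iteration`, `query`, `count`.
#' @export
reduction_curve <- function(doc, thesaurus, config, disease, backend,
                            policy = c("by-span-order", "by-smallest-count",
                                       "scripted"),
                            terms = NULL, stop_count = 10L, max_iter = 10L,
                            strict = TRUE) {
  policy <- match.arg(policy)
  kw <- identify_keywords(doc, thesaurus, config)
  kw <- kw[!kw$negated, , drop = FALSE]
  candidates <- setdiff(unique(kw$descriptor), disease)
  if (policy == "scripted") {
    stopifnot(!is.null(terms))
    missing <- setdiff(terms, candidates)
    if (length(missing)) {
      stop("scripted term(s) not identified in the document: ",
           paste(missing, collapse = ", "))
    }
    candidates <- terms
  }
  q <- initial_query(thesaurus, disease, strict = strict)
  n <- backend_count(backend, q)
  out <- data.frame(iteration = 0L, query = render_query(q, thesaurus),
                    count = n, stringsAsFactors = FALSE)
  it <- 0L
  while (n > stop_count && it < max_iter && length(candidates)) {
    pick <- if (policy == "by-smallest-count") {
      counts <- vapply(candidates, function(id) {
        backend_count(backend, add_term(q, thesaurus, id))
      }, 0L)
      candidates[order(counts, candidates)[1]]
    } else {
      candidates[1]
    }
    q <- add_term(q, thesaurus, pick)
    candidates <- setdiff(candidates, pick)
    n <- backend_count(backend, q)
    it <- it + 1L
    out <- rbind(out, data.frame(iteration = it,
                                 query = render_query(q, thesaurus),
                                 count = n, stringsAsFactors = FALSE))
  }
  out
}

#' Read / write gold annotation TSV
#'
#' Columns: doc_id, descriptor, optional section_index; with header.
#'
#' @param path file path.
#' @return `read_gold_tsv()`: data.frame; `write_gold_tsv()`: `path`.
#' @export
read_gold_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", stringsAsFactors = FALSE)
}

#' @rdname read_gold_tsv
#' @param gold data.frame with columns `doc_id`, `descriptor`.
#' @export
write_gold_tsv <- function(gold, path) {
  utils::write.table(gold, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
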