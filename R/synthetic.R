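# Seeded generators: mini-MeSH thesauri, CDA documents with gold
# annotations, and MeSH-indexed citation corpora. Same spec + seed =>
# byte-identical fixtures; each artifact kind draws from its own seeded
# stream so fixtures are independently reproducible.

GEN_QUALIFIERS <- c("EP", "DI", "TH", "DT", "PC")

#' Specification for the synthetic fixture generators
#'
#' Defaults emulate a small heterogeneous clinical-document collection: 17
#' English documents (the size of a curated evaluation set of EHRs,
#' laboratory reports and discharge summaries), each carrying planted MeSH
#' mentions in relevant sections, negated mentions, out-of-branch distractors
#' and mentions in an irrelevant section, plus a citation corpus whose index
#' sets favor the planted descriptors so conjunctive queries shrink
#' realistically.
#'
#' @param seed integer seed; sub-streams are derived per artifact kind.
#' @param n_descriptors mini-MeSH size.
#' @param branch_mix named weights over branch letters for tree-number
#'   placement (must include branches outside any restriction under test so
#'   distractors exist).
#' @param n_docs number of CDA documents.
#' @param planted_per_doc gold (positive, in-branch, relevant-section)
#'   mentions per document.
#' @param negated_per_doc negated in-branch mentions per document.
#' @param distractors_per_doc out-of-branch mentions in relevant sections.
#' @param irrelevant_per_doc in-branch mentions in a rule-less section.
#' @param synonym_rate probability a planted mention uses an entry-term
#'   synonym instead of the preferred name.
#' @param multiword_rate probability a generated term is two words.
#' @param qualified_fraction fraction of citation index terms carrying an
#'   explicit qualifier.
#' @param n_citations corpus size.
#' @return a validated list of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_descriptors = 60L,
                           branch_mix = c(A = 1, B = 1, C = 2, D = 2, E = 1,
                                          F = 1, G = 1, H = 1, J = 1, K = 1,
                                          N = 1, Z = 1),
                           n_docs = 17L, planted_per_doc = 5L,
                           negated_per_doc = 2L, distractors_per_doc = 3L,
                           irrelevant_per_doc = 2L, synonym_rate = 0.5,
                           multiword_rate = 0.4, qualified_fraction = 0.3,
                           n_citations = 120L) {
  spec <- list(seed = as.integer(seed), n_descriptors = as.integer(n_descriptors),
               branch_mix = branch_mix, n_docs = as.integer(n_docs),
               planted_per_doc = as.integer(planted_per_doc),
               negated_per_doc = as.integer(negated_per_doc),
               distractors_per_doc = as.integer(distractors_per_doc),
               irrelevant_per_doc = as.integer(irrelevant_per_doc),
               synonym_rate = synonym_rate, multiword_rate = multiword_rate,
               qualified_fraction = qualified_fraction,
               n_citations = as.integer(n_citations))
  counts <- c(spec$n_descriptors, spec$n_docs, spec$planted_per_doc,
              spec$negated_per_doc, spec$distractors_per_doc,
              spec$irrelevant_per_doc, spec$n_citations)
  if (any(counts < 0L)) stop("generator spec: counts must be >= 0")
  if (is.null(names(branch_mix)) ||
      !all(names(branch_mix) %in% mesh_branches())) {
    stop("generator spec: branch_mix must be named with valid branch letters")
  }
  if (any(branch_mix < 0) || all(branch_mix == 0)) {
    stop("generator spec: branch_mix weights must be >= 0 and not all zero")
  }
  for (p in c(spec$synonym_rate, spec$multiword_rate, spec$qualified_fraction)) {
    if (p < 0 || p > 1) stop("generator spec: rates must be in [0, 1]")
  }
  structure(spec, class = "generator_spec")
}

# nonsense-word pool, disjoint from template/negation vocabulary
gen_words <- function(n) {
  syll <- c("ba", "cri", "dol", "fen", "gam", "hy", "lix", "mor", "nu",
            "pra", "quo", "rin", "sa", "tev", "ul", "vex", "wo", "xan",
            "yel", "zib", "kef", "jor", "plu", "tris")
  reserved <- c(negation_lexicon(), "patient", "presents", "with",
                "reported", "routine", "follow", "up", "visit", "review")
  out <- character(0)
  while (length(out) < n) {
    w <- paste(sample(syll, sample(2:3, 1), replace = TRUE), collapse = "")
    if (!w %in% out && !w %in% reserved) out <- c(out, w)
  }
  out
}

cap <- function(w) paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))

#' Generate a mini-MeSH thesaurus
#'
#' Descriptors carry 1-2 tree numbers drawn from `branch_mix`, an entry-term
#' synonym at `synonym_rate`, two-word preferred names at `multiword_rate`,
#' and 0-3 allowable qualifiers. Every word is used in at most one term
#' across the thesaurus, so surface forms never overlap or nest.
#'
#' @param spec a [generator_spec].
#' @return a [mesh_thesaurus].
#' @export
make_mini_mesh <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::with_seed(spec$seed + 101L, {
    words <- gen_words(4L * spec$n_descriptors)
    wi <- 0L
    take <- function(k) {
      wi <<- wi + k
      words[(wi - k + 1L):wi]
    }
    term <- function() {
      k <- if (stats::runif(1) < spec$multiword_rate) 2L else 1L
      paste(cap(take(k)), collapse = " ")
    }
    branches <- names(spec$branch_mix)
    descs <- lapply(seq_len(spec$n_descriptors), function(i) {
      pref <- term()
      syns <- if (stats::runif(1) < spec$synonym_rate) term() else character()
      b1 <- sample(branches, 1L, prob = spec$branch_mix)
      trees <- sprintf("%s%02d.%03d", b1, sample(1:20, 1), sample(1:999, 1))
      if (stats::runif(1) < 0.25) {
        b2 <- sample(branches, 1L, prob = spec$branch_mix)
        trees <- c(trees, sprintf("%s%02d.%03d", b2, sample(1:20, 1),
                                  sample(1:999, 1)))
      }
      nq <- sample(0:3, 1L)
      mesh_descriptor(sprintf("D%06d", i), pref, syns, trees,
                      if (nq) sample(GEN_QUALIFIERS, nq) else character())
    })
    mesh_thesaurus(descs)
  })
}

branch_letters_of <- function(thesaurus, id) {
  unique(substr(thesaurus$descriptors[[id]]$tree_numbers, 1, 1))
}

pick_surface <- function(thesaurus, id, use_synonym) {
  d <- thesaurus$descriptors[[id]]
  syns <- setdiff(d$entry_terms, d$preferred_name)
  if (use_synonym && length(syns)) syns[1] else d$preferred_name
}

#' Generate CDA documents with known gold annotations
#'
#' Each document has 2-3 relevant narrative sections (per the configuration's
#' rules) plus an irrelevant `Appointment` section. Templated sentences plant
#' positive mentions ("Patient presents with X."), negated mentions ("No X
#' reported."), out-of-branch distractors and irrelevant-section mentions.
#' The gold standard is exactly the planted non-negated in-branch mentions in
#' relevant sections; `key` records every planted id per document, so
#' expected tp/fp/fn under any branch restriction are computable in advance.
#'
#' @param spec a [generator_spec].
#' @param thesaurus a [mesh_thesaurus] (from [make_mini_mesh()]).
#' @param config an [app_config]; its rules define the relevant sections.
#' @return list with elements `docs` (list of [cda_document]), `gold`
#'   (data.frame `doc_id`, `descriptor`, `section_index`) and `key`
#'   (per-document lists of `planted`, `negated`, `distractor`, `irrelevant`
#'   descriptor ids).
#' @export
make_cda_set <- function(spec, thesaurus, config = default_config()) {
  stopifnot(inherits(spec, "generator_spec"))
  all_ids <- names(thesaurus$descriptors)
  rule_pools <- lapply(config$rules, function(r) {
    br <- effective_branches(r, config)
    in_ids <- all_ids[vapply(all_ids, function(id)
      any(branch_letters_of(thesaurus, id) %in% br), NA)]
    out_ids <- all_ids[vapply(all_ids, function(id) {
      bl <- branch_letters_of(thesaurus, id)
      length(bl) > 0L && !any(bl %in% br)
    }, NA)]
    list(in_ids = in_ids, out_ids = out_ids)
  })

  withr::with_seed(spec$seed + 202L, {
    docs <- vector("list", spec$n_docs)
    gold <- data.frame(doc_id = character(), descriptor = character(),
                       section_index = integer(), stringsAsFactors = FALSE)
    key <- list()
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("doc%02d", d)
      n_sec <- sample(2:min(3L, length(config$rules)), 1L)
      rule_idx <- sort(sample(seq_along(config$rules), n_sec))
      used <- character()
      sections <- list()
      planted_ids <- negated_ids <- distractor_ids <- character()
      planted_rows <- list()
      quota <- function(total, k) {
        q <- rep(total %/% k, k)
        if (total %% k) q[seq_len(total %% k)] <- q[seq_len(total %% k)] + 1L
        q
      }
      np <- quota(spec$planted_per_doc, n_sec)
      nn <- quota(spec$negated_per_doc, n_sec)
      nd <- quota(spec$distractors_per_doc, n_sec)
      for (k in seq_len(n_sec)) {
        ri <- rule_idx[k]
        pool <- rule_pools[[ri]]
        sentences <- character()
        avail <- setdiff(pool$in_ids, used)
        if (length(avail) < np[k] + nn[k]) {
          stop("generator spec: not enough in-branch descriptors for document ",
               doc_id, "; increase n_descriptors or branch weights")
        }
        pl <- if (np[k]) sample(avail, np[k]) else character()
        used <- c(used, pl)
        for (id in pl) {
          surf <- pick_surface(thesaurus, id,
                               stats::runif(1) < spec$synonym_rate)
          sentences <- c(sentences,
                         sprintf("Patient presents with %s.", surf))
          planted_rows[[length(planted_rows) + 1L]] <-
            data.frame(doc_id = doc_id, descriptor = id,
                       section_index = k - 1L, stringsAsFactors = FALSE)
        }
        ng <- if (nn[k]) sample(setdiff(pool$in_ids, used), nn[k]) else character()
        used <- c(used, ng)
        for (id in ng) {
          sentences <- c(sentences, sprintf(
            "No %s reported.", pick_surface(thesaurus, id, FALSE)))
        }
        davail <- setdiff(pool$out_ids, used)
        if (length(davail) < nd[k]) {
          stop("generator spec: not enough out-of-branch descriptors for ",
               doc_id, "; widen branch_mix")
        }
        dt <- if (nd[k]) sample(davail, nd[k]) else character()
        used <- c(used, dt)
        for (id in dt) {
          sentences <- c(sentences, sprintf(
            "Patient presents with %s.", pick_surface(thesaurus, id, FALSE)))
        }
        sentences <- c(sentences, "Routine follow up visit.")
        rule <- config$rules[[ri]]
        sections[[k]] <- cda_section(
          title = rule$titles[1],
          codes = rule$codes[seq_len(min(1L, nrow(rule$codes))), ,
                             drop = FALSE],
          text = paste(sentences, collapse = " "),
          order_index = k - 1L)
        planted_ids <- c(planted_ids, pl)
        negated_ids <- c(negated_ids, ng)
        distractor_ids <- c(distractor_ids, dt)
      }
      # irrelevant section: in-branch mentions that must contribute nothing
      irr_avail <- setdiff(rule_pools[[rule_idx[1]]]$in_ids, used)
      n_irr <- min(spec$irrelevant_per_doc, length(irr_avail))
      irr <- if (n_irr) sample(irr_avail, n_irr) else character()
      irr_sent <- c(vapply(irr, function(id) sprintf(
        "Patient presents with %s.",
        pick_surface(thesaurus, id, FALSE)), ""),
        "Routine follow up visit.")
      sections[[n_sec + 1L]] <- cda_section(
        title = "Appointment", text = paste(irr_sent, collapse = " "),
        order_index = n_sec)
      docs[[d]] <- cda_document(doc_id = doc_id,
                                title = sprintf("Synthetic record %02d", d),
                                sections = sections)
      gold <- rbind(gold, do.call(rbind, planted_rows))
      key[[doc_id]] <- list(planted = planted_ids, negated = negated_ids,
                            distractor = distractor_ids, irrelevant = irr)
    }
    list(docs = docs, gold = gold, key = key)
  })
}

#' Generate a MeSH-indexed citation corpus
#'
#' Citation index sets of 2-5 descriptors are drawn with a bias toward a
#' preferred pool (typically the planted descriptors of a document set), so
#' conjunctive query chains shrink realistically; `qualified_fraction` of
#' index terms carry an explicit qualifier drawn from the descriptor's
#' allowable set.
#'
#' @param spec a [generator_spec].
#' @param thesaurus a [mesh_thesaurus].
#' @param favored descriptor ids to over-represent (default: all).
#' @return a `citation_corpus`.
#' @export
make_corpus <- function(spec, thesaurus, favored = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  all_ids <- names(thesaurus$descriptors)
  if (is.null(favored) || !length(favored)) favored <- all_ids
  withr::with_seed(spec$seed + 303L, {
    cits <- lapply(seq_len(spec$n_citations), function(i) {
      k <- sample(2:5, 1L)
      k_fav <- min(length(favored), sample(1:k, 1L))
      ids <- unique(c(sample(favored, k_fav),
                      sample(all_ids, k - k_fav)))
      quals <- vapply(ids, function(id) {
        aq <- thesaurus$descriptors[[id]]$qualifiers
        if (length(aq) && stats::runif(1) < spec$qualified_fraction) {
          sample(aq, 1L)
        } else NA_character_
      }, "")
      list(citation_id = sprintf("PM%05d", i),
           title = sprintf("Synthetic citation %d", i),
           date = sprintf("%04d-%02d-%02d", sample(2005:2011, 1L),
                          sample(1:12, 1L), sample(1:28, 1L)),
           index = data.frame(descriptor = ids, qualifier = unname(quals),
                              stringsAsFactors = FALSE))
    })
    names(cits) <- vapply(cits, `[[`, "", "citation_id")
    structure(list(citations = cits), class = "citation_corpus")
  })
}

#' Build a corpus realizing a prescribed citation-reduction curve
#'
#' Constructs citations so that the query chain disease, disease+terms[1],
#' disease+terms[1:2], ... returns exactly `counts[i + 1]` citations at
#' iteration i: `counts[j] - counts[j + 1]` citations are indexed with the
#' disease plus the first j keywords.
#'
#' @param thesaurus a [mesh_thesaurus].
#' @param disease descriptor id anchoring the chain.
#' @param terms descriptor ids added in iteration order.
#' @param counts non-increasing positive counts, one per iteration starting
#'   at the disease-only query (length `length(terms) + 1`).
#' @return a `citation_corpus`.
#' @export
make_curve_corpus <- function(thesaurus, disease, terms, counts) {
  stopifnot(length(counts) == length(terms) + 1L)
  if (any(diff(counts) > 0)) stop("counts must be non-increasing")
  depth_n <- diff(-c(counts, 0L))  # citations indexed to exactly depth j
  depth_of <- rep(seq_along(depth_n), depth_n)
  index_at <- lapply(seq_along(depth_n), function(j) {
    ids <- c(disease, terms[seq_len(j - 1L)])
    data.frame(descriptor = ids, qualifier = rep(NA_character_, length(ids)),
               stringsAsFactors = FALSE)
  })
  cits <- lapply(seq_along(depth_of), function(serial) {
    list(citation_id = sprintf("CV%05d", serial),
         title = sprintf("Curve citation %d", serial),
         date = "2010-06-01",
         index = index_at[[depth_of[serial]]])
  })
  names(cits) <- vapply(cits, `[[`, "", "citation_id")
  structure(list(citations = cits), class = "citation_corpus")
}

#' Write a complete fixture set to a directory
#'
#' Emits `mesh.tsv`, `config.xml`, `docNN.xml` CDA files, `gold.tsv`,
#' `corpus.tsv` and `key.json` (the generator bookkeeping). Running twice
#' with the same spec produces byte-identical files.
#'
#' @param spec a [generator_spec].
#' @param dir output directory (created if needed).
#' @param config an [app_config].
#' @return invisibly, the list returned by [make_cda_set()] plus `thesaurus`,
#'   `corpus` and `dir`.
#' @export
make_fixtures <- function(spec, dir, config = default_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  th <- make_mini_mesh(spec)
  cda <- make_cda_set(spec, th, config)
  corpus <- make_corpus(spec, th,
                        favored = unique(unlist(lapply(cda$key, `[[`,
                                                       "planted"))))
  save_mesh_tsv(th, file.path(dir, "mesh.tsv"))
  save_config(config, file.path(dir, "config.xml"))
  for (doc in cda$docs) {
    write_cda(doc, file.path(dir, paste0(doc$doc_id, ".xml")))
  }
  write_gold_tsv(cda$gold, file.path(dir, "gold.tsv"))
  write_corpus_tsv(corpus, file.path(dir, "corpus.tsv"))
  jsonlite::write_json(cda$key, file.path(dir, "key.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(c(cda, list(thesaurus = th, corpus = corpus, dir = dir)))
}
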