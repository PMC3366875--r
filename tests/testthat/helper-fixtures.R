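# Shared fixtures and independent oracles.

# Hand-built thesaurus over real MeSH descriptors used in examples.
toy_thesaurus <- function() {
  mesh_thesaurus(list(
    mesh_descriptor("D001249", "Asthma", c("Bronchial Asthma"),
                    "C08.127.108", c("EP", "DI")),
    mesh_descriptor("D006973", "Hypertension", c("High Blood Pressure"),
                    "C14.907.489", c("EP", "TH")),
    mesh_descriptor("D003922", "Diabetes Mellitus, Type 1",
                    c("Insulin-Dependent Diabetes Mellitus"),
                    "C18.452.394.750.124", c("EP", "DI", "DT")),
    mesh_descriptor("D010146", "Pain", character(), "C23.888.592.612",
                    c("DI", "DT")),
    mesh_descriptor("D010406", "Penicillins", c("Penicillin"),
                    "D02.065.589.099.750", c("AE", "TU")),
    mesh_descriptor("D005190", "Family History", character(), "E05.318",
                    character())
  ))
}

# Minimal CDA XML string with configurable sections.
toy_cda_xml <- function(path, sections = list(
  list(title = "Allergies", code = "48765-2",
       text = "No penicillin allergy."))) {
  doc <- cda_document(doc_id = "toy", title = "Toy document",
                      sections = lapply(seq_along(sections), function(i) {
    s <- sections[[i]]
    cda_section(title = s$title,
                codes = if (!is.null(s$code)) {
                  data.frame(system = "LOINC", code = s$code,
                             stringsAsFactors = FALSE)
                },
                text = s$text, order_index = i - 1L)
  }))
  write_cda(doc, path)
  path
}

# Independent brute-force matcher: enumerate every token window (n-gram)
# up to max_len whose endpoints are word tokens, normalize the raw span,
# look it up, intersect with `allowed`, then apply leftmost-longest
# non-overlapping pruning. Mirrors the stated matching contract without
# sharing the scanning code.
oracle_match_section <- function(text, thesaurus, allowed,
                                 max_len = thesaurus$max_term_tokens) {
  out <- data.frame(descriptor = character(), start = integer(),
                    end = integer(), stringsAsFactors = FALSE)
  sents <- split_sentences(text)
  for (k in seq_len(nrow(sents))) {
    toks <- tokenize(sents$text[k], offset = sents$start[k])
    n <- nrow(toks)
    cand <- data.frame(i = integer(), j = integer(), stringsAsFactors = FALSE)
    cand_ids <- list()
    for (i in seq_len(n)) {
      if (grepl("^[^[:alnum:]]+$", toks$text[i])) next
      for (j in i:min(n, i + max_len - 1L)) {
        if (grepl("^[^[:alnum:]]+$", toks$text[j])) next
        key <- normalize_term(substr(text, toks$start[i] + 1L, toks$end[j]))
        ids <- intersect(thesaurus$lookup[[key]], allowed)
        if (length(ids)) {
          cand <- rbind(cand, data.frame(i = i, j = j))
          cand_ids[[nrow(cand)]] <- sort(ids)
        }
      }
    }
    # leftmost-longest non-overlapping selection
    pos <- 1L
    while (pos <= n && nrow(cand)) {
      here <- which(cand$i == pos)
      if (length(here)) {
        pick <- here[which.max(cand$j[here])]
        out <- rbind(out, data.frame(
          descriptor = cand_ids[[pick]],
          start = toks$start[cand$i[pick]],
          end = toks$end[cand$j[pick]], stringsAsFactors = FALSE))
        pos <- cand$j[pick] + 1L
      } else {
        pos <- pos + 1L
      }
    }
  }
  out[order(out$start, out$descriptor), , drop = FALSE]
}

# Independent full-document oracle: section relevance, branch restriction
# and negation applied as separate filters around the n-gram matcher.
oracle_identify <- function(doc, thesaurus, config,
                            window = 3L, lexicon = negation_lexicon()) {
  res <- data.frame(descriptor = character(), section_index = integer(),
                    start = integer(), end = integer(), negated = logical(),
                    stringsAsFactors = FALSE)
  for (s in doc$sections) {
    rule <- resolve_section(s, config)
    if (is.null(rule)) next
    allowed <- descriptors_in_branches(thesaurus,
                                       effective_branches(rule, config))
    m <- oracle_match_section(s$text, thesaurus, allowed)
    if (!nrow(m)) next
    # negation filter, recomputed from scratch per match
    sents <- split_sentences(s$text)
    m$negated <- vapply(seq_len(nrow(m)), function(r) {
      k <- which(sents$start <= m$start[r] & sents$end >= m$end[r])[1]
      toks <- tokenize(sents$text[k], offset = sents$start[k])
      i <- which(toks$start == m$start[r])[1]
      if (is.na(i) || i <= 1L) return(FALSE)
      any(normalize_term(toks$text[max(1L, i - window):(i - 1L)]) %in% lexicon)
    }, NA)
    m$section_index <- s$order_index
    res <- rbind(res, m[, c("descriptor", "section_index", "start", "end",
                            "negated")])
  }
  res <- res[order(res$section_index, res$start, res$descriptor), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# Independent per-citation predicate evaluation for counts.
oracle_count <- function(corpus, query) {
  clauses <- c(query$clauses,
               list(list(id = query$disease$id, qualifiers = character())))
  sum(vapply(corpus$citations, function(cit) {
    for (cl in clauses) {
      if (!length(cl$qualifiers)) {
        if (!cl$id %in% cit$index$descriptor) return(FALSE)
      } else {
        for (q in cl$qualifiers) {
          ok <- any(cit$index$descriptor == cl$id &
                      !is.na(cit$index$qualifier) & cit$index$qualifier == q)
          if (!ok) return(FALSE)
        }
      }
    }
    TRUE
  }, NA))
}
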