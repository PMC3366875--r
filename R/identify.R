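# Dictionary-based MeSH keyword identification in CDA narratives:
# sentence split -> tokenize -> greedy longest-match lookup -> negation.

#' Default negation trigger lexicon
#'
#' Trigger words that, when found within the negation window immediately
#' before a match in the same sentence, flag the mention as negated
#' (e.g. "no Pain").
#'
#' @return character vector of normalized trigger tokens.
#' @export
negation_lexicon <- function() {
  c("no", "not", "denies", "denied", "without", "negative", "absent", "non")
}

#' Split text into sentence spans
#'
#' Sentences end at runs of `.`, `!` or `?` followed by whitespace or end of
#' text; a trailing fragment without a terminator is its own sentence. Spans
#' are 0-based half-open character offsets into `text`, trimmed of
#' surrounding whitespace.
#'
#' @param text a single character string.
#' @return data.frame with columns `text`, `start`, `end` (0-based half-open).
#' @export
split_sentences <- function(text) {
  empty <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[.!?]+(?=[[:space:]]|$)", text, perl = TRUE)[[1]]
  bounds <- if (m[1] == -1L) integer() else as.integer(m) + attr(m, "match.length") - 1L
  starts1 <- c(1L, bounds + 1L)          # 1-based candidate starts
  ends1 <- c(bounds, nchar(text))        # 1-based inclusive ends
  keep <- starts1 <= ends1
  starts1 <- starts1[keep]; ends1 <- ends1[keep]
  out <- empty
  for (k in seq_along(starts1)) {
    s <- starts1[k]; e <- ends1[k]
    while (s <= e && grepl("^[[:space:]]$", substr(text, s, s))) s <- s + 1L
    while (e >= s && grepl("^[[:space:]]$", substr(text, e, e))) e <- e - 1L
    if (s > e) next
    out <- rbind(out, data.frame(text = substr(text, s, e),
                                 start = s - 1L, end = e,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Tokenize a sentence into word and punctuation spans
#'
#' Word tokens are maximal alphanumeric runs; every other non-space character
#' is a single-character punctuation token. Punctuation tokens are emitted
#' (they count for negation-window distances) but never match MeSH terms.
#'
#' @param text sentence text.
#' @param offset 0-based offset of `text` within its section, added to spans.
#' @return data.frame with columns `text`, `start`, `end` (0-based half-open,
#'   relative to the section when `offset` is the sentence start).
#' @export
tokenize <- function(text, offset = 0L) {
  empty <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[[:alnum:]]+|[^[:alnum:][:space:]]", text)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(text = substring(text, starts, starts + lens - 1L),
             start = starts - 1L + offset,
             end = starts + lens - 1L + offset,
             stringsAsFactors = FALSE)
}

is_punct_token <- function(tok) grepl("^[^[:alnum:]]+$", tok)

#' Greedy longest-match dictionary lookup within one sentence
#'
#' At each token position, windows of `max_len` down to 1 tokens are tried;
#' the window's raw character span (from the section text) is normalized and
#' looked up in the thesaurus table. On a hit whose descriptor set intersects
#' `allowed`, one match per intersecting descriptor is emitted and scanning
#' advances past the window, so longer entry terms shadow their nested
#' sub-terms. Windows starting or ending on a punctuation token are skipped
#' (punctuation tokens never match terms). Matches never cross sentence
#' boundaries (tokens are one sentence's tokens).
#'
#' @param tokens token data.frame from [tokenize()] for a single sentence,
#'   with spans relative to `text`.
#' @param text the full section text the spans index into.
#' @param thesaurus a [mesh_thesaurus].
#' @param allowed descriptor ids eligible for matching (branch restriction).
#' @param max_len maximum window length in tokens; defaults to the longest
#'   entry term in the thesaurus.
#' @return data.frame with columns `descriptor`, `surface`, `start`, `end`,
#'   `token_index` (1-based index of the first token of the match).
#' @export
match_terms <- function(tokens, text, thesaurus, allowed,
                        max_len = thesaurus$max_term_tokens) {
  out <- data.frame(descriptor = character(), surface = character(),
                    start = integer(), end = integer(),
                    token_index = integer(), stringsAsFactors = FALSE)
  n <- nrow(tokens)
  i <- 1L
  while (i <= n) {
    if (is_punct_token(tokens$text[i])) { i <- i + 1L; next }
    advanced <- FALSE
    for (L in seq.int(min(max_len, n - i + 1L), 1L)) {
      j <- i + L - 1L
      if (is_punct_token(tokens$text[j])) next
      span_text <- substr(text, tokens$start[i] + 1L, tokens$end[j])
      ids <- thesaurus$lookup[[normalize_term(span_text)]]
      hit <- sort(intersect(ids, allowed))
      if (length(hit)) {
        out <- rbind(out, data.frame(
          descriptor = hit, surface = span_text,
          start = tokens$start[i], end = tokens$end[j],
          token_index = i, stringsAsFactors = FALSE))
        i <- j + 1L
        advanced <- TRUE
        break
      }
    }
    if (!advanced) i <- i + 1L
  }
  out
}

#' Is a match preceded by a negation trigger?
#'
#' True iff any of the `window` tokens immediately preceding the match,
#' within the same sentence, normalizes to a word of the negation lexicon.
#' A trigger farther back than `window` tokens does not negate (a documented
#' limitation for phrases like "No family history of asthma" at window 3).
#'
#' @param tokens the sentence's tokens (from [tokenize()]).
#' @param match one row of a [match_terms()] result (uses `token_index`).
#' @param window number of preceding tokens inspected (default 3).
#' @param lexicon negation trigger words, normalized.
#' @return logical flag.
#' @export
is_negated <- function(tokens, match, window = 3L,
                       lexicon = negation_lexicon()) {
  stopifnot(window >= 1L)
  i <- match$token_index[1]
  if (is.null(i) || is.na(i) || i <= 1L) return(FALSE)
  prev <- tokens$text[max(1L, i - window):(i - 1L)]
  any(normalize_term(prev) %in% lexicon)
}

new_keywords <- function() {
  kw <- data.frame(descriptor = character(), surface = character(),
                   section_index = integer(), start = integer(),
                   end = integer(), negated = logical(),
                   candidate_count = integer(), stringsAsFactors = FALSE)
  kw$candidate_qualifiers <- list()
  kw
}

#' Identify MeSH keywords in a CDA document
#'
#' For each section with a resolved relevance rule, restricts the dictionary
#' to the descriptors of the rule's effective branches, then runs sentence
#' splitting, tokenization, greedy longest matching and negation flagging.
#' Negated mentions are kept in the output (flagged) but are excluded from
#' query candidacy downstream. Candidate qualifiers are the intersection of
#' the descriptor's allowable qualifiers with the section rule's effective
#' qualifiers.
#'
#' @param doc a [cda_document].
#' @param thesaurus a [mesh_thesaurus].
#' @param config an [app_config]; sections without a rule contribute nothing.
#' @param window negation window in tokens.
#' @param lexicon negation trigger lexicon.
#' @return data.frame of class `identified_keywords` with columns
#'   `descriptor`, `surface`, `section_index` (0-based), `start`, `end`
#'   (0-based half-open offsets into the section text), `negated`,
#'   `candidate_count` (`NA` until [annotate_counts()]), and list column
#'   `candidate_qualifiers`; ordered by `(section_index, start, descriptor)`.
#' @export
identify_keywords <- function(doc, thesaurus, config = default_config(),
                              window = 3L, lexicon = negation_lexicon()) {
  out <- new_keywords()
  for (s in doc$sections) {
    rule <- resolve_section(s, config)
    if (is.null(rule)) next
    branches <- effective_branches(rule, config)
    allowed <- descriptors_in_branches(thesaurus, branches)
    eq <- effective_qualifiers(rule, thesaurus)
    out <- rbind(out, scan_section(s, thesaurus, allowed, eq, window, lexicon))
  }
  finish_keywords(out)
}

#' Baseline identification: every MeSH occurrence, everywhere
#'
#' No section relevance filter and all sixteen branches; negation flags are
#' computed but mentions are not excluded. Its concept set is a superset of
#' (or equal to) [identify_keywords()]'s for any configuration.
#'
#' @inheritParams identify_keywords
#' @return an `identified_keywords` data.frame (see [identify_keywords()]).
#' @export
identify_baseline <- function(doc, thesaurus, window = 3L,
                              lexicon = negation_lexicon()) {
  allowed <- descriptors_in_branches(thesaurus, mesh_branches())
  out <- new_keywords()
  for (s in doc$sections) {
    out <- rbind(out, scan_section(s, thesaurus, allowed,
                                   thesaurus$qualifier_inventory,
                                   window, lexicon))
  }
  finish_keywords(out)
}

scan_section <- function(section, thesaurus, allowed, eff_quals,
                         window, lexicon) {
  out <- new_keywords()
  sents <- split_sentences(section$text)
  for (k in seq_len(nrow(sents))) {
    toks <- tokenize(sents$text[k], offset = sents$start[k])
    m <- match_terms(toks, section$text, thesaurus, allowed)
    for (r in seq_len(nrow(m))) {
      aq <- thesaurus$descriptors[[m$descriptor[r]]]$qualifiers
      row <- data.frame(descriptor = m$descriptor[r], surface = m$surface[r],
                        section_index = section$order_index,
                        start = m$start[r], end = m$end[r],
                        negated = is_negated(toks, m[r, ], window, lexicon),
                        candidate_count = NA_integer_,
                        stringsAsFactors = FALSE)
      row$candidate_qualifiers <- list(sort(intersect(aq, eff_quals)))
      out <- rbind(out, row)
    }
  }
  out
}

finish_keywords <- function(kw) {
  kw <- kw[order(kw$section_index, kw$start, kw$descriptor), , drop = FALSE]
  rownames(kw) <- NULL
  class(kw) <- c("identified_keywords", "data.frame")
  kw
}

#' @export
print.identified_keywords <- function(x, ...) {
  cat(nrow(x), "identified keyword mention(s)\n")
  if (nrow(x)) {
    df <- data.frame(descriptor = x$descriptor, surface = x$surface,
                     section = x$section_index,
                     span = sprintf("%d-%d", x$start, x$end),
                     negated = x$negated,
                     qualifiers = vapply(x$candidate_qualifiers, paste,
                                         "", collapse = ","),
                     count = x$candidate_count)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}

#' Write identified keywords as standoff annotations
#'
#' TSV columns: doc_id, section_index, start, end, descriptor, negated.
#'
#' @param keywords an `identified_keywords` data.frame.
#' @param doc_id document identifier to stamp on every row.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_standoff <- function(keywords, doc_id, path) {
  df <- data.frame(doc_id = rep(doc_id, nrow(keywords)),
                   section_index = keywords$section_index,
                   start = keywords$start, end = keywords$end,
                   descriptor = keywords$descriptor,
                   negated = keywords$negated)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
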