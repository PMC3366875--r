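# HL7-CDA reading: section-structured documents with flattened narrative text.

LOINC_OID <- "2.16.840.1.113883.6.1"
SNOMED_OID <- "2.16.840.1.113883.6.96"

#' Construct a CDA section
#'
#' @param title section title.
#' @param codes data.frame with columns `system` (`"LOINC"` or `"SNOMED"`) and
#'   `code`, or `NULL`.
#' @param text narrative plain text (markup removed, whitespace-normalized).
#' @param order_index 0-based position within the document.
#' @return a list of class `cda_section`.
#' @export
cda_section <- function(title = "", codes = NULL, text = "", order_index = 0L) {
  if (is.null(codes)) {
    codes <- data.frame(system = character(), code = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(order_index >= 0L)
  if (nrow(codes) && any(!nzchar(codes$code))) stop("section code must be non-empty")
  structure(list(title = title, codes = codes,
                 text = squish(text), order_index = as.integer(order_index)),
            class = "cda_section")
}

#' Construct a CDA document
#'
#' @param doc_id document identifier.
#' @param title document title.
#' @param sections list of [cda_section] objects (re-indexed in order).
#' @return a list of class `cda_document`.
#' @export
cda_document <- function(doc_id = "", title = "", sections = list()) {
  for (i in seq_along(sections)) sections[[i]]$order_index <- i - 1L
  structure(list(doc_id = doc_id, title = title, sections = sections),
            class = "cda_document")
}

#' @export
print.cda_document <- function(x, ...) {
  cat("CDA document", sQuote(x$doc_id), "-", x$title, "\n")
  for (s in x$sections) {
    cat(sprintf("  [%d] %s (%d chars)\n", s$order_index, s$title, nchar(s$text)))
  }
  invisible(x)
}

squish <- function(x) {
  trimws(gsub("[[:space:]]+", " ", x))
}

code_system_name <- function(system_attr) {
  ifelse(system_attr %in% c(LOINC_OID, "LOINC"), "LOINC",
         ifelse(system_attr %in% c(SNOMED_OID, "SNOMED", "SNOMED-CT"),
                "SNOMED", NA_character_))
}

#' Parse an HL7-CDA XML document
#'
#' Accepts CDA R2 (`urn:hl7-org:v3`) as well as namespace-free XML using
#' `section`/`title`/`code`/`text` elements. Sections (including nested
#' sub-sections) are flattened depth-first in document order. Narrative text
#' is the concatenation of the text nodes of the section's `text` element in
#' document order, whitespace-normalized, with table cells separated by
#' spaces. Structured `entry` elements are ignored; only narrative is mined.
#'
#' @param xml path to a CDA XML file (or anything [xml2::read_xml()] accepts).
#' @param strict if `TRUE`, require a `ClinicalDocument` root element.
#' @return a [cda_document]; zero sections yields a warning.
#' @export
parse_cda <- function(xml, strict = FALSE) {
  doc <- tryCatch(xml2::read_xml(xml),
                  error = function(e) stop("CDA parse error: ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_name(xml2::xml_root(doc))
  if (strict && root != "ClinicalDocument") {
    stop("CDA parse error: root element is ", sQuote(root),
         ", expected ClinicalDocument")
  }
  doc_id <- xml2::xml_attr(xml2::xml_find_first(doc, "/*/id"), "extension")
  if (is.na(doc_id)) doc_id <- ""
  title <- xml2::xml_text(xml2::xml_find_first(doc, "/*/title"))
  if (is.na(title)) title <- ""

  secs <- xml2::xml_find_all(doc, ".//section")
  sections <- vector("list", length(secs))
  for (i in seq_along(secs)) {
    s <- secs[[i]]
    st <- xml2::xml_text(xml2::xml_find_first(s, "./title"))
    if (is.na(st)) st <- ""
    code_nodes <- xml2::xml_find_all(s, "./code")
    codes <- data.frame(
      system = code_system_name(xml2::xml_attr(code_nodes, "codeSystem")),
      code = xml2::xml_attr(code_nodes, "code"),
      stringsAsFactors = FALSE
    )
    sys_attr <- xml2::xml_attr(code_nodes, "system")
    codes$system[is.na(codes$system)] <- code_system_name(sys_attr)[is.na(codes$system)]
    codes <- codes[!is.na(codes$system) & !is.na(codes$code), , drop = FALSE]
    narr <- xml2::xml_find_first(s, "./text")
    txt <- ""
    if (!inherits(narr, "xml_missing")) {
      # exclude text belonging to nested sections inside the narrative block
      nodes <- xml2::xml_find_all(narr, ".//text()[not(ancestor::section[ancestor::text])]")
      txt <- paste(xml2::xml_text(nodes), collapse = " ")
    }
    sections[[i]] <- cda_section(title = squish(st), codes = codes,
                                 text = txt, order_index = i - 1L)
  }
  if (!length(sections)) warning("CDA document contains no sections")
  cda_document(doc_id = doc_id, title = squish(title), sections = sections)
}

#' Validate a CDA file without throwing
#'
#' Checks that the input is well-formed XML, has a `ClinicalDocument` root and
#' contains at least one section with narrative text. Findings are returned,
#' never thrown; an empty report means the document passed all three checks.
#'
#' @param xml path to the candidate file.
#' @return data.frame with columns `level` (`"error"`/`"warning"`), `message`,
#'   `location`; zero rows if valid.
#' @export
validate_cda <- function(xml) {
  finding <- function(level, message, location = "") {
    data.frame(level = level, message = message, location = location,
               stringsAsFactors = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(xml), error = function(e) e)
  if (inherits(doc, "error")) {
    return(finding("error", paste("not well-formed XML:",
                                  conditionMessage(doc)), "document"))
  }
  xml2::xml_ns_strip(doc)
  report <- finding(character(), character(), character())
  root <- xml2::xml_name(xml2::xml_root(doc))
  if (root != "ClinicalDocument") {
    report <- rbind(report, finding(
      "error", paste0("root element is '", root, "', not ClinicalDocument"),
      "/"))
  }
  secs <- xml2::xml_find_all(doc, ".//section")
  if (!length(secs)) {
    report <- rbind(report, finding("warning", "document has no sections",
                                    "structuredBody"))
  } else {
    texts <- vapply(secs, function(s) {
      n <- xml2::xml_find_first(s, "./text")
      if (inherits(n, "xml_missing")) "" else squish(xml2::xml_text(n))
    }, "")
    if (!any(nzchar(texts))) {
      report <- rbind(report, finding(
        "warning", "no section contains narrative text", "section"))
    }
  }
  report
}

#' Serialize a CDA document to XML
#'
#' Fixture serializer (used by the synthetic-data generators): writes a
#' namespace-free `ClinicalDocument` with one
#' `component/structuredBody/component/section` per section. Round-trips
#' through [parse_cda()] for whitespace-normalized narratives.
#'
#' @param doc a [cda_document].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cda <- function(doc, path) {
  root <- xml2::xml_new_root("ClinicalDocument")
  idn <- xml2::xml_add_child(root, "id")
  xml2::xml_set_attr(idn, "extension", doc$doc_id)
  xml2::xml_add_child(root, "title", doc$title)
  body <- xml2::xml_add_child(xml2::xml_add_child(root, "component"),
                              "structuredBody")
  for (s in doc$sections) {
    sec <- xml2::xml_add_child(xml2::xml_add_child(body, "component"),
                               "section")
    for (i in seq_len(nrow(s$codes))) {
      cn <- xml2::xml_add_child(sec, "code")
      xml2::xml_set_attr(cn, "code", s$codes$code[i])
      xml2::xml_set_attr(cn, "codeSystem",
                         if (s$codes$system[i] == "LOINC") LOINC_OID else SNOMED_OID)
    }
    xml2::xml_add_child(sec, "title", s$title)
    xml2::xml_add_child(sec, "text", s$text)
  }
  xml2::write_xml(root, path)
  invisible(path)
}
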