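# MeSH thesaurus model: descriptors, entry-term lookup table, branch index.

#' The sixteen top-level MeSH tree branches
#'
#' Letters identifying the top-level branches of the MeSH tree (e.g. `C` =
#' Diseases, `D` = Chemicals and Drugs, `Z` = Geographic Locations).
#'
#' @return A character vector of 16 single letters.
#' @export
mesh_branches <- function() {
  c("A", "B", "C", "D", "E", "F", "G", "H",
    "I", "J", "K", "L", "M", "N", "V", "Z")
}

#' Normalize a surface form for dictionary lookup
#'
#' Case-folds, collapses internal whitespace to single spaces and strips
#' leading/trailing punctuation and whitespace. Idempotent and deterministic;
#' no stemming (MeSH entry terms already enumerate lexical variants).
#'
#' @param x character vector of surface forms.
#' @return character vector of normalized lookup keys.
#' @examples
#' normalize_term("Bronchial  Asthma,")  # "bronchial asthma"
#' @export
normalize_term <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("^[[:punct:][:space:]]+", "", x)
  x <- gsub("[[:punct:][:space:]]+$", "", x)
  x
}

# Official MeSH subheading abbreviation -> full name (common subset).
# Unknown abbreviations fall back to the lowercased abbreviation.
MESH_QUALIFIER_NAMES <- c(
  AB = "abnormalities", AD = "administration & dosage", AE = "adverse effects",
  AN = "analysis", BL = "blood", CH = "chemistry", CL = "classification",
  CO = "complications", CN = "congenital", DG = "diagnostic imaging",
  DI = "diagnosis", DH = "diet therapy", DE = "drug effects",
  DT = "drug therapy", EC = "economics", EM = "embryology",
  EN = "enzymology", EP = "epidemiology", ET = "etiology", GE = "genetics",
  HI = "history", IM = "immunology", IN = "injuries", ME = "metabolism",
  MI = "microbiology", MO = "mortality", NU = "nursing", PS = "parasitology",
  PA = "pathology", PK = "pharmacokinetics", PD = "pharmacology",
  PH = "physiology", PP = "physiopathology", PC = "prevention & control",
  PX = "psychology", RT = "radiotherapy", RH = "rehabilitation",
  SU = "surgery", TU = "therapeutic use", TH = "therapy", TO = "toxicity",
  TM = "transmission", UR = "urine", VE = "veterinary", VI = "virology"
)

#' Resolve a qualifier abbreviation to its full subheading name
#'
#' @param abbrev character vector of two-letter qualifier abbreviations.
#' @param thesaurus optional [mesh_thesaurus] whose qualifier name table
#'   (e.g. loaded from NLM XML) takes precedence over the built-in table.
#' @return character vector of full names (lowercased abbreviation if unknown).
#' @export
qualifier_name <- function(abbrev, thesaurus = NULL) {
  out <- rep(NA_character_, length(abbrev))
  if (!is.null(thesaurus) && length(thesaurus$qualifier_names)) {
    hit <- abbrev %in% names(thesaurus$qualifier_names)
    out[hit] <- unname(thesaurus$qualifier_names[abbrev[hit]])
  }
  miss <- is.na(out) & abbrev %in% names(MESH_QUALIFIER_NAMES)
  out[miss] <- unname(MESH_QUALIFIER_NAMES[abbrev[miss]])
  out[is.na(out)] <- tolower(abbrev[is.na(out)])
  out
}

#' Construct a MeSH descriptor record
#'
#' @param id descriptor UI (e.g. `"D001249"`).
#' @param preferred_name the main heading.
#' @param entry_terms synonyms; the preferred name is added if absent.
#' @param tree_numbers dot-separated tree codes (e.g. `"C08.127.108"`); the
#'   leading letter must be one of the 16 branches.
#' @param qualifiers allowable qualifier abbreviations (uppercase, 2 chars).
#' @return a list of class `mesh_descriptor`.
#' @export
mesh_descriptor <- function(id, preferred_name, entry_terms = character(),
                            tree_numbers = character(),
                            qualifiers = character()) {
  if (!nzchar(id)) stop("descriptor id must be non-empty")
  if (!nzchar(preferred_name)) stop("preferred_name must be non-empty")
  entry_terms <- unique(c(preferred_name, as.character(entry_terms)))
  tree_numbers <- unique(as.character(tree_numbers))
  bad <- tree_numbers[!substr(tree_numbers, 1, 1) %in% mesh_branches()]
  if (length(bad)) {
    stop("invalid tree number(s) for ", id, ": ", paste(bad, collapse = ", "))
  }
  qualifiers <- unique(toupper(as.character(qualifiers)))
  if (length(qualifiers) && any(nchar(qualifiers) != 2L)) {
    stop("qualifier abbreviations must be 2 characters: ", id)
  }
  structure(
    list(id = id, preferred_name = preferred_name, entry_terms = entry_terms,
         tree_numbers = tree_numbers, qualifiers = qualifiers),
    class = "mesh_descriptor"
  )
}

#' Compile descriptors into a thesaurus with a normalized lookup table
#'
#' Builds the fast lookup structures used by keyword identification: a
#' normalized surface-form -> descriptor-id table over every entry term, a
#' branch-letter index over tree numbers, the longest entry-term length in
#' tokens, and the qualifier inventory (union over descriptors).
#'
#' @param descriptors list of [mesh_descriptor] records.
#' @param qualifier_names optional named character vector mapping qualifier
#'   abbreviations to full subheading names.
#' @return an object of class `mesh_thesaurus`.
#' @export
mesh_thesaurus <- function(descriptors = list(), qualifier_names = character()) {
  ids <- vapply(descriptors, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate descriptor id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(descriptors) <- ids

  lookup <- list()
  branch_index <- stats::setNames(
    rep(list(character()), length(mesh_branches())), mesh_branches())
  max_tok <- 1L
  for (d in descriptors) {
    for (e in d$entry_terms) {
      key <- normalize_term(e)
      if (!nzchar(key)) next
      lookup[[key]] <- unique(c(lookup[[key]], d$id))
      max_tok <- max(max_tok, nrow(tokenize(e)))
    }
    for (b in unique(substr(d$tree_numbers, 1, 1))) {
      branch_index[[b]] <- c(branch_index[[b]], d$id)
    }
  }
  structure(
    list(descriptors = descriptors, lookup = lookup,
         branch_index = branch_index, max_term_tokens = max_tok,
         qualifier_inventory = sort(unique(unlist(
           lapply(descriptors, `[[`, "qualifiers")))),
         qualifier_names = qualifier_names),
    class = "mesh_thesaurus"
  )
}

#' @export
print.mesh_thesaurus <- function(x, ...) {
  cat("MeSH thesaurus:", length(x$descriptors), "descriptors,",
      length(x$lookup), "entry-term keys,",
      "max term length", x$max_term_tokens, "tokens\n")
  inv <- x$qualifier_inventory
  if (length(inv)) cat("qualifier inventory:", paste(inv, collapse = " "), "\n")
  invisible(x)
}

#' Load a MeSH thesaurus
#'
#' Two dialects are supported: `"fixture-tsv"`, the package's compact
#' tab-separated dialect (columns: id, preferred name, pipe-joined entry
#' terms, pipe-joined tree numbers, pipe-joined qualifier abbreviations; no
#' header), and `"mesh-xml"`, the official NLM descriptor XML
#' (`DescriptorRecordSet`).
#'
#' @param source path to the file.
#' @param dialect `"fixture-tsv"` or `"mesh-xml"`.
#' @return a [mesh_thesaurus].
#' @export
load_mesh <- function(source, dialect = c("fixture-tsv", "mesh-xml")) {
  dialect <- match.arg(dialect)
  if (dialect == "fixture-tsv") load_mesh_tsv(source) else load_mesh_xml(source)
}

load_mesh_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  descs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L || length(f) > 5L) {
      stop("malformed fixture-tsv at line ", i, ": expected 2-5 fields, got ",
           length(f))
    }
    f <- c(f, rep("", 5L - length(f)))
    split_pipe <- function(s) if (nzchar(s)) strsplit(s, "|", fixed = TRUE)[[1]] else character()
    descs[[i]] <- tryCatch(
      mesh_descriptor(f[1], f[2], split_pipe(f[3]), split_pipe(f[4]),
                      split_pipe(f[5])),
      error = function(e) stop("fixture-tsv line ", i, ": ", conditionMessage(e))
    )
  }
  mesh_thesaurus(descs)
}

load_mesh_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed MeSH XML: ",
                                           conditionMessage(e)))
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  qual_names <- character()
  descs <- lapply(recs, function(r) {
    id <- xml2::xml_text(xml2::xml_find_first(r, "./DescriptorUI"))
    name <- xml2::xml_text(xml2::xml_find_first(r, "./DescriptorName/String"))
    terms <- xml2::xml_text(xml2::xml_find_all(r, ".//TermList/Term/String"))
    trees <- xml2::xml_text(xml2::xml_find_all(
      r, "./TreeNumberList/TreeNumber"))
    quals <- xml2::xml_find_all(r, ".//AllowableQualifier")
    ab <- toupper(trimws(xml2::xml_text(
      xml2::xml_find_all(quals, "./Abbreviation"))))
    qn <- xml2::xml_text(xml2::xml_find_all(
      quals, "./QualifierReferredTo/QualifierName/String"))
    if (length(ab) && length(ab) == length(qn)) {
      qual_names[ab] <<- qn
    }
    if (is.na(id) || is.na(name)) {
      stop("malformed MeSH XML: DescriptorRecord missing DescriptorUI or name")
    }
    mesh_descriptor(id, name, terms, trees, ab)
  })
  mesh_thesaurus(descs, qualifier_names = qual_names)
}

#' Write a thesaurus in the fixture TSV dialect
#'
#' Inverse of `load_mesh(..., dialect = "fixture-tsv")`: UTF-8, tab-separated,
#' pipe-joined multi-values, no header.
#'
#' @param thesaurus a [mesh_thesaurus].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_mesh_tsv <- function(thesaurus, path) {
  rows <- vapply(thesaurus$descriptors, function(d) {
    paste(d$id, d$preferred_name,
          paste(d$entry_terms, collapse = "|"),
          paste(d$tree_numbers, collapse = "|"),
          paste(d$qualifiers, collapse = "|"),
          sep = "\t")
  }, "")
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Descriptors located in a set of MeSH branches
#'
#' A descriptor is included iff at least one of its tree numbers starts with
#' one of the given branch letters.
#'
#' @param thesaurus a [mesh_thesaurus].
#' @param branches character vector of branch letters (subset of
#'   [mesh_branches()]).
#' @return sorted character vector of descriptor ids.
#' @export
descriptors_in_branches <- function(thesaurus, branches) {
  branches <- unique(as.character(branches))
  bad <- setdiff(branches, mesh_branches())
  if (length(bad)) {
    stop("invalid branch letter(s): ", paste(bad, collapse = ", "))
  }
  sort(unique(unlist(thesaurus$branch_index[branches], use.names = FALSE)))
}

#' Allowable qualifiers of a descriptor
#'
#' @param thesaurus a [mesh_thesaurus].
#' @param id a descriptor id present in the thesaurus.
#' @return data.frame with columns `abbreviation` and `name` (possibly 0 rows).
#' @export
allowable_qualifiers_for <- function(thesaurus, id) {
  d <- thesaurus$descriptors[[id]]
  if (is.null(d)) stop("unknown descriptor id: ", id)
  ab <- d$qualifiers
  data.frame(abbreviation = ab, name = qualifier_name(ab, thesaurus),
             stringsAsFactors = FALSE)
}
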