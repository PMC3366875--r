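# Identification configuration: relevant sections, branch and qualifier rules.

#' Construct a section relevance rule
#'
#' A rule matches a CDA section either by code equality or by normalized title
#' membership. Empty `branches`/`qualifiers` mean "unset": the configuration
#' default branches, respectively the full thesaurus qualifier inventory,
#' apply (see [effective_branches()], [effective_qualifiers()]).
#'
#' @param titles section title plus synonym titles.
#' @param codes data.frame with columns `system`, `code`, or `NULL`.
#' @param branches branch letters restricting identification in this section.
#' @param qualifiers qualifier abbreviations admissible in this section.
#' @return a list of class `section_rule`.
#' @export
section_rule <- function(titles = character(), codes = NULL,
                         branches = character(), qualifiers = character()) {
  if (is.null(codes)) {
    codes <- data.frame(system = character(), code = character(),
                        stringsAsFactors = FALSE)
  }
  titles <- as.character(titles)
  if (!length(titles) && !nrow(codes)) {
    stop("a section rule needs at least one title or code")
  }
  branches <- unique(as.character(branches))
  bad <- setdiff(branches, mesh_branches())
  if (length(bad)) stop("invalid branch letter(s): ", paste(bad, collapse = ", "))
  structure(list(titles = titles, codes = codes, branches = branches,
                 qualifiers = unique(toupper(as.character(qualifiers)))),
            class = "section_rule")
}

#' Construct an identification configuration
#'
#' @param rules ordered list of [section_rule] objects.
#' @param default_branches_when_unset branches applied to a matched rule whose
#'   own branch set is unset; defaults to the nine branches A-G
#'   (Anatomy through Biological Sciences), N (Health Care) and Z (Geographic
#'   Locations).
#' @param disease_branch branch the query disease must come from (`"C"`,
#'   Diseases, by default).
#' @return a list of class `app_config`.
#' @export
app_config <- function(rules = list(),
                       default_branches_when_unset = c("A", "B", "C", "D",
                                                       "E", "F", "G", "N", "Z"),
                       disease_branch = "C") {
  default_branches_when_unset <- unique(as.character(default_branches_when_unset))
  bad <- setdiff(c(default_branches_when_unset, disease_branch), mesh_branches())
  if (length(bad)) stop("invalid branch letter(s): ", paste(bad, collapse = ", "))
  structure(list(rules = rules,
                 default_branches_when_unset = default_branches_when_unset,
                 disease_branch = disease_branch),
            class = "app_config")
}

#' @export
print.app_config <- function(x, ...) {
  cat("identification config:", length(x$rules), "section rules;",
      "default branches", paste(x$default_branches_when_unset, collapse = ""),
      "; disease branch", x$disease_branch, "\n")
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    cat(sprintf("  %d. %s [%s]%s\n", i, paste(r$titles, collapse = " / "),
                if (length(r$branches)) paste(r$branches, collapse = "") else "unset",
                if (nrow(r$codes)) paste0(" codes: ", paste(r$codes$system,
                                                            r$codes$code,
                                                            collapse = ", ")) else ""))
  }
  invisible(x)
}

#' The shipped default configuration
#'
#' Rules for the common narrative EHR sections, each restricted to MeSH
#' branches A-G (the balanced precision/recall choice); sections like
#' Appointment or Chief Complaint carry no rule and are skipped.
#'
#' @return an [app_config].
#' @export
default_config <- function() {
  ag <- c("A", "B", "C", "D", "E", "F", "G")
  loinc <- function(code) data.frame(system = "LOINC", code = code,
                                     stringsAsFactors = FALSE)
  app_config(rules = list(
    section_rule(c("History of Present Illness", "Present Illness"),
                 loinc("10164-2"), branches = ag),
    section_rule(c("Allergies", "Allergies and Adverse Reactions"),
                 loinc("48765-2"), branches = ag),
    section_rule(c("Family History", "Family Diseases"),
                 loinc("10157-6"), branches = ag),
    section_rule(c("Medications", "Current Medications"),
                 loinc("10160-0"), branches = ag),
    section_rule(c("Problems", "Problem List"),
                 loinc("11450-4"), branches = ag),
    section_rule(c("Past Medical History"),
                 loinc("11348-0"), branches = ag)
  ))
}

#' Load / save a configuration XML file
#'
#' Schema:
#' `<config disease-branch="C" default-branches="ABCDEFGNZ">` containing one
#' `<section>` per rule with `<title>` elements, `<code system="LOINC"
#' value="..."/>` elements, an optional `<branches>` letter string and an
#' optional `<qualifiers>` space-separated abbreviation list.
#' `save_config()` and `load_config()` are mutually inverse.
#'
#' @param xml path to a configuration XML file.
#' @return an [app_config].
#' @export
load_config <- function(xml) {
  doc <- tryCatch(xml2::read_xml(xml),
                  error = function(e) stop("config parse error: ",
                                           conditionMessage(e)))
  root <- xml2::xml_root(doc)
  db <- xml2::xml_attr(root, "default-branches")
  dz <- xml2::xml_attr(root, "disease-branch")
  secs <- xml2::xml_find_all(root, "./section")
  rules <- vector("list", length(secs))
  for (i in seq_along(secs)) {
    s <- secs[[i]]
    titles <- xml2::xml_text(xml2::xml_find_all(s, "./title"))
    cn <- xml2::xml_find_all(s, "./code")
    codes <- data.frame(system = xml2::xml_attr(cn, "system"),
                        code = xml2::xml_attr(cn, "value"),
                        stringsAsFactors = FALSE)
    br <- xml2::xml_text(xml2::xml_find_first(s, "./branches"))
    qu <- xml2::xml_text(xml2::xml_find_first(s, "./qualifiers"))
    rules[[i]] <- tryCatch(
      section_rule(
        titles = titles, codes = codes,
        branches = if (is.na(br)) character() else strsplit(trimws(br), "")[[1]],
        qualifiers = if (is.na(qu)) character() else strsplit(trimws(qu), "[ |]+")[[1]]),
      error = function(e) stop("config rule ", i, ": ", conditionMessage(e)))
  }
  app_config(
    rules = rules,
    default_branches_when_unset =
      if (is.na(db)) c("A", "B", "C", "D", "E", "F", "G", "N", "Z")
      else strsplit(db, "")[[1]],
    disease_branch = if (is.na(dz)) "C" else dz
  )
}

#' @rdname load_config
#' @param config an [app_config].
#' @param path output path for `save_config()`.
#' @export
save_config <- function(config, path) {
  root <- xml2::xml_new_root("config")
  xml2::xml_set_attr(root, "default-branches",
                     paste(config$default_branches_when_unset, collapse = ""))
  xml2::xml_set_attr(root, "disease-branch", config$disease_branch)
  for (r in config$rules) {
    s <- xml2::xml_add_child(root, "section")
    for (t in r$titles) xml2::xml_add_child(s, "title", t)
    for (i in seq_len(nrow(r$codes))) {
      cn <- xml2::xml_add_child(s, "code")
      xml2::xml_set_attr(cn, "system", r$codes$system[i])
      xml2::xml_set_attr(cn, "value", r$codes$code[i])
    }
    if (length(r$branches)) {
      xml2::xml_add_child(s, "branches", paste(r$branches, collapse = ""))
    }
    if (length(r$qualifiers)) {
      xml2::xml_add_child(s, "qualifiers", paste(r$qualifiers, collapse = " "))
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Resolve the rule governing a CDA section
#'
#' Code equality takes precedence over title matching: the first rule (in
#' configuration order) sharing a `(system, code)` pair with the section wins;
#' failing that, the first rule whose title set contains the section title
#' under [normalize_term()]. `NULL` means the section is irrelevant and is
#' skipped by identification.
#'
#' @param section a [cda_section].
#' @param config an [app_config].
#' @return the matching [section_rule] (with attribute `rule_index`) or `NULL`.
#' @export
resolve_section <- function(section, config) {
  sec_codes <- section$codes
  if (nrow(sec_codes)) {
    sec_keys <- paste(sec_codes$system, sec_codes$code)
    for (i in seq_along(config$rules)) {
      r <- config$rules[[i]]
      if (nrow(r$codes) &&
          any(paste(r$codes$system, r$codes$code) %in% sec_keys)) {
        attr(r, "rule_index") <- i
        return(r)
      }
    }
  }
  key <- normalize_term(section$title)
  for (i in seq_along(config$rules)) {
    r <- config$rules[[i]]
    if (key %in% normalize_term(r$titles)) {
      attr(r, "rule_index") <- i
      return(r)
    }
  }
  NULL
}

#' Branches and qualifiers effectively applying to a matched rule
#'
#' An unset rule branch set resolves to the configuration's
#' `default_branches_when_unset` (nine branches A-G, N, Z by default); an
#' unset qualifier set resolves to the full thesaurus qualifier inventory.
#'
#' @param rule a [section_rule].
#' @param config an [app_config].
#' @return character vector of branch letters (never empty for a matched rule).
#' @export
effective_branches <- function(rule, config) {
  if (length(rule$branches)) rule$branches else config$default_branches_when_unset
}

#' @rdname effective_branches
#' @param thesaurus a [mesh_thesaurus].
#' @export
effective_qualifiers <- function(rule, thesaurus) {
  if (length(rule$qualifiers)) rule$qualifiers else thesaurus$qualifier_inventory
}
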