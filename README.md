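# ehrlit

Patient-specific literature retrieval from electronic health records.
`ehrlit` identifies Medical Subject Headings (MeSH) concepts in the
narrative sections of HL7-CDA clinical documents and iteratively builds
conjunctive PubMed-style queries that retrieve the citations sharing the
most MeSH descriptors with the record.

It is aimed at biomedical-informatics developers and researchers who need
the core of an EHR-driven retrieval pipeline as a scriptable, offline-
testable library: clinical NLP groups evaluating dictionary-based concept
recognition, and anyone building "find me the literature for *this*
patient" tooling on top of MEDLINE's MeSH indexing.

## The method

**Identification.** A MeSH thesaurus (official NLM XML or a compact TSV
dialect) is compiled into a normalized surface-form lookup table. For each
document section that a configuration declares relevant (matched by
LOINC/SNOMED code, then by title), the text is split into sentences and
tokens, and a greedy longest-match scan finds entry terms among the
descriptors of the section's MeSH tree branches. Unset branches default to
the nine branches A–G, N, Z (of the sixteen-branch MeSH tree); the shipped
rules use A–G, the balanced precision/recall choice. Mentions preceded by a
negation trigger (`no`, `denies`, `without`, ...) within a 3-token window
are flagged and excluded from query candidacy.

**Query building.** Selected keywords form the n-th query

```
(term_1[mh]) AND (term_2[mh]) AND ... AND (term_n[mh]) AND (disease[mh])
```

optionally with subheadings (`Diabetes Mellitus/epidemiology[mh]`) when the
qualifier is admissible for both the descriptor and the originating
section. With the relatedness degree

```
Rel(pub) = | MeSH(pub) ∩ ( MeSH(ehr) ∪ {disease} ) |
```

every citation retrieved by the n-th query has Rel ≥ n + 1, so each
iteration strictly focuses the result set. A deterministic local backend
implements these semantics exactly over an in-memory corpus (and serves as
the test oracle target); an optional NCBI E-utilities client (cached,
rate-limited, 1,000 queries/minute default) provides live counts.

**Evaluation.** Descriptor-level precision/recall against gold annotations
(macro or micro averaged), branch-configuration sweeps including an
everything-everywhere baseline, and citation-reduction trajectories across
query iterations.

**Synthetic data.** Seeded generators produce mini-MeSH thesauri, CDA
documents with planted/negated/distractor mentions plus gold annotations,
and MeSH-indexed corpora — with full bookkeeping, so expected confusion
counts and every query count are computable in advance and the pipeline is
tested for *exact* recovery.

## Worked example

```r
library(ehrlit)

th <- mesh_thesaurus(list(
  mesh_descriptor("D001249", "Asthma", "Bronchial Asthma",
                  "C08.127.108", c("EP", "DI")),
  mesh_descriptor("D006973", "Hypertension", "High Blood Pressure",
                  "C14.907.489", c("EP", "TH")),
  mesh_descriptor("D003922", "Diabetes Mellitus, Type 1",
                  "Insulin-Dependent Diabetes Mellitus",
                  "C18.452.394.750.124", c("EP", "DI", "DT")),
  mesh_descriptor("D010146", "Pain", character(),
                  "C23.888.592.612", c("DI", "DT"))))

doc <- cda_document("example", "Progress note", list(
  cda_section("History of Present Illness",
              data.frame(system = "LOINC", code = "10164-2"),
              "Known bronchial asthma and Hypertension. No Pain today.", 0L)))

identify_keywords(doc, th)
#> 3 identified keyword mention(s)
#>  descriptor          surface section  span negated qualifiers count
#>     D001249 bronchial asthma       0  6-22   FALSE      DI,EP    NA
#>     D006973     Hypertension       0 27-39   FALSE      EP,TH    NA
#>     D010146             Pain       0 44-48    TRUE      DI,DT    NA
```

The synonym *bronchial asthma* resolved to the Asthma descriptor; *Pain* was
found but flagged negated, so it cannot enter a query. Building the
two-keyword query for the disease *Diabetes Mellitus, Type 1*:

```r
q <- add_term(initial_query(th, "D003922", "D001249"), th, "D006973")
render_query(q)
#> [1] "(Asthma[mh]) AND (Hypertension[mh]) AND (Diabetes Mellitus, Type 1[mh])"
```

— a conjunction of three MeSH keywords (two from the record plus the
disease). Running the iterative refinement against a local corpus built to
carry a realistic citation decay:

```r
corpus <- make_curve_corpus(th, "D003922", c("D001249", "D006973"),
                            c(53137L, 1200L, 6L))
reduction_curve(doc, th, default_config(), "D003922",
                local_backend(corpus),
                policy = "scripted", terms = c("D001249", "D006973"))
#>   iteration                                                                   query count
#> 1         0                                         (Diabetes Mellitus, Type 1[mh]) 53137
#> 2         1                        (Asthma[mh]) AND (Diabetes Mellitus, Type 1[mh])  1200
#> 3         2 (Asthma[mh]) AND (Hypertension[mh]) AND (Diabetes Mellitus, Type 1[mh])     6
```

The disease-only general query returns 53,137 citations; two EHR keywords
cut it to 6, each of which shares at least 3 MeSH descriptors with the
record.

A command-line wrapper with the same functionality is installed as
`exec/ehrlit` (subcommands `identify`, `query`, `evaluate`, `curve`,
`make-fixtures`).

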