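---
title: "MeSH keyword identification in CDA records and iterative query building"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MeSH keyword identification in CDA records and iterative query building}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrlit)
```

## The problem

A clinician reading an electronic health record often wants the literature
that is specific to *this* patient: not everything indexed under the disease,
but the citations that share as many of the patient's documented features as
possible. `ehrlit` automates the two halves of that workflow:

1. **Keyword identification.** Find Medical Subject Headings (MeSH) concepts
   in the narrative sections of an HL7-CDA document, restricted to the
   sections and MeSH tree branches a configuration declares relevant, and
   flag negated mentions ("no pain").
2. **Query building.** Turn selected keywords into a conjunctive PubMed-style
   query, `(term1[mh]) AND ... AND (termN[mh]) AND (disease[mh])`, and
   iterate: each added keyword restricts the retrieved set further, so the
   n-th query only returns citations sharing at least n + 1 MeSH descriptors
   with the record.

The relatedness degree driving this is

    Rel(citation) = | MeSH(citation) ∩ ( MeSH(record) ∪ {disease} ) |

i.e. the number of indexing descriptors a citation shares with the union of
record-derived terms and the chosen disease. On the package's local backend
(which implements the clause semantics exactly, without tree explosion) the
n + 1 bound holds as a theorem and is enforced by tests.

## The identification procedure

For each section of a parsed document:

* **Section relevance.** `resolve_section()` matches the section against the
  configuration's rules — by LOINC/SNOMED code equality first, then by
  normalized title. Code matching wins because codes are less ambiguous than
  titles; ties among rules go to the first rule in configuration order.
  Sections without a rule (e.g. *Appointment*) contribute nothing.
* **Branch restriction.** The rule's branches (or, when unset, the
  configuration default of the nine branches A–G, N, Z) select the eligible
  descriptors via their tree numbers. This is what makes *Penicillin* in an
  *Allergies* section behave differently from the same token elsewhere: a
  drug descriptor living only in branch D is invisible to a C-restricted
  scan.
* **Matching.** Text is split into sentences and tokens (maximal
  alphanumeric runs; punctuation as single-character tokens that never match
  terms). At each position the matcher tries windows from the longest entry
  term in the thesaurus down to one token, normalizes the window's raw
  character span (case fold, whitespace collapse, edge-punctuation strip —
  no stemming, since MeSH entry terms already enumerate variants) and looks
  it up in the precompiled surface-form table. The first (longest) hit whose
  descriptors intersect the allowed set is emitted and scanning continues
  after the window, so "Diabetes Mellitus, Type 1" shadows its nested
  "Diabetes Mellitus". Ambiguous surface forms yield one match per candidate
  descriptor.
* **Negation.** A match is flagged negated when one of the `window = 3`
  tokens immediately before it in the same sentence is a trigger word
  (`no, not, denies, denied, without, negative, absent, non`). Both lexicon
  and window are arguments. The window is deliberately local: in "No family
  history of asthma" the trigger is four tokens back, so *asthma* is not
  flagged — a documented limitation of window-based negation, and the reason
  the window is configurable.

Negated mentions stay in the output (callers may want to display them) but
are excluded from query candidacy, from evaluation, and are rejected by
`add_term()`.

`identify_baseline()` is the reference-free comparator: every section, all
sixteen branches, negation computed but not used for exclusion. Its concept
set is provably a superset of any configured run's.

## Queries, qualifiers, counting

`initial_query()` anchors a query on a disease descriptor (strict mode
requires a tree number in branch C). `add_term()` AND-extends it, returning
a new value and deduplicating by descriptor. Qualifiers (subheadings such as
*epidemiology*) attach to a clause only when admissible for **both** the
descriptor (its allowable-qualifier list) and the originating section's
rule; a clause with q qualifiers renders as q separate conjuncts, each
carrying the `[mh]` field tag. The disease renders last. Rendering resolves
qualifier abbreviations to full subheading names through the thesaurus (NLM
XML supplies them) or a built-in table of the official abbreviations.

`annotate_counts()` implements the superscript-next-to-each-keyword
behaviour: for every non-negated keyword not yet in the query it reports the
citation count the query would have after AND-adding that keyword. Counts
come from a backend:

* `local_backend()` evaluates queries against an in-memory corpus, exactly:
  an unqualified clause needs the descriptor among a citation's index terms;
  a qualified clause needs the explicit (descriptor, qualifier) pair for
  each selected qualifier. Results are cached on the canonical rendered
  string; caching is transparent by construction and by test. Optional tree
  explosion (descendant matching, as live PubMed `[mh]` does) exists behind
  a flag but is off by default — the n + 1 theorem only holds without it,
  and local counts are meant to be exactly reasoned about.
* `entrez_backend()` is a thin live ESearch client (counts only, cached,
  rate-limited at 1,000 queries/minute by default; the limit is
  configurable, and a much lower setting is advisable against the modern
  public endpoint). It is never exercised by the test suite: live counts are
  time-varying by nature.

## Evaluation

`precision_recall()` scores identification at the descriptor level per
document — the gold standard a reviewer produces is a list of concepts, not
character spans — and macro-averages by default ("mean precision/recall over
documents"); micro pooling is available. Conventions for degenerate
documents are explicit: empty gold and empty identification count as
P = R = 100 (selectable exclusion instead), and an empty identification
against non-empty gold is vacuously precise (P = 100) with R = 0.

`branch_sweep()` reruns identification under several branch restrictions
(plus the baseline) and tabulates P/R per configuration. On fixtures whose
distractors are planted outside the kept branches this reproduces the
expected trade-off direction: widening branches raises recall and lowers
precision, and the baseline's recall bounds every configured recall.

`reduction_curve()` replaces interactive keyword clicking with three
policies — document order, greedy smallest-count, or a scripted list that
replays a recorded session — and records `(iteration, query, count)` until
the count reaches a first-page-sized result (10 by default) or candidates
run out. Counts are non-increasing because every step is an AND extension.

## The synthetic-data generators

Everything above is testable offline because `generator_spec()` +
`make_mini_mesh()` / `make_cda_set()` / `make_corpus()` produce fully
book-kept fixtures:

* **Mini-MeSH.** Descriptors get nonsense-word names in which every word is
  used at most once across the whole thesaurus, so surface forms never
  collide or nest accidentally; 1–2 tree numbers drawn from `branch_mix`;
  synonyms at `synonym_rate = 0.5`; two-word terms at `multiword_rate =
  0.4`; 0–3 allowable qualifiers.
* **Documents.** 17 documents by default (the size of a realistic curated
  evaluation set), each with 2–3 relevant sections plus an irrelevant
  *Appointment* section. Sentences are templated ("Patient presents with
  X.", "No X reported.") — narrative realism is deliberately sacrificed for
  exactness. Per document: 5 planted in-branch positives (the gold
  standard), 2 negated mentions, 3 out-of-branch distractors, 2
  irrelevant-section mentions. Because the generator records every choice,
  expected tp/fp/fn under any branch restriction are computable in advance,
  and the pipeline must reproduce them *exactly* — the suite checks P = R =
  100 under the matching configuration and the combinatorially predicted
  recall when a branch is dropped.
* **Corpora.** Citation index sets favor planted descriptors
  (`qualified_fraction = 0.3` of index terms carry an explicit qualifier),
  so conjunctive chains shrink realistically. `make_curve_corpus()` inverts
  a target count trajectory: given non-increasing counts it builds the
  corpus for which the query chain returns exactly those counts, which is
  how reduction-curve behaviour is pinned without a live index.

Each artifact kind draws from its own seed-derived stream, so fixtures are
independently reproducible; the same spec and seed give byte-identical
files.

What passing these tests does *not* show: performance on real clinical
prose. Real narratives have inflected and abbreviated mentions (no
stemming or abbreviation expansion here), long-range and post-positioned
negation ("asthma was ruled out"), cross-sentence structure, and MeSH
surface forms that collide in ways the generator's disjoint-word vocabulary
deliberately avoids. The generator demonstrates algorithmic correctness,
not clinical NLP accuracy; published precision/recall of this class of
dictionary matcher on real records (high 90s precision at roughly two-thirds
to four-fifths recall, moving along that trade-off as branches widen) should
be expected to differ from the synthetic 100/100.

## Numerical and design choices

* Problem sizes in the shipped tests: mini-thesauri of 25–80 descriptors,
  3–6 documents per run, corpora of 40–150 citations, and 100 documents for
  the oracle-equivalence sweep — small enough to run in seconds, large
  enough that every code path (ambiguity, negation, qualifiers, branch
  filtering) is exercised.
* Ties and determinism: matches are ordered by (section, start, descriptor);
  multi-descriptor hits emit in sorted id order; the smallest-count curve
  policy breaks count ties by descriptor id; search results order by date
  descending then id. Repeated runs are byte-identical.
* Degenerate inputs: empty thesauri have `max_term_tokens = 1`; empty
  documents parse to zero sections with a warning (validation reports,
  rather than throws, its findings); empty corpora count zero for every
  query; a document with no identified keywords yields a curve of length 1
  (the general query).
* Two distinct "defaults" exist on purpose: the shipped rules restrict to
  branches A–G (the balanced precision/recall operating point), while a
  rule with *unset* branches falls back to the nine branches A–G, N, Z.
  Both are ordinary overridable settings.
* The configuration XML schema is this package's own (round-trip identity is
  property-tested); the fixture TSV dialects for thesauri and corpora exist
  because shipping a full MeSH release is impractical — the official NLM
  descriptor XML loader is provided and year-agnostic.

## Known limitations

Exact dictionary matching only (no stemming, no word-sense disambiguation,
no abbreviation expansion); window-based negation misses long-range
triggers; structured CDA `entry` elements are ignored in favour of narrative
text; the local backend does not explode tree descendants by default, so
its counts can legitimately differ from live PubMed's for the same rendered
query; English-only.
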