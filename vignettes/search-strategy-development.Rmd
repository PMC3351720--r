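---
title: "Objectively derived search strategies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objectively derived search strategies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchdev)
```

## The problem

Search strategies for systematic reviews are traditionally written
conceptually: an information specialist collects synonyms for the health
condition and the intervention from their own expertise, a thesaurus and
colleagues. That process is hard to reproduce, offers no criterion for
when a strategy is "complete", and cannot be validated. Search *filters*
(reusable query blocks for study designs) are, by contrast, routinely
derived empirically from a reference standard and validated against
held-out records. `searchdev` implements the transfer of that
filter-development discipline to the routine, topic-specific (content)
part of a strategy — the health-condition and intervention blocks — for
which no validated filter exists.

The workflow:

1. **Test set.** References included in existing systematic reviews on a
   similar question are pooled into a quasi-gold standard
   (`read_medline()` / `read_ris()` + `merge_dedupe()`). Using reviews
   instead of a hand-search is a pragmatic reference standard; it is only
   as representative as the source reviews' own searches, which is why the
   workflow presumes a quality check of those searches.
2. **Split.** The test set is split at random into two-thirds for
   development and one-third for validation (`split_test_set()`).
3. **Term analysis.** Every text word of the development set's titles and
   abstracts is counted by *document frequency* — the number of records
   containing it — and compared with its frequency in a random population
   sample from the target database (`term_stats()`). The per-term
   sensitivity in the development set is `freq / N`. Controlled vocabulary
   is aggregated over subheadings and major-topic markers before counting
   (`cv_frequencies()`, `cv_stats()`).
4. **Screening.** Candidate terms are those present in at least 20% of
   development records with at most 2% sensitivity in the population
   sample (`select_candidates()`); a user-supplied map then assigns each
   candidate to *health condition*, *intervention* or *questionable*
   (`categorize_terms()`).
5. **Assembly.** The categorized terms are assembled into an Ovid-style
   strategy, health-condition block AND intervention block, that must
   retrieve 100% of the development set (`build_strategy()`);
   questionable terms are admitted only if the two topical blocks leave
   records uncovered.
6. **Validation and documentation.** The strategy is run against the
   held-out validation set (`validate_strategy()`) and every artifact is
   written to a standardized documentation bundle (`report_bundle()`).

## Key statistics

For a term $t$, a development set $D$ and a population sample $P$:

$$\mathrm{sens}_D(t) = \frac{|\{r \in D : t \in r\}|}{|D|}, \qquad
  \mathrm{sens}_P(t) = \frac{|\{r \in P : t \in r\}|}{|P|}$$

where $t \in r$ means the token occurs at least once in the record's
title or abstract. Candidate screening keeps $t$ when
$\mathrm{sens}_D(t) \ge 0.20$ and $\mathrm{sens}_P(t) \le 0.02$ (both
inclusive). For a strategy $S$ with final-line result $R(S)$ and a
reference set $V$:

$$\mathrm{sensitivity} = \frac{|R(S) \cap V|}{|V|}, \qquad
  \mathrm{precision} = \frac{|R(S) \cap V|}{|R(S)|}.$$

Development demands sensitivity 1.0 on $D$; precision is reported but not
thresholded — judging whether the hit count is workable is a decision for
the review team, so the package surfaces counts and leaves the call to the
user.

## Design decisions

**Document frequency, not occurrence counts.** Reported sensitivities in
this workflow are exact ratios of record counts; a term used five times in
one abstract counts once. This is what makes `sens * N == freq` an exact
integer identity, which the tests assert.

**No stopwords, no stemming.** The tokenizer (`tokenize()`) lowercases,
splits on every non-alphabetic character, and drops only tokens shorter
than two characters and purely numeric fragments. Frequent words like
"patients", "results" or "using" stay in the table deliberately: the
population-set comparison — not a language-specific stopword list — is
what rejects them, and the frequency table should show that happening.
"treated" and "treatment" are counted as distinct terms; truncation
(`treat*`) in the assembled query, not stemming in the analysis, is the
mechanism for collapsing morphological variants.

**Screening thresholds are inclusive and configurable.** Defaults 0.20
and 0.02. Terms above the development threshold but too common in the
population are kept as `near_miss` rather than discarded, because a
topically essential word (in the worked example, "cancer", population
sensitivity about 5%) may still belong in the strategy; promotion is a
manual relevance judgment via the category map. The tool never guesses
topical relevance: unmapped candidates stay uncategorized.

**Ranking ties.** Frequency tables are sorted by development-set frequency
descending with alphabetical tie-break, so output is deterministic.

**The query engine is deliberately small.** It parses exactly the
numbered-line dialect that documented strategies use: non-exploded
controlled-vocabulary lines (`Heading/`), fielded Boolean text lines
(`.ab,ti.` and the `:ti,ab,kw` variant), set-combination lines (`or/1-2`,
`and/3,7`), bare line combinations (`8 and 9`) and accession-list checks
(`.ui.`). `NOT`, adjacency operators and explosion are rejected at parse
time rather than silently misinterpreted. Truncation is an unbounded
prefix match on a single token; multi-token strings are not phrases —
tokens combine only through explicit Boolean operators. `kw` matches
tokens of the normalized controlled-vocabulary headings. All matching is
case-insensitive. Within a line, `and` binds tighter than `or`;
parentheses override, and the serializer re-emits parentheses around every
nested Boolean group so that parse–serialize–parse is structurally exact.

**Assembly is deterministic greedy coverage.** The manual trial-and-error
of practice is operationalized: all health-condition and intervention
candidates enter their blocks unconditionally (the aim is sensitivity, and
ORing a redundant specific term is cheap), and questionable terms are
added one at a time by largest gain in uncovered development records, with
ties broken by higher development sensitivity and then alphabetically.
This is the package's own operationalization, not a claim about how any
particular published strategy was assembled. Greedy set cover over a
covering family always terminates at full coverage, which is the
builder's tested invariant. An optional `minimize = TRUE` mode prunes
lines whose removal leaves development coverage intact, for teams that
need a more precise strategy; it trades unknown future sensitivity for
precision and is off by default.

**The split rule.** `round(2n/3)` with halves away from zero, so 38
references give 25 development + 13 validation. The seed is a mandatory
argument: an objectively derived strategy is a one-shot instrument, and an
auditable split is part of its documentation.

## The synthetic corpus generator

`generator_config()` + `generate_corpus()` emulate exactly the structure
the method relies on: each relevant record includes each topical term
independently with probability `p_relevant`; population records use the
much smaller `p_background`; controlled-vocabulary headings are planted
the same way, with a random subheading attached half the time and a
major-topic marker a fifth of the time; everything else is filler drawn
from a Zipf-distributed gibberish vocabulary (prefix `zq`, so planted and
background tokens can never collide). A `truth` table records every
planted occurrence.

`table2_scenario()` packages a configuration shaped like the published
worked example (brachytherapy for prostate cancer): planting
probabilities set to the printed sensitivities where available —
"prostate" 0.96/0.0068, "brachytherapy" 0.76/0.0006, "cancer" 0.96/0.0503
— plus high-frequency uninformative words ("patients", "results",
"treatment", "using") with background probabilities around 0.2 that the
screen must reject. The published frequency table is an extract cut at a
development frequency of 12 of 25, so for candidate terms missing from it
(adenocarcinoma, seed, permanent, implantation) the scenario fixes
mid-range values in [0.28, 0.40]; these were chosen once as plausible for
terms that made the candidate list without reaching the extract. The
population size, 7180, is back-calculated from the printed population
frequencies (1419/0.1976); the source does not state it, and the value is
an inference, not a fact. Default text lengths are Poisson with mean 8
tokens (titles) and 60 (abstracts) — abstracts shorter than typical
MEDLINE records, which keeps the full 7000-record pipeline comfortably
fast without affecting the document-frequency statistics the method uses.

The `ensure_coverage` flag forces at least one health-condition and one
intervention text term into every relevant record (flagged in `truth`).
It exists because the method presumes the quasi-gold standard is reachable
by topical terms; with the flag off, non-coverage is a legitimate,
reported outcome rather than a bug.

**What the generator does not emulate:** real language (word burstiness,
phrases, synonymy), correlated term occurrences, indexing errors,
duplicate records, or database-specific field quirks. Passing the
end-to-end tests therefore shows the pipeline's logic is correct under
the method's own statistical assumptions — not that any particular
strategy will perform identically on a live database, which is exactly
why the validation step against held-out real references exists.

## Numerical and degenerate-input choices

* Sensitivities are stored as exact ratios of integers; no rounding
  happens anywhere in the analysis, only in rendering.
* An empty development or population corpus is an error for the frequency
  operations; an empty query result is a count of 0, not an error.
* A corpus forbids duplicate accessions and records with neither title
  nor abstract; records with empty abstracts are kept, since titles still
  contribute text words.
* Accessions are opaque strings (PMIDs and other database ids mix);
  cross-database collisions are the caller's responsibility, matching the
  rule that a strategy is validated in the database it was designed for.
* RIS records without any id get the deterministic surrogate
  `ris:<ordinal>`.
* Input text is decoded as UTF-8 with a Latin-1 fallback; lowercasing
  happens in the tokenizer, never at I/O.

## Problem sizes used in the tests

The test suite exercises the evaluator against a naive per-record oracle
on 100 random corpora of up to 200 records with random strategies of up
to 8 lines; the split sampler on 1000 seeded splits of 38 ids (each id's
development-set frequency must sit inside the exact binomial 99% interval
of 25/38); planted-term sensitivities pooled over 100 seeded replicates
against exact binomial bounds; and the full synthetic scenario at 38
relevant + 7180 population records. These sizes were chosen to make the
statistical checks sharp while keeping the default test run fast.

## A worked run

```{r, eval = FALSE}
cfg <- table2_scenario(n_relevant = 38)
sim <- generate_corpus(cfg, seed = 1)
sp  <- split_test_set(accessions(sim$relevant), seed = 1)
dev <- corpus_subset(sim$relevant, sp$dev_ids, label = "development")

ts   <- term_stats(dev, sim$population)
cs   <- cv_stats(dev, sim$population)
cand <- categorize_terms(rbind(select_candidates(ts), select_candidates(cs)),
                         cfg$category_map, dev = dev, pop = sim$population)

built <- build_strategy(cand, dev)
db    <- merge_dedupe(list(sim$relevant, sim$population), label = "database")
validate_strategy(built$strategy, db, sp$val_ids, dev_ids = sp$dev_ids)
```

## Known limitations

* The strategy engine evaluates against a *local* corpus; it does not
  reproduce a live database's indexing (automatic term mapping, explosion,
  phrase indexes), so hit counts on a population sample estimate, rather
  than equal, database totals.
* Controlled-vocabulary matching has no MeSH tree: `Heading/` is
  non-exploded by design, and `exp` is a parse error.
* Statistical strategy assembly (logistic regression, factor analysis
  over term indicators) is out of scope; the builder is a transparent
  greedy procedure.
* A validated strategy is one-shot: database content drifts, so reusing
  it later requires re-validation. The mandatory seed and the
  documentation bundle exist to make that re-validation possible.
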