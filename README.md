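# searchdev

Objective (empirically guided) development and validation of Boolean
search strategies for systematic reviews and health-technology
assessments.

Conceptually written search strategies depend on the searcher's topic
knowledge, give no criterion for completeness and cannot be validated.
`searchdev` implements the alternative used in search-filter research for
the *content* part of a strategy (health condition and intervention):

1. pool the references of existing systematic reviews into a
   quasi-gold-standard **test set** (MEDLINE `.nbib`, RIS or JSON-lines);
2. **split** it randomly into a two-thirds development set and a
   one-third validation set;
3. compare each term's **document frequency** in the development set with
   a random **population sample** of the target database — for a term
   $t$, $\mathrm{sens}_D(t) = |\{r \in D : t \in r\}| / |D|$ — keeping
   terms with $\mathrm{sens}_D \ge 0.20$ and population sensitivity
   $\le 0.02$ (controlled vocabulary is aggregated over subheadings
   first);
4. categorize the candidates (health condition / intervention /
   questionable) via an explicit user-supplied map;
5. **assemble** an Ovid-style numbered-line strategy,
   `(health-condition block) AND (intervention block)`, that retrieves
   **100% of the development set**, admitting questionable terms only
   when the topical blocks leave records uncovered;
6. **validate** against the held-out set and write a standardized
   documentation bundle.

The package also contains a faithful evaluator for the Ovid strategy
dialect (`Heading/`, `(x and (y or z)).ab,ti.`, `or/1-2`, `and/3,7`,
`("id" or "id").ui.`, truncation `*`, Cochrane `:ti,ab,kw`) against a
local corpus, and a seeded synthetic-corpus generator with known
term-planting probabilities so the entire pipeline can be exercised and
tested without any database access.

## Worked example

The packaged scenario emulates a search for brachytherapy in patients
with prostate cancer: topical terms planted at realistic per-record
probabilities in 38 relevant records, rare in a 7180-record population
sample.

```r
library(searchdev)

cfg <- table2_scenario(n_relevant = 38)
sim <- generate_corpus(cfg, seed = 1)
sp  <- split_test_set(accessions(sim$relevant), seed = 1)   # 25 + 13
dev <- corpus_subset(sim$relevant, sp$dev_ids, label = "development")

ts <- term_stats(dev, sim$population)
head(ts[!startsWith(ts$term, "zq"), ], 8)
#> # A tibble: 8 × 6
#>   term          kind      freq_dev freq_pop sens_dev sens_pop
#>   <chr>         <chr>        <int>    <int>    <dbl>    <dbl>
#> 1 cancer        text_word       25      379     1    0.0528
#> 2 patients      text_word       25     1436     1    0.2
#> 3 results       text_word       25     1407     1    0.196
#> 4 treatment     text_word       24      991     0.96 0.138
#> 5 methods       text_word       23      340     0.92 0.0474
#> 6 prostate      text_word       23       49     0.92 0.00682
#> 7 brachytherapy text_word       19        3     0.76 0.000418
#> 8 psa           text_word       13       89     0.52 0.0124
```

"brachytherapy" appears in 19 of the 25 development records (sensitivity
0.76) but in only 3 of 7180 population records — a strongly
overrepresented, specific term. "patients" and "results" are maximally
sensitive but useless (population sensitivity ≈ 0.2); the population
comparison, not a stopword list, rejects them. Screening, categorization
and assembly:

```r
cs   <- cv_stats(dev, sim$population)
cand <- categorize_terms(rbind(select_candidates(ts), select_candidates(cs)),
                         cfg$category_map, dev = dev, pop = sim$population)
built <- build_strategy(cand, dev)
built
#> <build_result>
#>   dev sensitivity: 1.0000
#>   questionable terms used: none
#>   strategy:
#>     1 cancer.ab,ti.
#>     2 prostate.ab,ti.
#>     3 adenocarcinoma.ab,ti.
#>     4 prostatic neoplasms/
#>     5 or/1-4 [Health condition]
#>     6 brachytherapy.ab,ti.
#>     7 implantation.ab,ti.
#>     8 seed.ab,ti.
#>     9 permanent.ab,ti.
#>     10 brachytherapy/
#>     11 or/6-10 [Intervention]
#>     12 and/5,11
```

The two topical blocks already retrieve all 25 development records, so no
questionable term is needed. Validation on the held-out 13 records:

```r
db <- merge_dedupe(list(sim$relevant, sim$population), label = "database")
validate_strategy(built$strategy, db, sp$val_ids, dev_ids = sp$dev_ids)
#> <validation_report on corpus 'database'>
#>   sensitivity: 1.0000 (13 of 13 retrieved)
```

`report_bundle()` then writes the frequency tables, candidate list,
strategy, build log and validation counts as a deterministic plain-text
documentation bundle.

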