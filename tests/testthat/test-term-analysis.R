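test_that("tokenizer lowercases, splits on non-letters, keeps no short/numeric tokens", {
  expect_equal(tokenize("Brachytherapy versus radical prostatectomy"),
               c("brachytherapy", "versus", "radical", "prostatectomy"))
  expect_equal(tokenize("follow-up of PSA (prostate-specific antigen)"),
               c("follow", "up", "of", "psa", "prostate", "specific", "antigen"))
  expect_equal(tokenize(""), character())
  expect_equal(tokenize("a 123 I2 5-year"), c("year"))  # short + numeric dropped
})

test_that("doc_frequencies counts records, not occurrences", {
  corp <- make_corpus(
    titles = c("seed seed seed", "seed implant", "implant only"),
    abstracts = c("seed again seed", "", ""))
  f <- doc_frequencies(corp)
  expect_equal(unname(f["seed"]), 2)       # 5 occurrences in record 1 count once
  expect_equal(unname(f["implant"]), 2)
  expect_false("absent" %in% names(f))
  expect_error(doc_frequencies(corpus()), "empty")
})

test_that("doc_frequencies agrees with a brute-force membership scan", {
  withr::local_seed(42)
  for (rep in 1:5) {
    corp <- rand_corpus(sample(5:60, 1))
    f <- doc_frequencies(corp)
    views <- lapply(seq_len(corpus_size(corp)), function(i)
      unique(c(oracle_tokens(corp$records$title[i]),
               oracle_tokens(corp$records$abstract[i]))))
    vocab <- sort(unique(unlist(views)))
    brute <- vapply(vocab, function(tm)
      sum(vapply(views, function(v) tm %in% v, logical(1))), integer(1))
    expect_setequal(names(f), vocab)
    expect_equal(unname(f[vocab]), unname(brute))
  }
})

test_that("term_stats reports exact frequency ratios of dev and population sets", {
  dev <- make_planted_dev()
  pop <- make_corpus(
    vapply(1:50, function(i) paste("unrelated words here",
                                   if (i <= 4) "prostate"), character(1)),
    ids = paste0("p", 1:50))
  ts <- term_stats(dev, pop)
  row <- function(tm) ts[ts$term == tm, ]
  expect_equal(row("brachytherapy")$freq_dev, 19L)
  expect_equal(row("brachytherapy")$sens_dev, 0.76)
  expect_equal(row("prostate")$sens_dev, 0.96)
  expect_equal(row("patients")$sens_dev, 1.0)
  expect_equal(row("prostate")$freq_pop, 4L)
  expect_equal(row("prostate")$sens_pop, 4 / 50)
  expect_equal(row("cancer")$sens_pop, 0)           # absent from population
  # sorted by freq_dev descending, alphabetical ties
  expect_true(all(diff(ts$freq_dev) <= 0))
  # integer identity: sens_dev * |dev| == freq_dev exactly
  expect_equal(ts$sens_dev * corpus_size(dev), as.numeric(ts$freq_dev))
  expect_error(term_stats(corpus(), pop), "non-empty")
})

test_that("cv_frequencies aggregates subheadings and major-topic markers", {
  corp <- make_corpus(
    titles = c("one", "two", "three"),
    cv = list(c("Brachytherapy/methods"),
              c("*Brachytherapy"),
              c("Brachytherapy/methods", "Brachytherapy/adverse effects",
                "Prostatic Neoplasms/radiotherapy")))
  f <- cv_frequencies(corp)
  expect_equal(unname(f["brachytherapy"]), 3)   # once per record
  expect_equal(unname(f["prostatic neoplasms"]), 1)
  expect_equal(length(f), 2)
})

test_that("candidate screening partitions by the 20%/2% thresholds", {
  stats <- tibble::tibble(
    term = c("brachytherapy", "cancer", "rare", "edge"),
    kind = "text_word",
    freq_dev = c(19L, 24L, 3L, 5L), freq_pop = c(4L, 361L, 1L, 144L),
    sens_dev = c(0.76, 0.96, 0.12, 0.20),
    sens_pop = c(0.0006, 0.0503, 0.0001, 0.02))
  out <- select_candidates(stats)
  expect_equal(out$status,
               c("auto_pass", "near_miss", "excluded", "auto_pass"))
  # both thresholds are inclusive: sens_dev == 0.20 and sens_pop == 0.02 pass
  expect_equal(out$status[out$term == "edge"], "auto_pass")
  # exhaustive and disjoint
  expect_true(all(out$status %in% c("auto_pass", "near_miss", "excluded")))
  expect_error(select_candidates(stats, dev_threshold = 0), "thresholds")
})

test_that("lowering the population threshold never grows auto_pass", {
  withr::local_seed(1)
  stats <- tibble::tibble(
    term = sprintf("t%02d", 1:50), kind = "text_word",
    freq_dev = sample(0:25, 50, TRUE), freq_pop = sample(0:500, 50, TRUE))
  stats$sens_dev <- stats$freq_dev / 25
  stats$sens_pop <- stats$freq_pop / 5000
  thresholds <- c(0.05, 0.02, 0.01, 0.001)
  passes <- lapply(thresholds, function(pt)
    with(select_candidates(stats, pop_threshold = pt), term[status == "auto_pass"]))
  for (i in seq_len(length(passes) - 1)) {
    expect_true(all(passes[[i + 1]] %in% passes[[i]]))
  }
})

test_that("categorize_terms applies the user map and never guesses", {
  stats <- tibble::tibble(
    term = c("brachytherapy", "prostate", "gleason", "patients"),
    kind = "text_word",
    freq_dev = c(19L, 24L, 13L, 25L), freq_pop = c(4L, 49L, 4L, 1419L),
    sens_dev = c(0.76, 0.96, 0.52, 1.0),
    sens_pop = c(0.0006, 0.0068, 0.0006, 0.1976))
  cand <- select_candidates(stats)
  map <- c(brachytherapy = "intervention", prostate = "health_condition",
           gleason = "questionable")
  out <- categorize_terms(cand, map)
  expect_equal(out$category[out$term == "brachytherapy"], "intervention")
  expect_equal(out$category[out$term == "prostate"], "health_condition")
  expect_equal(out$category[out$term == "gleason"], "questionable")
  expect_true(is.na(out$category[out$term == "patients"]))  # uncategorized

  # empty map: everything uncategorized
  out0 <- categorize_terms(cand, character())
  expect_true(all(is.na(out0$category)))

  # mapped term absent from the corpus: manual_add with zero frequency
  dev <- make_planted_dev()
  pop <- make_corpus("population words", ids = "p1")
  out2 <- categorize_terms(cand, c(map, cryotherapy = "intervention"),
                           dev = dev, pop = pop)
  added <- out2[out2$term == "cryotherapy", ]
  expect_equal(added$screen_status, "manual_add")
  expect_equal(added$freq_dev, 0L)

  expect_error(categorize_terms(cand, c(brachytherapy = "treatment")),
               "unknown category")
})

test_that("planted-term sensitivity matches its planting probability (binomial check)", {
  cfg <- generator_config(
    n_relevant = 20, n_population = 5,
    topic_terms = tibble::tibble(term = c("brachytherapy", "rarely"),
                                 p_relevant = c(0.76, 0.10),
                                 p_background = c(0, 0)),
    vocab_size = 150, title_mean = 4, abstract_mean = 8)
  n_rep <- 100
  freq <- matrix(0L, n_rep, 2)
  for (r in seq_len(n_rep)) {
    sim <- generate_corpus(cfg, seed = 5000 + r)
    f <- doc_frequencies(sim$relevant)
    freq[r, ] <- c(f["brachytherapy"], ifelse(is.na(f["rarely"]), 0L, f["rarely"]))
  }
  # pooled draws: 100 replicates x 20 records, exact binomial 99% interval
  for (j in 1:2) {
    p <- c(0.76, 0.10)[j]
    total <- sum(freq[, j])
    bounds <- stats::qbinom(c(0.005, 0.995), n_rep * 20, p)
    expect_gte(total, bounds[1])
    expect_lte(total, bounds[2])
  }
})
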