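published_strategy <- c(
  "1 Prostatic Neoplasms/",
  "2 (prostat* and (cancer or adenocarcinoma)).ab,ti.",
  "3 or/1-2 [Health condition]",
  "4 Brachytherapy/",
  "5 Brachytherapy.ab,ti.",
  "6 ((seed* or permanent*) and implant*).ab,ti.",
  "7 or/4-6 [Intervention]",
  "8 and/3,7")

test_that("parser handles the standard Ovid constructs", {
  s <- parse_strategy(published_strategy)
  expect_equal(strategy_length(s), 8)
  expect_equal(s$lines[[1]]$expression$type, "cv_heading")
  expect_equal(s$lines[[1]]$expression$heading, "prostatic neoplasms")
  expect_equal(s$lines[[2]]$expression$type, "fielded_text")
  expect_setequal(s$lines[[2]]$expression$fields, c("ab", "ti"))
  expect_equal(s$lines[[3]]$expression$type, "line_range_or")
  expect_equal(s$lines[[3]]$annotation, "Health condition")
  expect_equal(s$lines[[8]]$expression$type, "line_list_and")
  expect_equal(s$lines[[8]]$expression$lines, c(3L, 7L))
  # truncation marker parsed on the token
  inner <- s$lines[[2]]$expression$expr
  expect_equal(inner$type, "and")
  expect_true(inner$children[[1]]$truncated)
  expect_equal(inner$children[[1]]$token, "prostat")
})

test_that("Cochrane field dialect parses to the same node as Ovid", {
  a <- parse_strategy("1 (brachytherapy and prostate):ti,ab,kw")
  b <- parse_strategy("1 (brachytherapy and prostate).ti,ab,kw.")
  expect_equal(a$lines[[1]]$expression, b$lines[[1]]$expression)
})

test_that("accession list lines parse into .ui. nodes", {
  s <- parse_strategy('1 ("18374503" or "11104883" or "2009027580").ui. [development set]')
  expect_equal(s$lines[[1]]$expression$type, "accession_list")
  expect_equal(s$lines[[1]]$expression$ids,
               c("18374503", "11104883", "2009027580"))
  expect_equal(s$lines[[1]]$annotation, "development set")
})

test_that("parser rejects unsupported or malformed constructs with line numbers", {
  expect_error(parse_strategy("1 prostate.ab,ti.\n2 and/3,7"), "line 2")
  expect_error(parse_strategy("1 (cancer not benign).ab,ti."), "NOT")
  expect_error(parse_strategy("1 (seed adj2 implant).ab,ti."), "adj")
  expect_error(parse_strategy("1 exp Prostatic Neoplasms/"), "exp")
  expect_error(parse_strategy("1 cancer.xy."), "field tag")
  expect_error(parse_strategy("1 ((cancer or seed).ab,ti."), "parenthes")
  expect_error(parse_strategy("1 cancer"), "field")
  expect_error(parse_strategy("3 cancer.ab,ti."), "increase")
})

test_that("serialize -> reparse is structurally identical", {
  s <- parse_strategy(published_strategy)
  s2 <- parse_strategy(format_strategy(s))
  expect_equal(s2, s)
  withr::local_seed(99)
  for (rep in 1:20) {
    corp <- rand_corpus(10)
    txt <- rand_strategy_text(corp, sample(2:8, 1))
    p1 <- parse_strategy(txt)
    p2 <- parse_strategy(format_strategy(p1))
    expect_equal(p2, p1)
  }
})

test_that("evaluation implements Boolean set semantics over records", {
  corp <- make_corpus(
    titles = c("prostate cancer brachytherapy", "prostate cancer", "breast cancer"),
    ids = c("r1", "r2", "r3"))
  s <- parse_strategy(c("1 brachytherapy.ab,ti.",
                        "2 (prostat* and cancer).ab,ti.",
                        "3 and/1,2"))
  res <- evaluate_strategy(s, corp)
  expect_equal(retrieved(res, 1), "r1")
  expect_setequal(retrieved(res, 2), c("r1", "r2"))
  expect_equal(retrieved(res, 3), "r1")
  expect_equal(hit_counts(res)$count, c(1L, 2L, 1L))
})

test_that("or-range unions member lines; accession list is an AND identity", {
  corp <- make_corpus(
    titles = c("alpha topic", "beta topic", "gamma topic"),
    ids = c("a", "b", "c"))
  s <- parse_strategy(c("1 (alpha or beta).ab,ti.",
                        "2 (beta or gamma).ab,ti.",
                        "3 or/1-2"))
  expect_setequal(retrieved(evaluate_strategy(s, corp), 3), c("a", "b", "c"))

  full <- sprintf('(%s).ui.', paste(sprintf('"%s"', accessions(corp)),
                                    collapse = " or "))
  s2 <- parse_strategy(c("1 (alpha or beta).ab,ti.", paste("2", full), "3 and/1,2"))
  res2 <- evaluate_strategy(s2, corp)
  expect_setequal(retrieved(res2, 2), accessions(corp))
  expect_setequal(retrieved(res2, 3), retrieved(res2, 1))
})

test_that("fields restrict matching and kw searches controlled vocabulary", {
  corp <- make_corpus(
    titles = c("brachytherapy here", "unrelated title"),
    abstracts = c("", "brachytherapy in abstract"),
    cv = list(character(), "Prostatic Neoplasms/surgery"),
    ids = c("t", "a"))
  expect_equal(retrieved(evaluate_strategy(
    parse_strategy("1 brachytherapy.ti."), corp)), "t")
  expect_equal(retrieved(evaluate_strategy(
    parse_strategy("1 brachytherapy.ab."), corp)), "a")
  expect_setequal(retrieved(evaluate_strategy(
    parse_strategy("1 brachytherapy.ab,ti."), corp)), c("t", "a"))
  expect_equal(retrieved(evaluate_strategy(
    parse_strategy("1 neoplasms.kw."), corp)), "a")
})

test_that("cv heading matching strips markers/subheadings but does not explode", {
  corp <- make_corpus(
    titles = c("one", "two", "three"),
    cv = list("Brachytherapy/methods", "*Brachytherapy",
              "Prostatic Neoplasms"),
    ids = c("m", "s", "p"))
  s <- parse_strategy("1 Brachytherapy/")
  expect_setequal(retrieved(evaluate_strategy(s, corp)), c("m", "s"))
})

test_that("truncation is an unbounded prefix match on single tokens", {
  corp <- make_corpus(
    titles = c("prostate", "prostatectomy", "prospective"),
    ids = c("a", "b", "c"))
  expect_setequal(retrieved(evaluate_strategy(
    parse_strategy("1 prostat*.ab,ti."), corp)), c("a", "b"))
  expect_setequal(retrieved(evaluate_strategy(
    parse_strategy("1 pros*.ab,ti."), corp)), c("a", "b", "c"))
})

test_that("adding a disjunct never shrinks, a conjunct never grows, a line", {
  withr::local_seed(7)
  for (rep in 1:10) {
    corp <- rand_corpus(40)
    base <- sprintf("(%s or %s)", sample(rand_vocab, 1), sample(rand_vocab, 1))
    extra <- sample(rand_vocab, 1)
    n_or0 <- hit_counts(evaluate_strategy(parse_strategy(
      sprintf("1 %s.ab,ti.", base)), corp))$count
    n_or1 <- hit_counts(evaluate_strategy(parse_strategy(
      sprintf("1 (%s or %s).ab,ti.", base, extra)), corp))$count
    expect_gte(n_or1, n_or0)
    n_and1 <- hit_counts(evaluate_strategy(parse_strategy(
      sprintf("1 (%s and %s).ab,ti.", base, extra)), corp))$count
    expect_lte(n_and1, n_or0)
  }
})

test_that("line references are referentially transparent", {
  withr::local_seed(13)
  for (rep in 1:10) {
    corp <- rand_corpus(30)
    t1 <- sprintf("1 %s.ab,ti.", rand_bool_text(1))
    t2 <- sprintf("2 %s.ab,ti.", rand_bool_text(1))
    t3 <- "3 or/1-2"
    res <- evaluate_strategy(parse_strategy(c(t1, t2, t3)), corp)
    expect_setequal(retrieved(res, 3),
                    union(retrieved(res, 1), retrieved(res, 2)))
  }
})

test_that("hit count table renders queries and counts", {
  corp <- make_corpus(c("alpha beta", "beta gamma"), ids = c("1", "2"))
  res <- evaluate_strategy(parse_strategy(c("1 nothing.ab,ti.",
                                            "2 beta.ab,ti.")), corp)
  tab <- hit_counts(res)
  expect_equal(tab$count, c(0L, 2L))
  expect_equal(tab$query[2], "beta.ab,ti.")
  md <- write_hit_counts(res, format = "markdown")
  expect_match(md, "\\| Number \\| Searches \\| Results \\|")
})
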