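test_that("rule blocks parse with kb-to-nt conversion", {
  rules <- parse_rules(
    "RULE T CATEGORY terpene CUTOFF 20 NEIGHBOURHOOD 10 CONDITIONS TPS")
  expect_length(rules, 1)
  r <- rules[[1]]
  expect_equal(r$rule_name, "T")
  expect_equal(r$category, "terpene")
  expect_equal(r$cutoff_nt, 20000L)
  expect_equal(r$neighbourhood_nt, 10000L)
  expect_equal(r$conditions$kind, "PROFILE")
  expect_equal(r$conditions$profile_name, "TPS")
  expect_null(r$extends)
})

test_that("operator precedence is not > and > or", {
  cond <- parse_rules(
    "RULE X CATEGORY c CUTOFF 1 NEIGHBOURHOOD 0 CONDITIONS A and B or C"
  )[[1]]$conditions
  expect_equal(cond$kind, "OR")
  expect_equal(cond$children[[1]]$kind, "AND")
  expect_equal(cond$children[[2]]$profile_name, "C")
  cond2 <- parse_rules(
    "RULE X CATEGORY c CUTOFF 1 NEIGHBOURHOOD 0 CONDITIONS not A and B"
  )[[1]]$conditions
  expect_equal(cond2$kind, "AND")
  expect_equal(cond2$children[[1]]$kind, "NOT")
  cond3 <- parse_rules(
    "RULE X CATEGORY c CUTOFF 1 NEIGHBOURHOOD 0 CONDITIONS A and (B or C)"
  )[[1]]$conditions
  expect_equal(cond3$kind, "AND")
  expect_equal(cond3$children[[2]]$kind, "OR")
})

test_that("minimum and minscore parse into the right nodes", {
  cond <- parse_rules(
    "RULE X CATEGORY c CUTOFF 1 NEIGHBOURHOOD 0 CONDITIONS minimum(2, [A, B, C])"
  )[[1]]$conditions
  expect_equal(cond$kind, "MINIMUM")
  expect_equal(cond$count, 2L)
  expect_equal(cond$profiles, c("A", "B", "C"))
  cond2 <- parse_rules(
    "RULE X CATEGORY c CUTOFF 1 NEIGHBOURHOOD 0 CONDITIONS minscore(KS, 100)"
  )[[1]]$conditions
  expect_equal(cond2$kind, "MINSCORE")
  expect_equal(cond2$score, 100)
})

test_that("parse errors carry line and column; duplicates rejected", {
  expect_error(parse_rules(
    "RULE X CATEGORY c CUTOFF 1 NEIGHBOURHOOD 0 CONDITIONS (A and B"),
    "line 1")
  expect_error(parse_rules(
    "RULE X CATEGORY c CUTOFF 1 NEIGHBOURHOOD 0 CONDITIONS A ? B"),
    "column")
  two <- paste(
    "RULE X CATEGORY c CUTOFF 1 NEIGHBOURHOOD 0 CONDITIONS A",
    "RULE X CATEGORY c CUTOFF 1 NEIGHBOURHOOD 0 CONDITIONS B", sep = "\n")
  expect_error(parse_rules(two), "duplicate rule name")
  expect_error(parse_rules(
    "RULE X CATEGORY c CUTOFF 0 NEIGHBOURHOOD 0 CONDITIONS A"),
    "CUTOFF")
})

test_that("EXTENDS clauses are attached to their rule", {
  rules <- parse_rules(paste(
    "RULE tat CATEGORY transAT CUTOFF 10 NEIGHBOURHOOD 20",
    "  CONDITIONS AT and minscore(KS, 100)",
    "  EXTENDS KS",
    "RULE plain CATEGORY x CUTOFF 5 NEIGHBOURHOOD 5 CONDITIONS AT",
    sep = "\n"))
  expect_equal(format_condition(rules[[1]]$extends), "KS")
  expect_null(rules[[2]]$extends)
})

test_that("formatting a condition re-parses to the same tree", {
  texts <- c("A and B or C", "not A and (B or C)",
             "minimum(2, [A, B, C]) or minscore(KS, 75.5)")
  for (txt in texts) {
    rule <- parse_rules(paste(
      "RULE X CATEGORY c CUTOFF 1 NEIGHBOURHOOD 0 CONDITIONS", txt))[[1]]
    again <- parse_rules(paste(
      "RULE X CATEGORY c CUTOFF 1 NEIGHBOURHOOD 0 CONDITIONS",
      format_condition(rule$conditions)))[[1]]
    expect_equal(again$conditions, rule$conditions, ignore_attr = TRUE)
  }
})

test_that("condition evaluation matches documented semantics at boundaries", {
  no_hits <- tibble::tibble(profile_name = character(), bitscore = numeric())
  expect_true(evaluate_condition(cond_not(cond_profile("A")), no_hits))
  # distinctness: two hits to the same profile count once
  aa <- tibble::tibble(profile_name = c("A", "A"), bitscore = c(50, 60))
  expect_false(evaluate_condition(cond_minimum(2, c("A", "B", "C")), aa))
  expect_true(evaluate_condition(cond_minimum(1, c("A", "B", "C")), aa))
  # minscore boundary is inclusive
  near <- tibble::tibble(profile_name = "A", bitscore = 49.9)
  expect_false(evaluate_condition(cond_minscore("A", 50), near))
  at <- tibble::tibble(profile_name = "A", bitscore = 50)
  expect_true(evaluate_condition(cond_minscore("A", 50), at))
  # unknown profile in a condition simply never matches
  expect_false(evaluate_condition(cond_profile("ZZZ"), aa))
})

test_that("evaluation agrees with the independent oracle on random trees", {
  set.seed(77)
  pool <- c("A", "B", "C", "D")
  random_tree <- function(depth) {
    if (depth == 0 || stats::runif(1) < 0.35) {
      pick <- sample(3, 1)
      if (pick == 1) return(cond_profile(sample(pool, 1)))
      if (pick == 2) return(cond_minscore(sample(pool, 1), sample(20:60, 1)))
      return(cond_minimum(sample(1:3, 1), sample(pool, sample(2:4, 1))))
    }
    op <- sample(c("and", "or", "not"), 1)
    if (op == "not") return(cond_not(random_tree(depth - 1)))
    kids <- lapply(seq_len(sample(2:3, 1)), function(i) random_tree(depth - 1))
    do.call(if (op == "and") cond_and else cond_or, kids)
  }
  for (i in 1:100) {
    tree <- random_tree(3)
    n <- sample(0:6, 1)
    hits <- tibble::tibble(profile_name = sample(pool, n, replace = TRUE),
                           bitscore = round(stats::runif(n, 10, 70), 1))
    expect_equal(evaluate_condition(tree, hits), oracle_eval(tree, hits))
  }
})
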