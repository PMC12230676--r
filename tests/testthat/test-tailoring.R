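aa_pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_prot <- function(n) {
  paste0("M", paste(sample(aa_pool, n - 1, replace = TRUE), collapse = ""))
}

tmp_reference <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "reference.faa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             fasta)
  meta <- file.path(dir, "reference.tsv")
  readr::write_tsv(tibble::tibble(
    entry_id = names(seqs),
    display_name = paste0("enzyme ", names(seqs)),
    reaction_text = paste0("reaction of ", names(seqs)),
    url_template = "https://example.org/entry/{id}"), meta, progress = FALSE)
  read_reference_set(fasta, meta)
}

test_that("identical sequences cross-link at 100% identity", {
  set.seed(1)
  s <- rand_prot(200)
  ref <- tmp_reference(list(E1 = s))
  links <- mite_crosslink(s, ref)
  expect_equal(links$entry_id, "E1")
  expect_equal(links$percent_identity, 100)
  expect_equal(links$url, "https://example.org/entry/E1")
})

test_that("the 60% identity boundary is inclusive", {
  set.seed(2)
  s <- rand_prot(300)
  ref <- tmp_reference(list(E1 = s))
  # exactly 60.0%: 120 of 300 conservative substitutions
  at60 <- mutate_exact_identity(s, 120)
  expect_equal(pairwise_identity(s, at60), 60)   # substitution-only closed form
  expect_equal(mite_crosslink(at60, ref)$entry_id, "E1")
  # 59%: one more substitution triple -> below the threshold, no link
  at59 <- mutate_exact_identity(s, 123)
  expect_equal(pairwise_identity(s, at59), 59)
  expect_equal(nrow(mite_crosslink(at59, ref)), 0)
})

test_that("identity is symmetric on equal-length ungapped pairs", {
  set.seed(3)
  for (i in 1:10) {
    a <- rand_prot(150)
    b <- mutate_exact_identity(a, sample(0:100, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("all passing reference entries return, sorted by identity", {
  set.seed(4)
  s <- rand_prot(250)
  ref <- tmp_reference(list(
    far = rand_prot(250),
    close = mutate_exact_identity(s, 25),
    closer = mutate_exact_identity(s, 5)))
  links <- mite_crosslink(s, ref)
  expect_equal(links$entry_id, c("closer", "close"))
  expect_true(all(diff(links$percent_identity) <= 0))
})

halogenase_region <- function() {
  set.seed(5)
  record <- mk_record(30000, "linear", list(
    oxyA = c(1000, 2200), oxyB = c(2500, 3700), oxyC = c(4000, 5200),
    oxyD = c(5500, 6700), bhaA = c(7500, 9100), bgtfA = c(9500, 10700)))
  record$cds$translation <- vapply(seq_len(6), function(i) rand_prot(300),
                                   character(1))
  # plant the tryptophan-6 regioselectivity motif in the halogenase
  tr <- record$cds$translation[record$cds$cds_id == "bhaA"]
  record$cds$translation[record$cds$cds_id == "bhaA"] <-
    paste0(substr(tr, 1, 100), "GWTWSIDS", substr(tr, 109, 300))
  hits <- mk_hits(
    list("oxyA", "p450", 140), list("oxyB", "p450", 150),
    list("oxyC", "p450", 135), list("oxyD", "p450", 160),
    list("bhaA", "flavin_halogenase", 180), list("bgtfA", "glycosyltransferase", 120))
  rules <- parse_rules(paste(
    "RULE hal CATEGORY halogenated CUTOFF 10 NEIGHBOURHOOD 5",
    "  CONDITIONS minimum(2, [flavin_halogenase, p450, glycosyltransferase])",
    sep = "\n"))
  rs <- detect_regions(record, hits, rules)
  list(record = record, region = rs$regions[[1]], hits = hits)
}

test_that("tailoring annotations group by EC category with fixture truth counts", {
  x <- halogenase_region()
  ann <- categorize_tailoring_enzymes(x$region, x$hits, fixture_tailoring_map(),
                                      x$record,
                                      halogenase_signatures = fixture_halogenase_signatures())
  counts <- table(ann$ec_category)
  expect_equal(unname(counts[["oxidoreductases"]]), 4L)
  expect_equal(unname(counts[["transferases"]]), 2L)
  report <- tailoring_report(ann)
  expect_named(report, c("oxidoreductases", "transferases"))
  # every annotated gene really carries a tailoring hit
  expect_true(all(ann$cds_id %in% x$hits$cds_id))
})

test_that("halogenase predictions grade from family level to regioselectivity", {
  sigs <- fixture_halogenase_signatures()
  set.seed(6)
  plain <- rand_prot(300)
  fam <- predict_halogenase(plain, sigs)
  expect_equal(fam$prediction_text, "flavin-dependent halogenase")
  expect_equal(fam$detail_rank, 1L)
  trp6 <- paste0(substr(plain, 1, 50), "GWTWSIDS", substr(plain, 59, 300))
  expect_equal(predict_halogenase(trp6, sigs)$detail_rank, 3L)
  expect_match(predict_halogenase(trp6, sigs)$prediction_text, "C6")
  pyr <- paste0(substr(plain, 1, 50), "CPYCGG", substr(plain, 57, 300))
  expect_equal(predict_halogenase(pyr, sigs)$prediction_text,
               "halogenated pyrrole")
})

test_that("summaries carry the highest-detail prediction available", {
  x <- halogenase_region()
  ann <- categorize_tailoring_enzymes(x$region, x$hits, fixture_tailoring_map(),
                                      x$record,
                                      halogenase_signatures = fixture_halogenase_signatures())
  bha <- ann[ann$cds_id == "bhaA", ]
  expect_match(bha$summary, "C6 regioselectivity")
  preds <- bha$predictions[[1]]
  expect_gte(nrow(preds), 2)  # family-level map entry plus the motif grade
  expect_equal(bha$summary, preds$text[which.max(preds$detail_rank)])
  # invariant over all annotations: summary rank is maximal
  for (i in seq_len(nrow(ann))) {
    p <- ann$predictions[[i]]
    expect_equal(ann$summary[i], p$text[which.max(p$detail_rank)])
  }
})

test_that("reference cross-links join the prediction list when identity passes", {
  x <- halogenase_region()
  bha_tr <- x$record$cds$translation[x$record$cds$cds_id == "bhaA"]
  ref <- tmp_reference(list(MITE001 = bha_tr))
  ann <- categorize_tailoring_enzymes(x$region, x$hits, fixture_tailoring_map(),
                                      x$record,
                                      halogenase_signatures = fixture_halogenase_signatures(),
                                      reference = ref)
  bha <- ann[ann$cds_id == "bhaA", ]
  expect_match(bha$summary, "MITE001")
  srcs <- bha$predictions[[1]]$source
  expect_true("mite" %in% srcs)
})

test_that("a region without tailoring hits reports nothing", {
  record <- mk_record(20000, "linear", list(g = c(1000, 2000)))
  rules <- parse_rules(
    "RULE t CATEGORY terpene CUTOFF 10 NEIGHBOURHOOD 5 CONDITIONS TPS")
  hits <- mk_hits(list("g", "TPS", 80))
  rs <- detect_regions(record, hits, rules)
  ann <- categorize_tailoring_enzymes(rs$regions[[1]], hits,
                                      fixture_tailoring_map(), record)
  expect_equal(nrow(ann), 0)
  expect_length(tailoring_report(ann), 0)
})
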