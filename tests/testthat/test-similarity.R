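test_that("confidence tiers reproduce the documented boundaries", {
  expect_equal(bin_confidence(75.0), "high")
  expect_equal(bin_confidence(74.9), "medium")
  expect_equal(bin_confidence(50.0), "medium")
  expect_equal(bin_confidence(49.9), "low")
  expect_equal(bin_confidence(15.0), "low")
  expect_equal(bin_confidence(14.9), "hidden")
  expect_equal(bin_confidence(0), "hidden")
  expect_equal(bin_confidence(100), "high")
  expect_error(bin_confidence(101), "\\[0, 100\\]")
  expect_error(bin_confidence(-0.1), "\\[0, 100\\]")
})

test_that("binning is monotone over the whole percentage range", {
  tiers <- c(hidden = 0, low = 1, medium = 2, high = 3)
  grid <- seq(0, 100, by = 0.1)
  ranks <- tiers[vapply(grid, bin_confidence, character(1))]
  expect_true(all(diff(ranks) >= 0))
})

test_that("similarity counts matched reference genes over the total", {
  set.seed(21)
  genes <- stats::setNames(
    vapply(1:4, function(i) {
      paste0("M", paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                               249, replace = TRUE), collapse = ""))
    }, character(1)), paste0("r", 1:4))
  ref <- reference_cluster("ref1", "test reference", genes)
  # all four genes present verbatim -> 100%
  all4 <- compute_cluster_similarity(unname(genes), ref)
  expect_equal(all4$similarity_percent, 100)
  expect_equal(all4$confidence, "high")
  # three of four -> 75%, still high (inclusive boundary)
  three <- compute_cluster_similarity(unname(genes[1:3]), ref)
  expect_equal(three$similarity_percent, 75)
  expect_equal(three$confidence, "high")
  # unrelated query genes -> 0%, hidden
  set.seed(22)
  unrelated <- vapply(1:3, function(i) {
    paste0("M", paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                             249, replace = TRUE), collapse = ""))
  }, character(1))
  none <- compute_cluster_similarity(unrelated, ref)
  expect_equal(none$similarity_percent, 0)
  expect_equal(none$confidence, "hidden")
  expect_error(compute_cluster_similarity(character(0), ref), "at least one")
})

test_that("the per-gene 30% identity threshold is inclusive", {
  set.seed(23)
  g <- paste0("M", paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                299, replace = TRUE), collapse = ""))
  ref <- reference_cluster("ref1", "one-gene reference", c(gene = g))
  at30 <- mutate_exact_identity(g, 210)    # exactly 30.0%
  expect_equal(pairwise_identity(g, at30), 30)
  expect_equal(compute_cluster_similarity(at30, ref)$similarity_percent, 100)
  at29 <- mutate_exact_identity(g, 213)    # exactly 29.0%
  expect_equal(pairwise_identity(g, at29), 29)
  expect_equal(compute_cluster_similarity(at29, ref)$similarity_percent, 0)
})

test_that("similarity agrees with exhaustive pair enumeration and is monotone", {
  set.seed(24)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mk <- function(n) paste0("M", paste(sample(aa, n - 1, TRUE), collapse = ""))
  ref_genes <- stats::setNames(vapply(1:5, function(i) mk(120), character(1)),
                               paste0("r", 1:5))
  ref <- reference_cluster("refX", "enumeration reference", ref_genes)
  queries <- c(mutate_exact_identity(ref_genes[[1]], 24),   # 80%
               mutate_exact_identity(ref_genes[[2]], 90),   # 25%, unmatched
               mk(120))
  got <- compute_cluster_similarity(queries, ref)
  # oracle: full identity matrix, count reference genes whose best >= 30
  best <- vapply(ref_genes, function(g) {
    max(vapply(queries, pairwise_identity, numeric(1), b = g))
  }, numeric(1))
  expect_equal(got$similarity_percent, 100 * mean(best >= 30))
  expect_equal(got$matched_genes, sum(best >= 30))
  # adding a matching query gene never lowers the similarity
  more <- compute_cluster_similarity(c(queries, ref_genes[[3]]), ref)
  expect_gte(more$similarity_percent, got$similarity_percent)
})

test_that("region comparison reads reference directories and sorts results", {
  dir <- withr::local_tempdir()
  set.seed(25)
  gen <- generate_reference_set(seed = 99, n_clusters = 2,
                                genes_per_cluster = 3,
                                divergence = c(0, 0.5), dir = dir)
  refs <- read_reference_clusters(dir)
  expect_length(refs, 2)
  expect_equal(refs[[1]]$cluster_id, "refcluster_1")
  # querying with cluster 1's own genes ranks it first at 100%
  record <- mk_record(20000, "linear", list(a = c(1000, 2000),
                                            b = c(3000, 4000),
                                            c = c(5000, 6000)))
  record$cds$translation <- unname(refs[[1]]$genes)
  rules <- parse_rules(
    "RULE d CATEGORY demo CUTOFF 10 NEIGHBOURHOOD 5 CONDITIONS P")
  rs <- detect_regions(record, mk_hits(list("a", "P", 60)), rules)
  sim <- region_similarity(rs$regions[[1]], record, refs)
  expect_equal(sim$cluster_id[1], "refcluster_1")
  expect_equal(sim$similarity_percent[1], 100)
  expect_equal(sim$confidence[1], "high")
})
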