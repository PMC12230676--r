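two_gene_rule <- parse_rules(
  "RULE ab CATEGORY demo CUTOFF 10 NEIGHBOURHOOD 5 CONDITIONS A and B")[[1]]

test_that("two genes within the cutoff form one protocluster", {
  record <- mk_record(40000, "linear",
                      list(gA = c(1000, 2000), gB = c(7000, 8000)))
  hits <- mk_hits(list("gA", "A"), list("gB", "B"))
  pcs <- form_protoclusters(record, hits, two_gene_rule)
  expect_length(pcs, 1)
  expect_equal(pcs[[1]]$core_cds_ids, c("gA", "gB"))
  expect_equal(pcs[[1]]$core_location$start, 1000L)
  expect_equal(pcs[[1]]$core_location$end, 8000L)
  expect_equal(pcs[[1]]$full_location$start, 0L)     # clamped at contig start
  expect_equal(pcs[[1]]$full_location$end, 13000L)
})

test_that("genes beyond the cutoff never satisfy a joint condition", {
  record <- mk_record(40000, "linear",
                      list(gA = c(1000, 2000), gB = c(17500, 18500)))
  hits <- mk_hits(list("gA", "A"), list("gB", "B"))
  expect_length(form_protoclusters(record, hits, two_gene_rule), 0)
})

test_that("a cluster flanking the origin of a circular contig is detected whole", {
  record <- mk_record(50000, "circular",
                      list(gA = c(48000, 49000), gB = c(1000, 2000)))
  hits <- mk_hits(list("gA", "A"), list("gB", "B"))
  pcs <- form_protoclusters(record, hits, two_gene_rule)
  expect_length(pcs, 1)
  core <- pcs[[1]]$core_location
  expect_true(core$crosses_origin)
  expect_equal(core$start, 48000L)
  expect_equal(core$end, 2000L)
  # the same layout rotated to the middle of the contig gives the same
  # covered set (rotated back)
  rot <- 25000L
  pcs2 <- form_protoclusters(rotate_record(record, rot), hits, two_gene_rule)
  expect_setequal(
    (loc_positions(pcs2[[1]]$core_location) - rot) %% 50000L,
    loc_positions(core))
})

test_that("protocluster formation matches the exhaustive subset oracle", {
  rules <- oracle_rule_pool()
  n_cases <- 60
  for (case_i in seq_len(n_cases)) {
    topo <- if (case_i %% 2 == 0) "circular" else "linear"
    case <- random_case(seed = 9000 + case_i, topology = topo)
    if (nrow(case$hits) == 0) next
    for (rule in rules) {
      got <- form_protoclusters(case$record, case$hits, rule)
      # engine sees only rule-relevant hits, mirror that for the oracle
      rel <- case$hits[case$hits$profile_name %in%
                         bgcscout:::condition_profiles(rule$conditions), ,
                       drop = FALSE]
      want <- oracle_protoclusters(case$record, rel, rule)
      expect_length(got, length(want))
      if (length(want) > 0) {
        got_cores <- lapply(got, function(p) p$core_cds_ids)
        want_cores <- lapply(want, function(sub) {
          sort(oracle_core_ids(rule$conditions,
                               rel[rel$cds_id %in% sub, , drop = FALSE]))
        })
        key <- function(l) paste(vapply(l, paste, character(1), collapse = ","))
        expect_setequal(key(got_cores), key(want_cores))
      }
    }
  }
})

# --- EXTENDS ----------------------------------------------------------------

tat_rule <- parse_rules(paste(
  "RULE tat CATEGORY transAT CUTOFF 10 NEIGHBOURHOOD 5",
  "  CONDITIONS AT and minscore(KS, 100)",
  "  EXTENDS KS", sep = "\n"))[[1]]

tat_record_hits <- function(gaps_kb = c(9, 8, 8, 8)) {
  # atA, ksM (high-scoring KS), then chained low-scoring KS genes
  starts <- cumsum(c(1000, 1000 + gaps_kb * 1000))
  cds <- lapply(starts, function(s) c(s, s + 1000))
  names(cds) <- c("atA", "ksM", paste0("ks", seq_along(gaps_kb[-1])))
  record <- mk_record(100000, "linear", cds)
  hits <- mk_hits(list("atA", "AT", 150), list("ksM", "KS", 120),
                  list("ks1", "KS", 50), list("ks2", "KS", 55),
                  list("ks3", "KS", 52))
  list(record = record, hits = hits)
}

test_that("EXTENDS absorbs a module gene within cutoff of the core", {
  x <- tat_record_hits(gaps_kb = c(9, 8, 20, 20))  # only ks1 reachable
  pcs <- form_protoclusters(x$record, x$hits, tat_rule)
  expect_equal(pcs[[1]]$core_cds_ids, c("atA", "ksM"))
  grown <- apply_extends(pcs[[1]], x$record, x$hits, tat_rule)
  expect_equal(grown$core_cds_ids, c("atA", "ks1", "ksM"))
})

test_that("chained module genes are absorbed to the fixpoint", {
  x <- tat_record_hits(gaps_kb = c(9, 8, 8, 8))
  pcs <- form_protoclusters(x$record, x$hits, tat_rule)
  expect_equal(pcs[[1]]$core_cds_ids, c("atA", "ksM"))
  grown <- apply_extends(pcs[[1]], x$record, x$hits, tat_rule)
  expect_equal(grown$core_cds_ids, c("atA", "ks1", "ks2", "ks3", "ksM"))
  # core and full locations were recomputed
  expect_equal(grown$core_location$end,
               cds_location(x$record, "ks3")$end)
  expect_equal(grown$full_location$end,
               cds_location(x$record, "ks3")$end + 5000L)
})

test_that("an extends gene beyond the cutoff leaves the cluster unchanged", {
  x <- tat_record_hits(gaps_kb = c(9, 12, 8, 8))  # ks1 sits 12 kb away
  pcs <- form_protoclusters(x$record, x$hits, tat_rule)
  grown <- apply_extends(pcs[[1]], x$record, x$hits, tat_rule)
  expect_equal(grown$core_cds_ids, pcs[[1]]$core_cds_ids)
  expect_true(loc_identical(grown$full_location, pcs[[1]]$full_location))
})

# --- region merging ---------------------------------------------------------

test_that("disjoint and overlapping protoclusters merge as documented", {
  record <- mk_record(100000, "linear", list(
    t1 = c(5000, 6000), n1 = c(12000, 13000), far = c(70000, 71000)))
  rules <- parse_rules(paste(
    "RULE terp CATEGORY terpene CUTOFF 10 NEIGHBOURHOOD 10 CONDITIONS TPS",
    "RULE nrps CATEGORY NRPS CUTOFF 10 NEIGHBOURHOOD 10 CONDITIONS AMP",
    "RULE sid CATEGORY siderophore CUTOFF 5 NEIGHBOURHOOD 5 CONDITIONS IUC",
    sep = "\n"))
  hits <- mk_hits(list("t1", "TPS"), list("n1", "AMP"), list("far", "IUC"))
  rs <- detect_regions(record, hits, rules)
  expect_length(rs$regions, 2)
  # overlapping terpene + NRPS neighbourhoods merged into one region
  expect_setequal(region_products(rs$regions[[1]]), c("terpene", "NRPS"))
  expect_length(rs$regions[[1]]$protoclusters, 2)
  expect_equal(region_products(rs$regions[[2]]), "siderophore")
  expect_equal(vapply(rs$regions, function(r) r$region_number, integer(1)),
               1:2)
})

test_that("merging is idempotent and independent of protocluster order", {
  record <- mk_record(60000, "circular", list(
    a = c(1000, 2000), b = c(9000, 10000), c = c(30000, 31000)))
  rules <- parse_rules(paste(
    "RULE r1 CATEGORY p1 CUTOFF 10 NEIGHBOURHOOD 10 CONDITIONS A",
    "RULE r2 CATEGORY p2 CUTOFF 10 NEIGHBOURHOOD 10 CONDITIONS B",
    "RULE r3 CATEGORY p3 CUTOFF 10 NEIGHBOURHOOD 10 CONDITIONS C",
    sep = "\n"))
  hits <- mk_hits(list("a", "A"), list("b", "B"), list("c", "C"))
  pcs <- unlist(lapply(rules, function(r) {
    form_protoclusters(record, hits, r)
  }), recursive = FALSE)
  base <- merge_regions(pcs, record)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    again <- merge_regions(pcs[perm], record)
    expect_equal(tidy(again), tidy(base))
  }
})

test_that("protoclusters flanking the origin merge into one wrapped region", {
  record <- mk_record(50000, "circular", list(
    gA = c(47000, 48000), gB = c(2000, 3000)))
  rules <- parse_rules(paste(
    "RULE rA CATEGORY pA CUTOFF 5 NEIGHBOURHOOD 3 CONDITIONS A",
    "RULE rB CATEGORY pB CUTOFF 5 NEIGHBOURHOOD 3 CONDITIONS B", sep = "\n"))
  hits <- mk_hits(list("gA", "A"), list("gB", "B"))
  rs <- detect_regions(record, hits, rules)
  # neighbourhoods [44k,1k) and [49k,6k) overlap across the origin
  expect_length(rs$regions, 1)
  expect_true(rs$regions[[1]]$location$crosses_origin)
  expect_equal(rs$regions[[1]]$location$start, 44000L)
  expect_equal(rs$regions[[1]]$location$end, 6000L)
  # the rotation-to-linear oracle agrees: rotating the record so nothing
  # wraps yields the same covered set rotated back
  rot <- 25000L
  rs2 <- detect_regions(rotate_record(record, rot), hits, rules)
  expect_length(rs2$regions, 1)
  expect_setequal(
    (loc_positions(rs2$regions[[1]]$location) - rot) %% 50000L,
    loc_positions(rs$regions[[1]]$location))
})

test_that("detection is deterministic and rotation-equivariant on random genomes", {
  rules <- oracle_rule_pool()
  for (case_i in 1:25) {
    case <- random_case(seed = 5000 + case_i, topology = "circular")
    base <- detect_regions(case$record, case$hits, rules)
    expect_equal(detect_regions(case$record, case$hits, rules), base)
    base_sets <- region_position_sets(base)
    for (r in c(500L, 1471L, 2900L)) {
      rotated <- detect_regions(rotate_record(case$record, r), case$hits, rules)
      expect_equal(region_position_sets(rotated, rotate_back = r), base_sets)
    }
  }
})

test_that("a merged azole rule fires on the union of the two old rules' instances", {
  merged <- parse_rules(paste(
    "RULE azole-containing-RiPPs CATEGORY azoleRiPP CUTOFF 10 NEIGHBOURHOOD 10",
    "  CONDITIONS YcaO and (macro or dehydro)", sep = "\n"))
  old <- parse_rules(paste(
    "RULE thiopeptide CATEGORY thiopeptide CUTOFF 10 NEIGHBOURHOOD 10",
    "  CONDITIONS YcaO and macro",
    "RULE linear-azole CATEGORY lap CUTOFF 10 NEIGHBOURHOOD 10",
    "  CONDITIONS YcaO and dehydro", sep = "\n"))
  # three instance layouts: thiopeptide-like, LAP-like, and neither
  layouts <- list(
    list(hits = mk_hits(list("g1", "YcaO"), list("g2", "macro"))),
    list(hits = mk_hits(list("g1", "YcaO"), list("g2", "dehydro"))),
    list(hits = mk_hits(list("g1", "YcaO")))
  )
  record <- mk_record(30000, "linear", list(g1 = c(1000, 2000),
                                            g2 = c(4000, 5000)))
  for (lay in layouts) {
    fired_old <- length(form_protoclusters(record, lay$hits, old[[1]])) +
      length(form_protoclusters(record, lay$hits, old[[2]])) > 0
    fired_new <- length(form_protoclusters(record, lay$hits, merged[[1]])) > 0
    expect_equal(fired_new, fired_old)
  }
})
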