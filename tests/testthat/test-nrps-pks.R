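dom <- function(kind, cds = "g1", start = 0, end = start + 50, score = 50) {
  tibble::tibble(cds_id = cds, domain_kind = kind, ali_start = as.integer(start),
                 ali_end = as.integer(end), bitscore = score)
}
dom_seq <- function(kinds, cds = "g1") {
  dplyr::bind_rows(lapply(seq_along(kinds), function(i) {
    dom(kinds[i], cds, start = (i - 1) * 100)
  }))
}

test_that("a CAL-loaded starter plus an extending module assemble as traced", {
  mods <- assemble_modules(dom_seq(c("CAL", "CP", "C", "A", "CP", "TE")))
  expect_equal(nrow(mods), 2)
  expect_equal(mods$role, c("starter", "extender"))
  expect_true(all(mods$complete))
  expect_equal(mods$domains[[1]]$domain_kind, c("CAL", "CP"))
  # the thioesterase attaches to the final module as termination
  expect_equal(mods$domains[[2]]$domain_kind, c("C", "A", "CP", "TE"))
})

test_that("degenerate domain lists form the documented modules", {
  # a bare A+CP pair is a complete starter
  mods <- assemble_modules(dom_seq(c("A", "CP")))
  expect_equal(mods$role, "starter")
  expect_true(mods$complete)
  # C+A without a carrier protein stays incomplete
  mods2 <- assemble_modules(dom_seq(c("C", "A")))
  expect_equal(mods2$role, "incomplete")
  expect_false(mods2$complete)
  expect_equal(nrow(assemble_modules(dom_seq(character(0)))), 0)
})

test_that("modification and interface domains ride along inside modules", {
  mods <- assemble_modules(dom_seq(
    c("C", "A", "KR", "BETA_HYDROXYLASE", "INTERFACE", "CP",
      "KS", "AT", "DH", "ER", "CP", "AB_HYDROLASE")))
  expect_equal(nrow(mods), 2)
  expect_equal(mods$domains[[1]]$domain_kind,
               c("C", "A", "KR", "BETA_HYDROXYLASE", "INTERFACE", "CP"))
  expect_equal(mods$domains[[2]]$domain_kind,
               c("KS", "AT", "DH", "ER", "CP", "AB_HYDROLASE"))
})

test_that("module assembly is a stable partition of its input", {
  set.seed(303)
  kinds_pool <- c("A", "C", "E", "KS", "AT", "KR", "DH", "ER", "CP", "TE",
                  "CAL", "BETA_HYDROXYLASE", "INTERFACE", "AB_HYDROLASE")
  for (i in 1:40) {
    kinds <- sample(kinds_pool, sample(1:12, 1), replace = TRUE)
    domains <- dom_seq(kinds)
    mods <- assemble_modules(domains)
    flat <- dplyr::bind_rows(mods$domains)
    # partition: every domain in exactly one module
    expect_equal(nrow(flat), nrow(domains))
    # stability: concatenating modules reproduces the input order
    expect_equal(flat$ali_start, domains$ali_start)
  }
})

test_that("overlapping domain annotations keep the higher bitscore", {
  profiles <- tibble::tibble(
    profile_name = c("ksA", "ksB", "other"),
    bitscore_cutoff = 0, description = "", category = "x",
    domain_kind = c("KS", "AT", NA))
  hits <- tibble::tibble(
    cds_id = "g1", profile_name = c("ksA", "ksB", "other"),
    bitscore = c(80, 60, 99), evalue = 0,
    ali_start = c(0L, 30L, 0L), ali_end = c(100L, 90L, 10L))
  doms <- domains_from_hits(hits, profiles)
  expect_equal(nrow(doms), 1)  # overlap resolved, unmapped profile dropped
  expect_equal(doms$domain_kind, "KS")
})

test_that("cross-gene domain order follows the region arc", {
  record <- mk_record(50000, "circular",
                      list(gB = c(1000, 4000), gA = c(47000, 49000)))
  domains <- dplyr::bind_rows(dom("CAL", "gA"), dom("CP", "gA", 100),
                              dom("C", "gB"), dom("A", "gB", 100),
                              dom("CP", "gB", 200))
  region <- list(region_number = 1L,
                 location = bgc_location(46000, 5000, 50000, TRUE),
                 protoclusters = list())
  ordered <- order_cluster_domains(domains, record, region)
  # gA starts the arc even though its coordinate is larger
  expect_equal(ordered$cds_id, c("gA", "gA", "gB", "gB", "gB"))
  mods <- assemble_modules(ordered)
  expect_equal(mods$role, c("starter", "extender"))
})

test_that("active-site checks find and miss catalytic residues", {
  specs <- fixture_motif_specs()
  base <- strrep("G", 200)
  with_motif <- paste0(substr(base, 1, 30), "HHILADG", substr(base, 38, 200))
  d <- dom("C", start = 0, end = 150)
  res <- check_active_site(d[1, ], with_motif, specs)
  expect_true(res$active)
  expect_equal(res$observed, "HHILADG")
  # the second histidine is catalytic: H->Q inactivates
  broken <- sub("HHILADG", "HQILADG", with_motif)
  res2 <- check_active_site(d[1, ], broken, specs)
  expect_false(res2$active)
  expect_true(res2$window_ok)
})

test_that("the motif is still found anywhere within the slack window", {
  specs <- fixture_motif_specs()
  base <- strrep("G", 200)
  d <- dom("C", start = 0, end = 150)
  for (offset in c(20, 25, 30, 35, 40)) {  # window_offset 30, slack 10
    tr <- paste0(substr(base, 1, offset), "HHILADG",
                 substr(base, offset + 8, 200))
    expect_true(check_active_site(d[1, ], tr, specs)$active)
  }
  # far outside the window: not found
  far <- paste0(substr(base, 1, 120), "HHILADG", substr(base, 128, 200))
  expect_false(check_active_site(d[1, ], far, specs)$active)
})

test_that("a window outside the translation is flagged, not an error", {
  specs <- fixture_motif_specs()
  d <- dom("E", start = 500, end = 600)
  res <- check_active_site(d[1, ], strrep("A", 100), specs)
  expect_false(res$active)
  expect_false(res$window_ok)
})

test_that("substrate-predictor links embed the domain sequence", {
  tr <- paste0(strrep("M", 100), strrep("K", 400), strrep("L", 100))
  d <- dom("A", start = 100, end = 500)
  url <- paras_link(d[1, ], tr)
  expect_match(url, "^https://")
  expect_match(url, strrep("K", 400), fixed = TRUE)
  d2 <- dom("A", start = 0, end = 100)
  expect_false(identical(paras_link(d2[1, ], tr), url))
  expect_error(paras_link(dom("C")[1, ], tr), "A domains")
  expect_error(paras_link(d[1, ], ""), "empty")
})
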