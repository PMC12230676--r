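# Deterministic synthetic fixtures: toy genomes with planted clusters
# (including origin-spanning ones), matching hit tables, rule files,
# annotation tables and reference sets with known ground truth, so the
# whole pipeline is testable without any database download. Identical
# seeds give identical bytes; ground truth depends only on the planted
# layout, never on the random filler.

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Run code with a temporarily seeded RNG, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_protein <- function(n) {
  paste0("M", paste(sample(aa_alphabet, n - 1L, replace = TRUE), collapse = ""))
}

random_dna <- function(n) {
  paste(sample(c("a", "c", "g", "t"), n, replace = TRUE), collapse = "")
}

# For each amino acid, a conservative partner with non-negative BLOSUM62
# score (except proline, whose best non-self score is -1). Substituting
# with these keeps the gapless diagonal alignment optimal, so the percent
# identity of a substitution-only pair is exactly (n - k) / n * 100.
conservative_partner <- c(
  A = "S", R = "K", N = "D", D = "E", C = "A", Q = "E", E = "D", G = "A",
  H = "Y", I = "V", L = "I", K = "R", M = "L", F = "Y", P = "A", S = "T",
  T = "S", W = "Y", Y = "F", V = "I"
)

#' Mutate a protein to an exact percent identity
#'
#' Substitutes `n_substitutions` positions with conservative replacement
#' residues (similar amino acids under BLOSUM62), which keeps the global
#' alignment gapless, so the identity under [pairwise_identity()] is
#' exactly `(n - k) / n * 100`. Used to construct sequence pairs that
#' bracket identity thresholds precisely.
#'
#' @param sequence Amino-acid string.
#' @param n_substitutions Number of positions to substitute.
#' @return The mutated sequence.
#' @export
mutate_exact_identity <- function(sequence, n_substitutions) {
  n <- nchar(sequence)
  if (n_substitutions > n) stop("more substitutions than positions")
  chars <- strsplit(sequence, "")[[1]]
  pos <- sample(n, n_substitutions)
  chars[pos] <- conservative_partner[chars[pos]]
  paste(chars, collapse = "")
}

#' Mutate a protein towards a target percent identity
#'
#' Applies point substitutions only (no indels), so the identity under
#' the package's global-alignment formula is directly controllable; the
#' result is verified against the formula and adjusted until it falls
#' within `tolerance` percentage points of the target.
#'
#' @param sequence Amino-acid string.
#' @param target_identity Desired percent identity to the input.
#' @param tolerance Acceptable deviation in percentage points.
#' @return The mutated sequence, with attribute `measured_identity`.
#' @export
mutate_to_identity <- function(sequence, target_identity, tolerance = 2) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  k <- max(0L, min(n, round(n * (1 - target_identity / 100))))
  build <- function(k) {
    out <- chars
    if (k > 0) {
      pos <- sample(n, k)
      out[pos] <- vapply(out[pos], function(orig) {
        sample(setdiff(aa_alphabet, orig), 1)
      }, character(1))
    }
    paste(out, collapse = "")
  }
  mut <- build(k)
  measured <- pairwise_identity(sequence, mut)
  iter <- 0L
  while (abs(measured - target_identity) > tolerance && iter < 30L) {
    k <- k + if (measured > target_identity) 1L else -1L
    k <- max(0L, min(n, k))
    mut <- build(k)
    measured <- pairwise_identity(sequence, mut)
    iter <- iter + 1L
  }
  attr(mut, "measured_identity") <- measured
  mut
}

# ---- fixture annotation tables ---------------------------------------------

#' Built-in fixture profile metadata
#' @return Tibble under the [read_profile_meta()] contract.
#' @export
fixture_profiles <- function() {
  tribble_args <- list(
    # profile_name, cutoff, description, category, domain_kind
    c("terpene_synthase_C10", "25", "monoterpene synthase family", "terpene_synthase", NA),
    c("terpene_synthase_C15", "25", "sesquiterpene synthase family", "terpene_synthase", NA),
    c("terpene_synthase_C20", "25", "diterpene synthase family", "terpene_synthase", NA),
    c("geosmin_synthase_like", "50", "germacradienol/geosmin synthase subfamily", "terpene_synthase", NA),
    c("squalene_hopene_cyclase", "30", "squalene-hopene cyclase", "terpene_synthase", NA),
    c("Condensation", "20", "NRPS condensation domain", "nrps_domain", "C"),
    c("Epimerization", "20", "NRPS epimerization domain", "nrps_domain", "E"),
    c("AMP-binding", "20", "NRPS adenylation domain", "nrps_domain", "A"),
    c("PP-binding", "15", "phosphopantetheine carrier domain", "nrps_domain", "CP"),
    c("Thioesterase", "20", "thioesterase domain", "nrps_domain", "TE"),
    c("CAL_domain", "20", "CoA-ligase starter domain", "nrps_domain", "CAL"),
    c("PKS_KS", "25", "polyketide ketosynthase domain", "pks_domain", "KS"),
    c("PKS_AT", "25", "polyketide acyltransferase domain", "pks_domain", "AT"),
    c("PKS_KR", "20", "polyketide ketoreductase domain", "pks_domain", "KR"),
    c("PKS_DH", "20", "polyketide dehydratase domain", "pks_domain", "DH"),
    c("PKS_ER", "20", "polyketide enoylreductase domain", "pks_domain", "ER"),
    c("beta_hydroxylase", "20", "siderophore-associated beta-hydroxylase", "nrps_domain", "BETA_HYDROXYLASE"),
    c("interface_domain", "20", "siderophore synthetase interface domain", "nrps_domain", "INTERFACE"),
    c("ab_hydrolase", "20", "generic alpha/beta-hydrolase", "nrps_domain", "AB_HYDROLASE"),
    c("YcaO", "25", "azole-forming cyclodehydratase", "ripp", NA),
    c("thiopep_macrocyclase", "25", "thiopeptide macrocyclase", "ripp", NA),
    c("azole_dehydrogenase", "25", "azoline dehydrogenase", "ripp", NA),
    c("IucA_IucC", "30", "NRPS-independent siderophore synthetase", "siderophore", NA),
    c("flavin_halogenase", "25", "flavin-dependent halogenase", "halogenase", NA),
    c("p450", "25", "cytochrome P450 monooxygenase", "tailoring", NA),
    c("glycosyltransferase", "25", "glycosyltransferase", "tailoring", NA),
    c("methyltransferase", "25", "SAM-dependent methyltransferase", "tailoring", NA),
    c("smcog_oxidoreductase", "15", "smCOG-style generic oxidoreductase", "smcog", NA),
    c("motif_precursor", "10", "dynamic profile: short precursor with core motif", "ripp", NA)
  )
  m <- do.call(rbind, tribble_args)
  tibble::tibble(
    profile_name = m[, 1],
    bitscore_cutoff = as.numeric(m[, 2]),
    description = m[, 3],
    category = m[, 4],
    domain_kind = m[, 5]
  )
}

#' Built-in fixture detection rules (DSL text)
#' @return Character scalar of rule DSL source.
#' @export
fixture_rules_text <- function() {
  paste(
    "# fixture detection rules",
    "RULE terpene CATEGORY terpene CUTOFF 20 NEIGHBOURHOOD 10",
    "  CONDITIONS terpene_synthase_C10 or terpene_synthase_C15 or terpene_synthase_C20 or geosmin_synthase_like or squalene_hopene_cyclase",
    "RULE NRPS-like CATEGORY NRPS CUTOFF 20 NEIGHBOURHOOD 20",
    "  CONDITIONS (Condensation or CAL_domain) and AMP-binding and PP-binding",
    "RULE transAT-PKS CATEGORY transAT-PKS CUTOFF 10 NEIGHBOURHOOD 20",
    "  CONDITIONS PKS_AT and minscore(PKS_KS, 100)",
    "  EXTENDS PKS_KS",
    "RULE azole-containing-RiPPs CATEGORY azole-containing-RiPPs CUTOFF 10 NEIGHBOURHOOD 10",
    "  CONDITIONS YcaO and (thiopep_macrocyclase or azole_dehydrogenase)",
    "RULE siderophore CATEGORY siderophore CUTOFF 5 NEIGHBOURHOOD 5",
    "  CONDITIONS IucA_IucC",
    "RULE halogenase-demo CATEGORY halogenated CUTOFF 10 NEIGHBOURHOOD 5",
    "  CONDITIONS minimum(2, [flavin_halogenase, p450, glycosyltransferase])",
    sep = "\n"
  )
}

#' Built-in fixture detection rules (parsed)
#' @return List of `bgc_rule` objects.
#' @export
fixture_rules <- function() parse_rules(fixture_rules_text())

#' Built-in fixture terpene subfamily table
#' @return Tibble under the [read_terpene_table()] contract.
#' @export
fixture_terpene_table <- function() {
  tibble::tibble(
    profile_name = c("terpene_synthase_C10", "terpene_synthase_C15",
                     "terpene_synthase_C20", "terpene_synthase_C25",
                     "terpene_synthase_C30", "terpene_synthase_C40",
                     "indole_diterpene_synthase", "squalene_hopene_cyclase",
                     "pentalenene_synthase_like", "geosmin_synthase_like"),
    terpenoid_class = c("monoterpene", "sesquiterpene", "diterpene",
                        "sesterterpene", "triterpene", "tetraterpene",
                        "diterpene", "triterpene", "sesquiterpene",
                        "sesquiterpene"),
    chain_length = c(10L, 15L, 20L, 25L, 30L, 40L, 20L, 30L, 15L, 15L),
    subclass = c(NA, NA, NA, NA, NA, NA, "indole diterpenoid", "hopanoid",
                 "pentalenene-type", "eudesmane-type"),
    cyclization = c(NA, NA, NA, NA, NA, NA, NA, NA, "C1-C11", "C1-C10"),
    products = c(NA, NA, NA, NA, NA, NA, NA, "hopene", "pentalenene",
                 "germacradienol;geosmin"),
    specificity_rank = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L)
  )
}

#' Built-in fixture tailoring profile map
#' @return Tibble under the [read_tailoring_map()] contract.
#' @export
fixture_tailoring_map <- function() {
  tibble::tibble(
    profile_name = c("p450", "flavin_halogenase", "glycosyltransferase",
                     "methyltransferase", "smcog_oxidoreductase"),
    ec_category = c("oxidoreductases", "transferases", "transferases",
                    "transferases", "oxidoreductases"),
    prediction_text = c("cytochrome P450 monooxygenase",
                        "flavin-dependent halogenase",
                        "glycosyltransferase",
                        "SAM-dependent methyltransferase",
                        "smCOG: generic oxidoreductase"),
    detail_rank = c(2L, 1L, 2L, 2L, 0L),
    source = c("profile", "profile", "profile", "profile", "smcog")
  )
}

#' Built-in fixture halogenase signature table
#' @return Tibble under the [read_halogenase_signatures()] contract.
#' @export
fixture_halogenase_signatures <- function() {
  tibble::tibble(
    motif_name = c("trp6_signature", "trp7_signature", "pyrrole_signature"),
    pattern = c("GWTWS[IV]DS", "FTPWYE[LM]K", "CPYCGG"),
    prediction_text = c(
      "tryptophan halogenase, C6 regioselectivity",
      "tryptophan halogenase, C7 regioselectivity",
      "halogenated pyrrole"),
    detail_rank = c(3L, 3L, 2L)
  )
}

#' Built-in fixture active-site motif specifications
#' @return Tibble under the [read_motif_specs()] contract.
#' @export
fixture_motif_specs <- function() {
  tibble::tibble(
    domain_kind = c("C", "E"),
    motif_name = c("C-domain catalytic core", "E-domain catalytic core"),
    pattern = c("HH[ILV].{2}DG", "HH[ILV].{2}DG"),
    window_offset = c(30L, 30L),
    window_slack = c(10L, 10L)
  )
}

#' Write all fixture annotation tables plus the rule file to a directory
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_fixture_tables <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    rules = file.path(dir, "rules.txt"),
    profiles = file.path(dir, "profiles.tsv"),
    terpene_table = file.path(dir, "terpene_table.tsv"),
    tailoring_map = file.path(dir, "tailoring_map.tsv"),
    halogenase_signatures = file.path(dir, "halogenase_signatures.tsv"),
    motif_specs = file.path(dir, "motif_specs.tsv")
  )
  writeLines(fixture_rules_text(), paths$rules)
  readr::write_tsv(fixture_profiles(), paths$profiles, progress = FALSE)
  readr::write_tsv(fixture_terpene_table(), paths$terpene_table, progress = FALSE)
  readr::write_tsv(fixture_tailoring_map(), paths$tailoring_map, progress = FALSE)
  readr::write_tsv(fixture_halogenase_signatures(), paths$halogenase_signatures,
                   progress = FALSE)
  readr::write_tsv(fixture_motif_specs(), paths$motif_specs, progress = FALSE)
  paths
}

# ---- planted clusters ------------------------------------------------------

#' Describe a planted cluster
#'
#' A planted cluster is a gene layout plus the profile hits each gene
#' should receive; together with the paired rule's neighbourhood distance
#' it determines the expected detected region in closed form.
#'
#' @param category Product category of the paired rule.
#' @param cds Tibble with columns `name`, `aa_len`, `gap_after` (nt to the
#'   next gene), `is_core`, `hits` (list of tibbles with `profile_name`,
#'   `bitscore` and optional `ali_start`/`ali_end`) and optional
#'   `translation`.
#' @param neighbourhood_nt Neighbourhood distance of the paired rule.
#' @param expected Optional list of extra expectations (module roles,
#'   tailoring category counts, ...), copied into the truth.
#' @return A `bgc_planted_cluster`.
#' @export
planted_cluster <- function(category, cds, neighbourhood_nt, expected = list()) {
  if (!"translation" %in% names(cds)) cds$translation <- NA_character_
  structure(list(category = category, cds = cds,
                 neighbourhood_nt = as.integer(neighbourhood_nt),
                 expected = expected),
            class = "bgc_planted_cluster")
}

hit_spec <- function(profile_name, bitscore, ali_start = NA, ali_end = NA) {
  tibble::tibble(profile_name = profile_name, bitscore = bitscore,
                 ali_start = as.integer(ali_start), ali_end = as.integer(ali_end))
}

# Translation with the C-domain catalytic motif (or a broken variant)
# placed at the expected active-site window.
nrps_c_translation <- function(aa_len, motif_at, motif = "HHILADG") {
  base <- random_protein(aa_len)
  paste0(substr(base, 1, motif_at), motif,
         substr(base, motif_at + nchar(motif) + 1L, aa_len))
}

#' Prebuilt planted clusters
#'
#' Each builder returns a `bgc_planted_cluster` matching one fixture rule:
#' a geosmin-like terpene cluster, a two-gene NRPS with starter and
#' termination modules, a trans-AT PKS with a distant trans-acting AT and
#' chained module genes, an azole-containing RiPP pair, a single-gene
#' siderophore synthetase and a tailoring-rich halogenase demo cluster.
#' Builders draw random translations, so call them inside a seeded
#' context (see [generate_genome()]).
#'
#' @name planted_fixtures
NULL

#' @rdname planted_fixtures
#' @export
fixture_planted_terpene <- function() {
  planted_cluster(
    category = "terpene",
    cds = tibble::tibble(
      name = c("geoA"),
      aa_len = c(720L),
      gap_after = c(0L),
      is_core = c(TRUE),
      hits = list(dplyr::bind_rows(
        hit_spec("geosmin_synthase_like", 310, 0, 700),
        hit_spec("terpene_synthase_C15", 120, 0, 330)
      ))
    ),
    neighbourhood_nt = 10000L,
    expected = list(terpene_products = c("germacradienol", "geosmin"))
  )
}

#' @rdname planted_fixtures
#' @export
fixture_planted_nrps <- function() {
  planted_cluster(
    category = "NRPS",
    cds = tibble::tibble(
      name = c("nrpsA", "nrpsB"),
      aa_len = c(500L, 1100L),
      gap_after = c(400L, 0L),
      is_core = c(TRUE, TRUE),
      hits = list(
        dplyr::bind_rows(
          hit_spec("CAL_domain", 180, 0, 400),
          hit_spec("PP-binding", 60, 420, 490)
        ),
        dplyr::bind_rows(
          hit_spec("Condensation", 210, 0, 300),
          hit_spec("AMP-binding", 330, 310, 800),
          hit_spec("PP-binding", 60, 820, 890),
          hit_spec("Thioesterase", 140, 900, 1080)
        )
      ),
      # the condensation domain carries its catalytic HHxxxDG motif at the
      # expected active-site window (alignment start + 30 aa)
      translation = c(NA_character_, nrps_c_translation(1100L, 30L))
    ),
    neighbourhood_nt = 20000L,
    expected = list(module_roles = c("starter", "extender"),
                    module_complete = c(TRUE, TRUE))
  )
}

#' @rdname planted_fixtures
#' @export
fixture_planted_transat <- function() {
  # the trans-acting AT gene sits 9 kb from the first module gene; three
  # further module genes follow at 8 kb gaps, each only reachable through
  # the EXTENDS fixpoint (their KS bitscores sit below the rule's
  # minscore threshold, so they never mark cores on their own)
  planted_cluster(
    category = "transAT-PKS",
    cds = tibble::tibble(
      name = c("tatAT", "ksM", "ks1", "ks2", "ks3"),
      aa_len = c(400L, 1000L, 900L, 900L, 900L),
      gap_after = c(9000L, 8000L, 8000L, 8000L, 0L),
      is_core = c(TRUE, TRUE, TRUE, TRUE, TRUE),
      hits = list(
        hit_spec("PKS_AT", 150, 0, 380),
        dplyr::bind_rows(
          hit_spec("PKS_KS", 180, 0, 430),
          hit_spec("PP-binding", 60, 900, 980)
        ),
        dplyr::bind_rows(
          hit_spec("PKS_KS", 55, 0, 430),
          hit_spec("PP-binding", 60, 800, 880)
        ),
        dplyr::bind_rows(
          hit_spec("PKS_KS", 52, 0, 430),
          hit_spec("PP-binding", 60, 800, 880)
        ),
        dplyr::bind_rows(
          hit_spec("PKS_KS", 58, 0, 430),
          hit_spec("PP-binding", 60, 800, 880)
        )
      )
    ),
    neighbourhood_nt = 20000L,
    expected = list(extends_core = c("ks1", "ks2", "ks3"),
                    base_core = c("ksM", "tatAT"))
  )
}

#' @rdname planted_fixtures
#' @export
fixture_planted_azole <- function() {
  planted_cluster(
    category = "azole-containing-RiPPs",
    cds = tibble::tibble(
      name = c("azoB", "azoC"),
      aa_len = c(450L, 320L),
      gap_after = c(300L, 0L),
      is_core = c(TRUE, TRUE),
      hits = list(
        hit_spec("YcaO", 190, 0, 440),
        hit_spec("azole_dehydrogenase", 95, 0, 300)
      )
    ),
    neighbourhood_nt = 10000L
  )
}

#' @rdname planted_fixtures
#' @export
fixture_planted_siderophore <- function() {
  planted_cluster(
    category = "siderophore",
    cds = tibble::tibble(
      name = "iucA",
      aa_len = 580L,
      gap_after = 0L,
      is_core = TRUE,
      hits = list(hit_spec("IucA_IucC", 250, 0, 560))
    ),
    neighbourhood_nt = 5000L
  )
}

#' @rdname planted_fixtures
#' @export
fixture_planted_halogenase <- function() {
  # balhimycin-style tailoring demo: four P450s, one tryptophan
  # halogenase whose translation carries the C6 regioselectivity motif,
  # one glycosyltransferase
  hal_tr <- function() {
    base <- random_protein(520L)
    paste0(substr(base, 1, 200), "GWTWSIDS", substr(base, 209, 520))
  }
  planted_cluster(
    category = "halogenated",
    cds = tibble::tibble(
      name = c("oxyA", "oxyB", "oxyC", "oxyD", "bhaA", "bgtfA"),
      aa_len = c(400L, 400L, 400L, 400L, 520L, 410L),
      gap_after = c(200L, 200L, 200L, 500L, 400L, 0L),
      is_core = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
      hits = list(
        hit_spec("p450", 140, 0, 390),
        hit_spec("p450", 150, 0, 390),
        hit_spec("p450", 135, 0, 390),
        hit_spec("p450", 160, 0, 390),
        hit_spec("flavin_halogenase", 180, 0, 500),
        hit_spec("glycosyltransferase", 120, 0, 400)
      ),
      translation = c(NA, NA, NA, NA, hal_tr(), NA)
    ),
    neighbourhood_nt = 5000L,
    expected = list(tailoring_counts = list(oxidoreductases = 4L,
                                            transferases = 2L))
  )
}

# ---- genome generation -----------------------------------------------------

#' Generate a synthetic genome with planted clusters
#'
#' Lays each planted cluster's genes sequentially from its `start`
#' position (wrapping on circular contigs), fills the rest of the contig
#' with seeded pseudo-random sequence, and derives the ground-truth
#' regions in closed form from the layout and each cluster's
#' neighbourhood distance. Identical seeds give identical output;
#' changing the seed changes the filler and translations but never the
#' truth regions. Overlapping layouts (including touching expected
#' regions, which would merge) are an error.
#'
#' @param seed Integer seed.
#' @param topology `"linear"` or `"circular"`.
#' @param planted Named list of `bgc_planted_cluster` objects; names are
#'   used as gene-id prefixes. `starts` gives each cluster's first-gene
#'   position.
#' @param starts Integer vector of start offsets, one per planted cluster.
#' @param length Contig length in nucleotides.
#' @param record_id Record identifier.
#' @param dir Optional output directory; when given, a GenBank file, hit
#'   TSV and truth JSON are written.
#' @return List with `record`, `hits`, `truth` and (when `dir` is given)
#'   `paths`.
#' @export
generate_genome <- function(seed, topology, planted, starts, length,
                            record_id = "FIXREC1", dir = NULL) {
  topology <- match.arg(topology, c("linear", "circular"))
  if (base::length(planted) != base::length(starts)) {
    stop("need one start per planted cluster")
  }
  L <- as.integer(length)
  with_seed(seed, {
    cds_rows <- list()
    truth_regions <- list()
    for (ci in seq_along(planted)) {
      pc <- planted[[ci]]
      prefix <- names(planted)[ci] %||% sprintf("c%d", ci)
      cur <- as.integer(starts[ci])
      core_start <- NA_integer_
      core_end_track <- NA_integer_  # unwrapped running coordinate
      track <- cur  # unwrapped layout cursor
      for (gi in seq_len(nrow(pc$cds))) {
        aa <- pc$cds$aa_len[gi]
        nt <- 3L * (aa + 1L)
        g_start_unwrapped <- track
        g_end_unwrapped <- track + nt
        if (g_end_unwrapped - as.integer(starts[ci]) > L) {
          stop("planted layout does not fit in contig length")
        }
        if (g_end_unwrapped > L && topology != "circular") {
          stop("planted layout runs past the end of a linear contig")
        }
        s <- g_start_unwrapped %% L
        e_excl <- g_end_unwrapped %% L
        crosses <- s + nt > L
        loc_end <- if (e_excl == 0L) L else e_excl
        translation <- pc$cds$translation[gi]
        if (is.na(translation)) translation <- random_protein(aa)
        cds_rows[[base::length(cds_rows) + 1L]] <- tibble::tibble(
          cds_id = paste0(prefix, "_", pc$cds$name[gi]),
          start = s, end = if (crosses) e_excl else loc_end,
          crosses_origin = crosses, strand = 1L,
          translation = translation,
          .cluster = ci, .hits = pc$cds$hits[gi]
        )
        if (pc$cds$is_core[gi]) {
          if (is.na(core_start)) core_start <- g_start_unwrapped
          core_end_track <- g_end_unwrapped
        }
        track <- g_end_unwrapped + pc$cds$gap_after[gi]
      }
      # closed-form expected region: core hull +/- neighbourhood
      full_start <- core_start - pc$neighbourhood_nt
      full_end <- core_end_track + pc$neighbourhood_nt
      if (topology == "linear") {
        full_start <- max(0L, full_start)
        full_end <- min(L, full_end)
        loc <- bgc_location(full_start, full_end, L)
      } else if (full_end - full_start >= L) {
        loc <- bgc_location(0L, L, L)
      } else {
        s <- full_start %% L
        len_full <- full_end - full_start
        loc <- if (s + len_full <= L) bgc_location(s, s + len_full, L)
               else bgc_location(s, s + len_full - L, L, crosses_origin = TRUE)
      }
      truth_regions[[ci]] <- list(
        start = loc$start, end = loc$end,
        crosses_origin = loc$crosses_origin,
        products = pc$category,
        expected = pc$expected
      )
    }
    cds <- dplyr::bind_rows(cds_rows)
    # reject overlapping gene layouts
    for (i in seq_len(nrow(cds))) {
      for (j in seq_len(nrow(cds))) {
        if (i < j && loc_overlaps(
          bgc_location(cds$start[i], cds$end[i], L, cds$crosses_origin[i]),
          bgc_location(cds$start[j], cds$end[j], L, cds$crosses_origin[j]))) {
          stop("planted layouts overlap: ", cds$cds_id[i], " and ", cds$cds_id[j])
        }
      }
    }
    # reject truth regions that would merge (keeps truth 1:1 with layout)
    if (base::length(truth_regions) > 1) {
      locs <- lapply(truth_regions, function(r) {
        bgc_location(r$start, r$end, L, r$crosses_origin)
      })
      for (i in seq_along(locs)) {
        for (j in seq_along(locs)) {
          if (i < j && circular_gap(locs[[i]], locs[[j]],
                                    circular = topology == "circular") == 0L) {
            stop("planted clusters ", i, " and ", j,
                 " would merge into one region; space them out")
          }
        }
      }
    }
    hits <- dplyr::bind_rows(lapply(seq_len(nrow(cds)), function(i) {
      h <- cds$.hits[[i]]
      if (is.null(h) || nrow(h) == 0) return(NULL)
      aa_n <- nchar(cds$translation[i])
      tibble::tibble(
        cds_id = cds$cds_id[i], profile_name = h$profile_name,
        bitscore = h$bitscore, evalue = 1e-20,
        ali_start = ifelse(is.na(h$ali_start), 0L, h$ali_start),
        ali_end = pmin(ifelse(is.na(h$ali_end), aa_n, h$ali_end), aa_n)
      )
    }))
    record <- bgc_record(record_id, L, topology,
                         cds[setdiff(names(cds), c(".cluster", ".hits"))],
                         sequence = random_dna(L))
    ord <- order(vapply(truth_regions, function(r) r$start, integer(1)))
    truth <- list(
      record_id = record_id, topology = topology, contig_length = L,
      regions = unname(truth_regions[ord])
    )
    out <- list(record = record, hits = hits, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        genbank = file.path(dir, paste0(record_id, ".gbk")),
        hits = file.path(dir, paste0(record_id, "_hits.tsv")),
        truth = file.path(dir, paste0(record_id, "_truth.json"))
      )
      write_genbank(record, paths$genbank)
      write_hit_table(hits, paths$hits)
      jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
      out$paths <- paths
    }
    out
  })
}

#' Generate a reference-cluster set with controlled query divergence
#'
#' Emits `n_clusters` reference clusters of random proteins plus, for
#' each divergence level, query translations mutated to the matching
#' identity target (substitutions only, verified post hoc against the
#' package identity formula within 2 percentage points).
#'
#' @param seed Integer seed.
#' @param n_clusters Number of reference clusters.
#' @param genes_per_cluster Genes per cluster.
#' @param divergence Numeric vector in `[0, 1]`: per-level fraction of
#'   diverged positions (0 means identical queries).
#' @param gene_aa Protein length in amino acids.
#' @param dir Optional directory: writes `index.tsv` plus one FASTA per
#'   cluster.
#' @return List with `clusters` (list of `bgc_reference_cluster`),
#'   `queries` (tibble: `cluster_id`, `gene_id`, `divergence`,
#'   `target_identity`, `measured_identity`, `sequence`) and `paths`.
#' @export
generate_reference_set <- function(seed, n_clusters = 2, genes_per_cluster = 4,
                                   divergence = c(0, 0.4), gene_aa = 300,
                                   dir = NULL) {
  if (any(divergence < 0 | divergence > 1)) {
    stop("divergence levels must be in [0, 1]")
  }
  with_seed(seed, {
    clusters <- lapply(seq_len(n_clusters), function(i) {
      genes <- stats::setNames(
        vapply(seq_len(genes_per_cluster), function(g) random_protein(gene_aa),
               character(1)),
        sprintf("ref%d_gene%d", i, seq_len(genes_per_cluster))
      )
      reference_cluster(sprintf("refcluster_%d", i),
                        sprintf("synthetic reference cluster %d", i), genes)
    })
    queries <- dplyr::bind_rows(lapply(clusters, function(cl) {
      dplyr::bind_rows(lapply(names(cl$genes), function(gid) {
        dplyr::bind_rows(lapply(divergence, function(d) {
          target <- 100 * (1 - d)
          mut <- mutate_to_identity(cl$genes[[gid]], target)
          tibble::tibble(
            cluster_id = cl$cluster_id, gene_id = gid, divergence = d,
            target_identity = target,
            measured_identity = attr(mut, "measured_identity"),
            sequence = as.character(mut))
        }))
      }))
    }))
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      index <- tibble::tibble(
        cluster_id = vapply(clusters, function(c) c$cluster_id, character(1)),
        display_name = vapply(clusters, function(c) c$display_name, character(1)),
        fasta = paste0(vapply(clusters, function(c) c$cluster_id, character(1)),
                       ".faa")
      )
      readr::write_tsv(index, file.path(dir, "index.tsv"), progress = FALSE)
      for (cl in clusters) {
        writeLines(
          unlist(lapply(names(cl$genes), function(g) {
            c(paste0(">", g), cl$genes[[g]])
          })),
          file.path(dir, paste0(cl$cluster_id, ".faa"))
        )
      }
      paths <- list(dir = dir, index = file.path(dir, "index.tsv"))
    }
    list(clusters = clusters, queries = queries, paths = paths)
  })
}

#' Default end-to-end fixture bundle
#'
#' A circular 120 kb genome carrying five planted clusters — terpene,
#' NRPS, trans-AT PKS, azole-containing RiPP and a tailoring-rich
#' halogenase demo — with the terpene cluster spanning the origin, plus a
#' reference-cluster set derived from the NRPS cluster genes at identity
#' levels pinning each confidence tier.
#'
#' @param seed Integer seed.
#' @param dir Optional directory for on-disk outputs.
#' @return List with `genome` (from [generate_genome()]), `references`
#'   (list of `bgc_reference_cluster`), `expected_confidence` (named
#'   character) and `paths`.
#' @export
generate_fixture_bundle <- function(seed, dir = NULL) {
  planted <- with_seed(seed, list(
    terp = fixture_planted_terpene(),
    nrps = fixture_planted_nrps(),
    tat = fixture_planted_transat(),
    azo = fixture_planted_azole(),
    hal = fixture_planted_halogenase()
  ))
  # terpene cluster spans the origin: its single 2163 nt gene starts 1 kb
  # before the end of the 250 kb contig; the other clusters are spaced so
  # no two expected regions touch
  L <- 250000L
  starts <- c(terp = L - 1000L, nrps = 35000L, tat = 85000L, azo = 165000L,
              hal = 190000L)
  genome <- generate_genome(seed, "circular", planted, starts, L,
                            record_id = "FIXBUNDLE", dir = dir)
  # reference clusters from the NRPS genes at tier-pinning identities:
  # ~100% of genes matched -> high, one of two -> medium/low variants via
  # divergence, plus an unrelated cluster expected hidden
  nrps_tr <- genome$record$cds$translation[
    genome$record$cds$cds_id %in% c("nrps_nrpsA", "nrps_nrpsB")]
  refs <- with_seed(seed + 1L, {
    near <- reference_cluster(
      "ref_nrps_high", "NRPS-like reference (close homolog)",
      stats::setNames(vapply(nrps_tr, function(s) {
        as.character(mutate_to_identity(s, 85))
      }, character(1)), c("g1", "g2")))
    mixed <- reference_cluster(
      "ref_nrps_medium", "NRPS-like reference (partial homolog)",
      stats::setNames(c(
        as.character(mutate_to_identity(nrps_tr[1], 60)),
        as.character(mutate_to_identity(nrps_tr[2], 20, tolerance = 5)),
        random_protein(400L), random_protein(350L)
      ), paste0("g", 1:4)))
    far <- reference_cluster(
      "ref_unrelated", "unrelated reference cluster",
      stats::setNames(c(random_protein(300L), random_protein(420L),
                        random_protein(380L)), paste0("g", 1:3)))
    list(near, mixed, far)
  })
  expected_confidence <- c(ref_nrps_high = "high", ref_nrps_medium = "low",
                           ref_unrelated = "hidden")
  paths <- NULL
  if (!is.null(dir)) {
    refdir <- file.path(dir, "references")
    dir.create(refdir, recursive = TRUE, showWarnings = FALSE)
    index <- tibble::tibble(
      cluster_id = vapply(refs, function(c) c$cluster_id, character(1)),
      display_name = vapply(refs, function(c) c$display_name, character(1)),
      fasta = paste0(vapply(refs, function(c) c$cluster_id, character(1)), ".faa")
    )
    readr::write_tsv(index, file.path(refdir, "index.tsv"), progress = FALSE)
    for (cl in refs) {
      writeLines(unlist(lapply(names(cl$genes), function(g) {
        c(paste0(">", g), cl$genes[[g]])
      })), file.path(refdir, paste0(cl$cluster_id, ".faa")))
    }
    tables <- write_fixture_tables(dir)
    paths <- c(genome$paths, list(references = refdir), tables)
  }
  list(genome = genome, references = refs,
       expected_confidence = expected_confidence, paths = paths)
}
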