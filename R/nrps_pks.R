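# NRPS/PKS assembly-line annotation: order detected domains along the
# genes of a cluster, group them into biosynthetic modules (CoA-ligase
# loaded starter modules included), and check condensation/epimerization
# domains for their catalytic residues.

domain_kinds <- c("A", "C", "E", "KS", "AT", "KR", "DH", "ER", "CP", "TE",
                  "CAL", "BETA_HYDROXYLASE", "INTERFACE", "AB_HYDROLASE")
module_openers <- c("C", "KS", "CAL")
module_loaders <- c("A", "AT")
module_modifiers <- c("KR", "DH", "ER", "E", "BETA_HYDROXYLASE", "INTERFACE")
module_terminators <- c("TE", "AB_HYDROLASE")

#' Derive domain annotations from profile hits
#'
#' Keeps hits whose profile metadata carries a `domain_kind`, mapping each
#' to a domain annotation. Overlapping domain intervals on one CDS are
#' resolved by keeping the higher-bitscore annotation.
#'
#' @param hits Cutoff-filtered hit tibble.
#' @param profiles Profile metadata tibble with a `domain_kind` column.
#' @return Tibble with columns `cds_id`, `domain_kind`, `ali_start`,
#'   `ali_end`, `bitscore`.
#' @export
domains_from_hits <- function(hits, profiles) {
  kind <- profiles$domain_kind[match(hits$profile_name, profiles$profile_name)]
  dom <- hits[!is.na(kind), , drop = FALSE]
  dom$domain_kind <- kind[!is.na(kind)]
  bad <- setdiff(unique(dom$domain_kind), domain_kinds)
  if (length(bad) > 0) stop("unknown domain_kind(s): ", paste(bad, collapse = ", "))
  dom <- dplyr::arrange(dom, .data$cds_id, dplyr::desc(.data$bitscore))
  keep <- logical(nrow(dom))
  for (i in seq_len(nrow(dom))) {
    prior <- which(keep & dom$cds_id == dom$cds_id[i])
    clash <- any(dom$ali_start[prior] < dom$ali_end[i] &
                   dom$ali_start[i] < dom$ali_end[prior])
    keep[i] <- !clash
  }
  dom <- dom[keep, c("cds_id", "domain_kind", "ali_start", "ali_end", "bitscore")]
  tibble::as_tibble(dom)
}

#' Order a cluster's domains along the assembly line
#'
#' Genes are walked in order of their position along the region arc
#' (starting at the region start, so origin-spanning clusters stay
#' collinear); within a gene, domains are ordered by alignment start on
#' the translation.
#'
#' @param domains Domain tibble from [domains_from_hits()].
#' @param record The `bgc_record`.
#' @param region Optional region whose arc defines the walk origin;
#'   defaults to position 0.
#' @return The ordered domain tibble.
#' @export
order_cluster_domains <- function(domains, record, region = NULL) {
  if (nrow(domains) == 0) return(domains)
  origin <- if (!is.null(region)) region$location$start else 0L
  cds <- record$cds
  idx <- match(domains$cds_id, cds$cds_id)
  if (anyNA(idx)) {
    stop("domain references CDS absent from record: ",
         paste(unique(domains$cds_id[is.na(idx)]), collapse = ", "))
  }
  offset <- (cds$start[idx] - origin) %% record$length
  domains[order(offset, domains$ali_start), , drop = FALSE]
}

#' Assemble ordered domains into biosynthetic modules
#'
#' Greedy left-to-right split: a module opens at a condensation (C),
#' ketosynthase (KS) or CoA-ligase (CAL) domain — or at a leading
#' adenylation (A) / acyltransferase (AT) domain for a starter module —
#' accumulates modification domains, and closes at a carrier-protein (CP)
#' domain. A thioesterase (TE) or alpha/beta-hydrolase following the last
#' closed module attaches to it as the termination domain. A module
#' opening with CAL is a starter (CAL domains load fatty-acid-derived
#' starter units); trailing unclosed domains form an incomplete module.
#' A module is complete when it contains a carrier protein plus a loader
#' (A, AT or CAL).
#'
#' @param domains Ordered domain tibble (see [order_cluster_domains()]).
#' @return Tibble with one row per module: `module`, `role`, `complete`,
#'   and a `domains` list-column holding each module's domain rows.
#' @export
assemble_modules <- function(domains) {
  empty <- tibble::tibble(module = integer(), role = character(),
                          complete = logical(), domains = list())
  if (nrow(domains) == 0) return(empty)
  modules <- list()
  cur <- domains[0, , drop = FALSE]
  closed_last <- NULL  # index of last closed module, for TE attachment

  push <- function(rows, closed) {
    kinds <- rows$domain_kind
    role <- if (all(kinds %in% module_terminators)) {
      "termination"
    } else if (!closed) {
      "incomplete"
    } else if (kinds[1] == "CAL" ||
               (length(modules) == 0 && kinds[1] %in% module_loaders)) {
      "starter"
    } else if (kinds[1] %in% c("C", "KS")) {
      "extender"
    } else {
      "incomplete"
    }
    complete <- closed && any(kinds == "CP") &&
      any(kinds %in% c(module_loaders, "CAL"))
    modules[[length(modules) + 1L]] <<- list(role = role, complete = complete,
                                             domains = rows)
  }

  for (i in seq_len(nrow(domains))) {
    kind <- domains$domain_kind[i]
    row <- domains[i, , drop = FALSE]
    if (kind %in% module_openers) {
      if (nrow(cur) > 0) { push(cur, closed = FALSE); cur <- domains[0, ] }
      cur <- row
      closed_last <- NULL
    } else if (kind == "CP") {
      cur <- dplyr::bind_rows(cur, row)
      push(cur, closed = TRUE)
      closed_last <- length(modules)
      cur <- domains[0, , drop = FALSE]
    } else if (kind %in% module_terminators && nrow(cur) == 0 &&
               !is.null(closed_last)) {
      # termination domain trailing a closed module: attach to it
      m <- modules[[closed_last]]
      m$domains <- dplyr::bind_rows(m$domains, row)
      modules[[closed_last]] <- m
    } else {
      cur <- dplyr::bind_rows(cur, row)
    }
  }
  if (nrow(cur) > 0) push(cur, closed = FALSE)

  tibble::tibble(
    module = seq_along(modules),
    role = vapply(modules, function(m) m$role, character(1)),
    complete = vapply(modules, function(m) m$complete, logical(1)),
    domains = lapply(modules, function(m) m$domains)
  )
}

#' Read active-site motif specifications
#'
#' TSV with columns `domain_kind`, `motif_name`, `pattern` (regular
#' expression over amino acids), `window_offset` (aa downstream of the
#' domain alignment start where the motif is expected) and `window_slack`
#' (aa of tolerance either side).
#'
#' @param path Path to the TSV.
#' @return A tibble of motif specifications.
#' @export
read_motif_specs <- function(path) {
  spec <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("domain_kind", "motif_name", "pattern", "window_offset",
                "window_slack")
  missing <- setdiff(required, names(spec))
  if (length(missing) > 0) {
    stop("motif spec missing column(s): ", paste(missing, collapse = ", "))
  }
  tibble::as_tibble(spec)
}

#' Check a condensation/epimerization domain's catalytic residues
#'
#' Extracts the expected motif window from the translation (relative to
#' the domain's alignment start, widened by the slack) and searches for
#' the motif pattern. The domain is flagged inactive when the catalytic
#' residues are missing. A window falling outside the translation yields
#' an inactive result with a diagnostic flag.
#'
#' @param domain One domain row (`cds_id`, `domain_kind`, `ali_start`,
#'   `ali_end`).
#' @param translation The CDS translation.
#' @param motif_spec Motif-spec tibble (see [read_motif_specs()]); the row
#'   matching the domain kind is used.
#' @return Tibble with `motif_name`, `expected_motif`, `observed`,
#'   `active` and `window_ok`.
#' @export
check_active_site <- function(domain, translation, motif_spec) {
  spec <- motif_spec[motif_spec$domain_kind == domain$domain_kind, , drop = FALSE]
  if (nrow(spec) == 0) {
    stop("no motif specification for domain kind ", domain$domain_kind)
  }
  spec <- spec[1, ]
  win_start <- domain$ali_start + spec$window_offset - spec$window_slack
  # generous motif span: pattern literal width plus slack both sides
  motif_width <- nchar(gsub("\\[.*?\\]", "x", gsub("\\{(\\d+)\\}", "", spec$pattern)))
  win_end <- domain$ali_start + spec$window_offset + spec$window_slack +
    motif_width + 10L
  n <- nchar(translation)
  if (win_start >= n || win_end <= 0) {
    return(tibble::tibble(
      motif_name = spec$motif_name, expected_motif = spec$pattern,
      observed = NA_character_, active = FALSE, window_ok = FALSE))
  }
  window <- substr(translation, max(1L, win_start + 1L), min(n, win_end))
  m <- regexpr(spec$pattern, window, perl = TRUE)
  observed <- if (m[1] > 0) {
    substr(window, m[1], m[1] + attr(m, "match.length") - 1L)
  } else NA_character_
  tibble::tibble(
    motif_name = spec$motif_name, expected_motif = spec$pattern,
    observed = observed, active = m[1] > 0, window_ok = TRUE)
}

#' Active-site results for every C/E domain of a cluster
#' @param domains Domain tibble.
#' @param record The `bgc_record` (for translations).
#' @param motif_spec Motif-spec tibble.
#' @return Tibble with one row per checked domain.
#' @export
check_cluster_active_sites <- function(domains, record, motif_spec) {
  targets <- domains[domains$domain_kind %in% unique(motif_spec$domain_kind), ,
                     drop = FALSE]
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    d <- targets[i, ]
    tr <- record$cds$translation[match(d$cds_id, record$cds$cds_id)]
    res <- check_active_site(d, tr, motif_spec)
    dplyr::bind_cols(d[c("cds_id", "domain_kind", "ali_start")], res)
  })
  if (length(rows) == 0) {
    return(tibble::tibble(cds_id = character(), domain_kind = character(),
                          ali_start = integer(), motif_name = character(),
                          expected_motif = character(), observed = character(),
                          active = logical(), window_ok = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Link-out URL for adenylation-domain substrate prediction
#'
#' Builds a URL to an external substrate-specificity predictor embedding
#' the A-domain's amino-acid sequence. No network access is performed.
#'
#' @param domain Domain row with `domain_kind == "A"`.
#' @param translation The CDS translation.
#' @return A URL string.
#' @export
paras_link <- function(domain, translation) {
  if (!identical(domain$domain_kind, "A")) {
    stop("substrate-prediction links are only generated for A domains")
  }
  if (is.na(translation) || nchar(translation) == 0) {
    stop("cannot build a substrate-prediction link from an empty translation")
  }
  seq <- substr(translation, domain$ali_start + 1L,
                min(nchar(translation), domain$ali_end))
  if (nchar(seq) == 0) stop("A-domain alignment interval is empty")
  sprintf("https://paras.bioinformatics.nl/?sequence=%s", seq)
}
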