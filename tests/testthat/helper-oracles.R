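# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's arithmetic paths:
# gaps are measured over explicit position sets and grouping is done by
# exhaustive subset enumeration.

# record from compact cds specs: list(c(start, end), ...) with optional wrap
mk_record <- function(length, topology = "linear", cds = list(),
                      record_id = "test") {
  if (length(cds) == 0) {
    return(bgc_record(record_id, length, topology))
  }
  rows <- lapply(seq_along(cds), function(i) {
    spec <- cds[[i]]
    tibble::tibble(
      cds_id = names(cds)[i] %||% sprintf("cds%02d", i),
      start = spec[1], end = spec[2],
      crosses_origin = isTRUE(spec[1] >= spec[2]),
      strand = 1L,
      translation = strrep("M", 50)
    )
  })
  bgc_record(record_id, length, topology, dplyr::bind_rows(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_hits <- function(...) {
  specs <- list(...)
  dplyr::bind_rows(lapply(specs, function(s) {
    tibble::tibble(cds_id = s[[1]], profile_name = s[[2]],
                   bitscore = if (length(s) >= 3) as.numeric(s[[3]]) else 50,
                   evalue = 1e-10, ali_start = 0L, ali_end = 10L)
  }))
}

# Brute-force minimal gap via explicit position sets.
oracle_gap <- function(a, b, circular = TRUE) {
  pa <- loc_positions(a)
  pb <- loc_positions(b)
  if (length(intersect(pa, pb)) > 0) return(0L)
  L <- a$contig_length
  d <- outer(pa, pb, function(x, y) {
    if (circular) pmin((x - y) %% L, (y - x) %% L) else abs(x - y)
  })
  as.integer(min(d) - 1L)
}

# Independent condition evaluator over a hits tibble (profile_name,
# bitscore), written against the documented semantics rather than the
# package's implementation.
oracle_eval <- function(node, hits) {
  k <- node$kind
  if (k == "PROFILE") return(any(hits$profile_name == node$profile_name))
  if (k == "MINSCORE") {
    return(any(hits$profile_name == node$profile_name &
                 hits$bitscore >= node$score))
  }
  if (k == "MINIMUM") {
    return(sum(node$profiles %in% hits$profile_name) >= node$count)
  }
  if (k == "NOT") return(!oracle_eval(node$children[[1]], hits))
  kids <- vapply(node$children, oracle_eval, logical(1), hits = hits)
  if (k == "AND") all(kids) else any(kids)
}

# Exhaustive protocluster oracle: enumerate every subset of hit-bearing
# genes, keep subsets connected under gap <= cutoff (gaps measured by the
# position-set oracle), take the maximal connected subsets, and test the
# rule condition on each subset's pooled hits.
oracle_protoclusters <- function(record, hits, rule) {
  ids <- sort(unique(hits$cds_id))
  n <- length(ids)
  if (n == 0) return(list())
  circ <- record$topology == "circular"
  locs <- lapply(ids, cds_location, record = record)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        adj[i, j] <- adj[j, i] <-
          oracle_gap(locs[[i]], locs[[j]], circ) <= rule$cutoff_nt
      }
    }
  }
  connected <- function(sub) {
    if (length(sub) <= 1) return(TRUE)
    seen <- sub[1]
    repeat {
      grow <- setdiff(sub[apply(adj[seen, sub, drop = FALSE], 2, any)], seen)
      if (length(grow) == 0) break
      seen <- c(seen, grow)
    }
    length(seen) == length(sub)
  }
  subsets <- lapply(seq_len(2^n - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
  })
  conn <- Filter(connected, subsets)
  maximal <- Filter(function(sub) {
    outside <- setdiff(seq_len(n), sub)
    length(outside) == 0 || !any(adj[sub, outside, drop = FALSE])
  }, conn)
  satisfied <- Filter(function(sub) {
    oracle_eval(rule$conditions, hits[hits$cds_id %in% ids[sub], , drop = FALSE])
  }, maximal)
  lapply(satisfied, function(sub) sort(ids[sub]))
}

# Core genes of a satisfied subset under the documented marking rule:
# every individually satisfied atomic condition (not under NOT) marks the
# hits satisfying it; core genes are those carrying marked hits.
oracle_core_ids <- function(node, hits) {
  k <- node$kind
  if (k == "PROFILE") {
    if (!oracle_eval(node, hits)) return(character())
    return(unique(hits$cds_id[hits$profile_name == node$profile_name]))
  }
  if (k == "MINSCORE") {
    if (!oracle_eval(node, hits)) return(character())
    return(unique(hits$cds_id[hits$profile_name == node$profile_name &
                                hits$bitscore >= node$score]))
  }
  if (k == "MINIMUM") {
    if (!oracle_eval(node, hits)) return(character())
    return(unique(hits$cds_id[hits$profile_name %in% node$profiles]))
  }
  if (k == "NOT") return(character())
  unique(unlist(lapply(node$children, oracle_core_ids, hits = hits)))
}

# Random small genome + hit set for property tests: up to max_cds short
# genes at random non-overlapping positions, hits drawn from a small
# profile pool.
random_case <- function(seed, max_cds = 8, length = 3000, topology = "circular",
                        profile_pool = c("A", "B", "C")) {
  set.seed(seed)
  n <- sample(2:max_cds, 1)
  width <- 80L
  # place genes on a grid to guarantee no overlap
  slots <- sample(floor(length / 150L), n)
  starts <- sort((slots - 1L) * 150L)
  cds <- lapply(seq_len(n), function(i) c(starts[i], starts[i] + width))
  names(cds) <- sprintf("g%02d", seq_len(n))
  record <- mk_record(length, topology, cds)
  hits <- dplyr::bind_rows(
    tibble::tibble(cds_id = character(), profile_name = character(),
                   bitscore = numeric(), evalue = numeric(),
                   ali_start = integer(), ali_end = integer()),
    lapply(names(cds), function(id) {
      k <- sample(0:2, 1)
      if (k == 0) return(NULL)
      tibble::tibble(cds_id = id,
                     profile_name = sample(profile_pool, k, replace = TRUE),
                     bitscore = round(stats::runif(k, 20, 80), 1),
                     evalue = 1e-9, ali_start = 0L, ali_end = 10L)
    }))
  list(record = record, hits = hits)
}

oracle_rule_pool <- function() {
  parse_rules(paste(
    "RULE r1 CATEGORY c1 CUTOFF 0.4 NEIGHBOURHOOD 0.1 CONDITIONS A and B",
    "RULE r2 CATEGORY c2 CUTOFF 0.6 NEIGHBOURHOOD 0.1 CONDITIONS A or (B and C)",
    "RULE r3 CATEGORY c3 CUTOFF 0.5 NEIGHBOURHOOD 0.2 CONDITIONS minimum(2, [A, B, C])",
    "RULE r4 CATEGORY c4 CUTOFF 0.4 NEIGHBOURHOOD 0.1 CONDITIONS A and not C",
    "RULE r5 CATEGORY c5 CUTOFF 0.5 NEIGHBOURHOOD 0.1 CONDITIONS minscore(A, 50)",
    sep = "\n"))
}

# covered position set of a region list, optionally rotated back
region_position_sets <- function(region_set, rotate_back = 0L) {
  L <- region_set$contig_length
  sets <- lapply(region_set$regions, function(r) {
    sort((loc_positions(r$location) - rotate_back) %% L)
  })
  sets[order(vapply(sets, function(s) s[1], integer(1)))]
}
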