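# Protocluster and region formation. Genes carrying rule-relevant hits are
# grouped by gap distance (connected components under gap <= cutoff, an
# order-independent and rotation-stable grouping), each component's pooled
# hits are tested against the rule condition, satisfied components become
# protoclusters, EXTENDS absorbs distant core genes to a fixpoint, and
# overlapping protoclusters merge into regions. All distance arithmetic is
# origin-aware, so clusters spanning the origin of a circular replicon are
# detected and reported as single origin-spanning regions rather than
# being split or missed.

new_protocluster <- function(rule_name, product, core_location, full_location,
                             core_cds_ids) {
  structure(
    list(rule_name = rule_name, product = product,
         core_location = core_location, full_location = full_location,
         core_cds_ids = sort(core_cds_ids)),
    class = "bgc_protocluster"
  )
}

#' @export
print.bgc_protocluster <- function(x, ...) {
  cat(sprintf("<protocluster %s (%s): core [%d, %d)%s, %d core gene(s)>\n",
              x$rule_name, x$product, x$core_location$start,
              x$core_location$end,
              if (x$core_location$crosses_origin) " wrapping" else "",
              length(x$core_cds_ids)))
  invisible(x)
}

# union-find over indices
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

#' Form protoclusters for one rule
#'
#' Genes with hits are connected when the gap between them is at most the
#' rule's cutoff distance; each connected component's pooled hits are
#' tested against the rule condition. For a satisfied component the core
#' is the shortest arc covering the genes whose hits belong to satisfied
#' atomic conditions (conditions under `not` never mark cores), and the
#' full location extends the core by the neighbourhood distance in both
#' directions, wrapping on circular contigs and clamping on linear ones.
#'
#' @param record A `bgc_record`.
#' @param hits Cutoff-filtered hit tibble.
#' @param rule A `bgc_rule`.
#' @return List of `bgc_protocluster` objects (possibly empty).
#' @export
form_protoclusters <- function(record, hits, rule) {
  hits <- hits[hits$cds_id %in% record$cds$cds_id &
                 hits$profile_name %in% rule_profiles(rule), , drop = FALSE]
  cds_ids <- sort(unique(hits$cds_id))
  if (length(cds_ids) == 0) return(list())
  circular <- record$topology == "circular"
  locs <- lapply(cds_ids, cds_location, record = record)
  n <- length(cds_ids)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    keep <- vapply(seq_len(ncol(pairs)), function(k) {
      circular_gap(locs[[pairs[1, k]]], locs[[pairs[2, k]]],
                   circular = circular) <= rule$cutoff_nt
    }, logical(1))
    edges <- t(pairs[, keep, drop = FALSE])
  }
  comps <- uf_components(n, edges)
  out <- list()
  for (comp in comps) {
    comp_ids <- cds_ids[comp]
    comp_hits <- hits[hits$cds_id %in% comp_ids, , drop = FALSE]
    if (!evaluate_condition(rule$conditions, comp_hits)) next
    core_ids <- unique(comp_hits$cds_id[satisfied_core_hits(rule$conditions, comp_hits)])
    if (length(core_ids) == 0) next
    core_loc <- minimal_covering_arc(lapply(core_ids, cds_location, record = record),
                                     topology = record$topology)
    full_loc <- extend_location(core_loc, rule$neighbourhood_nt,
                                circular = circular)
    out[[length(out) + 1L]] <- new_protocluster(
      rule$rule_name, rule$category, core_loc, full_loc, core_ids)
  }
  # deterministic order by core start
  if (length(out) > 1) {
    out <- out[order(vapply(out, function(p) p$core_location$start, integer(1)))]
  }
  out
}

#' Absorb distant core genes via a rule's EXTENDS condition
#'
#' Iterates to a fixpoint: any gene whose own hits satisfy the EXTENDS
#' condition and whose gap to the current core arc is at most the rule
#' cutoff joins the core; the core and full locations are recomputed each
#' round. The core only grows and is bounded by the gene count, so the
#' iteration terminates. This lets chained module-bearing genes join a
#' cluster whose trans-acting partner sits far away.
#'
#' @param protocluster A `bgc_protocluster` from [form_protoclusters()].
#' @param record The `bgc_record` it was detected on.
#' @param hits Cutoff-filtered hit tibble.
#' @param rule The `bgc_rule` (must carry an `EXTENDS` condition).
#' @return The (possibly grown) `bgc_protocluster`.
#' @export
apply_extends <- function(protocluster, record, hits, rule) {
  if (is.null(rule$extends)) return(protocluster)
  circular <- record$topology == "circular"
  hits <- hits[hits$cds_id %in% record$cds$cds_id &
                 hits$profile_name %in% condition_profiles(rule$extends), ,
               drop = FALSE]
  candidates <- setdiff(unique(hits$cds_id), protocluster$core_cds_ids)
  candidates <- candidates[vapply(candidates, function(id) {
    evaluate_condition(rule$extends, hits[hits$cds_id == id, , drop = FALSE])
  }, logical(1))]
  core_ids <- protocluster$core_cds_ids
  repeat {
    core_loc <- minimal_covering_arc(lapply(core_ids, cds_location, record = record),
                                     topology = record$topology)
    reach <- candidates[vapply(candidates, function(id) {
      circular_gap(cds_location(record, id), core_loc,
                   circular = circular) <= rule$cutoff_nt
    }, logical(1))]
    if (length(reach) == 0) break
    core_ids <- c(core_ids, reach)
    candidates <- setdiff(candidates, reach)
  }
  core_loc <- minimal_covering_arc(lapply(core_ids, cds_location, record = record),
                                   topology = record$topology)
  full_loc <- extend_location(core_loc, rule$neighbourhood_nt, circular = circular)
  new_protocluster(protocluster$rule_name, protocluster$product,
                   core_loc, full_loc, core_ids)
}

#' Merge protoclusters into regions
#'
#' Protoclusters whose full locations overlap or abut (gap 0) are merged
#' transitively into one region; the region location is the shortest arc
#' covering its members, clamped to the whole contig when everything is
#' covered. Regions are numbered 1..n by start coordinate (an
#' origin-spanning region sorts by the start of its wrapping arc). The
#' result is independent of input order.
#'
#' @param protoclusters List of `bgc_protocluster` objects on one record.
#' @param record The `bgc_record`.
#' @return A `bgc_region_set`.
#' @export
merge_regions <- function(protoclusters, record) {
  circular <- record$topology == "circular"
  regions <- list()
  if (length(protoclusters) > 0) {
    n <- length(protoclusters)
    edges <- matrix(integer(0), ncol = 2)
    if (n > 1) {
      pairs <- utils::combn(n, 2)
      keep <- vapply(seq_len(ncol(pairs)), function(k) {
        circular_gap(protoclusters[[pairs[1, k]]]$full_location,
                     protoclusters[[pairs[2, k]]]$full_location,
                     circular = circular) == 0L
      }, logical(1))
      edges <- t(pairs[, keep, drop = FALSE])
    }
    comps <- uf_components(n, edges)
    regions <- lapply(comps, function(comp) {
      members <- protoclusters[comp]
      ord <- order(vapply(members, function(p) p$full_location$start, integer(1)),
                   vapply(members, function(p) p$rule_name, character(1)))
      members <- members[ord]
      loc <- minimal_covering_arc(lapply(members, function(p) p$full_location),
                                  topology = record$topology)
      list(region_number = NA_integer_, location = loc, protoclusters = members)
    })
    starts <- vapply(regions, function(r) r$location$start, integer(1))
    lens <- vapply(regions, function(r) loc_length(r$location), integer(1))
    regions <- regions[order(starts, lens)]
    for (i in seq_along(regions)) regions[[i]]$region_number <- i
  }
  structure(
    list(record_id = record$record_id, contig_length = record$length,
         topology = record$topology, regions = unname(regions)),
    class = "bgc_region_set"
  )
}

#' @export
print.bgc_region_set <- function(x, ...) {
  cat(sprintf("<bgc_region_set %s: %d region(s) on %d nt %s contig>\n",
              x$record_id, length(x$regions), x$contig_length, x$topology))
  for (r in x$regions) {
    cat(sprintf("  region %d [%d, %d)%s: %s\n", r$region_number,
                r$location$start, r$location$end,
                if (r$location$crosses_origin) " wrapping" else "",
                paste(region_products(r), collapse = ", ")))
  }
  invisible(x)
}

region_products <- function(region) {
  unique(vapply(region$protoclusters, function(p) p$product, character(1)))
}

#' Run rule-based detection on a record
#'
#' Applies profile cutoffs when `profiles` is supplied, forms
#' protoclusters for every rule (including EXTENDS growth) and merges them
#' into numbered regions.
#'
#' @param record A `bgc_record`.
#' @param hits Hit tibble.
#' @param rules List of `bgc_rule` objects.
#' @param profiles Optional profile metadata tibble; when given, hits are
#'   filtered by trusted cutoffs first.
#' @return A `bgc_region_set`.
#' @export
detect_regions <- function(record, hits, rules, profiles = NULL) {
  if (!is.null(profiles)) hits <- apply_cutoffs(hits, profiles)
  pcs <- list()
  for (rule in rules) {
    found <- form_protoclusters(record, hits, rule)
    if (!is.null(rule$extends)) {
      found <- lapply(found, apply_extends, record = record, hits = hits,
                      rule = rule)
    }
    pcs <- c(pcs, found)
  }
  merge_regions(pcs, record)
}

#' CDS contained in a region
#' @param region One region element of a `bgc_region_set`.
#' @param record The `bgc_record`.
#' @return The record's CDS tibble filtered to genes overlapping the region.
#' @export
region_cds <- function(region, record) {
  circular <- record$topology == "circular"
  cds <- record$cds
  keep <- vapply(seq_len(nrow(cds)), function(i) {
    loc <- bgc_location(cds$start[i], cds$end[i], record$length,
                        cds$crosses_origin[i])
    loc_overlaps(loc, region$location)
  }, logical(1))
  cds[keep, , drop = FALSE]
}

#' Serialize a region set to the canonical JSON report structure
#' @param region_set A `bgc_region_set`.
#' @return A list ready for `jsonlite::toJSON(auto_unbox = TRUE)`.
#' @export
region_report <- function(region_set) {
  list(
    record_id = region_set$record_id,
    contig_length = region_set$contig_length,
    topology = region_set$topology,
    regions = lapply(region_set$regions, function(r) {
      list(
        number = r$region_number,
        start = r$location$start,
        end = r$location$end,
        crosses_origin = r$location$crosses_origin,
        products = as.list(region_products(r)),
        protoclusters = lapply(r$protoclusters, function(p) {
          list(rule = p$rule_name, product = p$product,
               core_start = p$core_location$start,
               core_end = p$core_location$end,
               core_crosses_origin = p$core_location$crosses_origin,
               start = p$full_location$start,
               end = p$full_location$end,
               crosses_origin = p$full_location$crosses_origin,
               core_cds_ids = as.list(p$core_cds_ids))
        })
      )
    })
  )
}
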