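# End-to-end driver: detect regions on every record, then run the
# downstream analyses (modules, terpene, tailoring, known-cluster
# similarity) per region in that order, and write JSON plus annotated
# GenBank output.

#' Build a pipeline run configuration
#'
#' Validates that every referenced path exists. Paths other than `input`,
#' `rules` and `profiles` are optional; analyses without their tables are
#' skipped.
#'
#' @param input GenBank input file.
#' @param rules Rule DSL file.
#' @param profiles Profile metadata TSV.
#' @param hits Hit-table TSV (omit to run with zero hits).
#' @param known_clusters Reference-cluster directory (with `index.tsv`).
#' @param tailoring_db Directory holding `reference.faa` and
#'   `reference.tsv` for identity cross-links.
#' @param tailoring_map Tailoring profile-map TSV.
#' @param terpene_table Terpene subfamily TSV.
#' @param halogenase_signatures Halogenase signature TSV.
#' @param motif_specs Active-site motif TSV.
#' @param output_dir Output directory (created on demand).
#' @param circular_override `"auto"`, `"linear"` or `"circular"`.
#' @param timestamps Include a timestamp in the JSON output?
#' @return A `bgc_run_config`.
#' @export
run_config <- function(input, rules, profiles, hits = NULL,
                       known_clusters = NULL, tailoring_db = NULL,
                       tailoring_map = NULL, terpene_table = NULL,
                       halogenase_signatures = NULL, motif_specs = NULL,
                       output_dir = NULL,
                       circular_override = c("auto", "linear", "circular"),
                       timestamps = TRUE) {
  circular_override <- match.arg(circular_override)
  required <- list(input = input, rules = rules, profiles = profiles)
  for (name in names(required)) {
    if (is.null(required[[name]]) || !file.exists(required[[name]])) {
      stop("invalid configuration: missing ", name, " file",
           if (!is.null(required[[name]])) paste0(" '", required[[name]], "'"))
    }
  }
  for (p in list(hits, tailoring_map, terpene_table, halogenase_signatures,
                 motif_specs)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("invalid configuration: no such file '", p, "'")
    }
  }
  for (d in list(known_clusters, tailoring_db)) {
    if (!is.null(d) && !dir.exists(d)) {
      stop("invalid configuration: no such directory '", d, "'")
    }
  }
  structure(
    list(input = input, rules = rules, profiles = profiles, hits = hits,
         known_clusters = known_clusters, tailoring_db = tailoring_db,
         tailoring_map = tailoring_map, terpene_table = terpene_table,
         halogenase_signatures = halogenase_signatures,
         motif_specs = motif_specs, output_dir = output_dir,
         circular_override = circular_override, timestamps = timestamps),
    class = "bgc_run_config"
  )
}

#' Analyse one detected region
#'
#' Runs module assembly with active-site checks, terpene product
#' prediction, tailoring-enzyme categorization and known-cluster
#' similarity for a single region. Analyses whose tables are `NULL` are
#' skipped.
#'
#' @param region One region of a `bgc_region_set`.
#' @param record The `bgc_record`.
#' @param hits Cutoff-filtered hit tibble.
#' @param profiles Profile metadata tibble.
#' @param terpene_table,tailoring_map,halogenase_signatures,motif_specs
#'   Annotation tables (or `NULL`).
#' @param references List of `bgc_reference_cluster` (or `NULL`).
#' @param mite_reference Reference set from [read_reference_set()] (or
#'   `NULL`).
#' @return Named list of analysis results.
#' @export
analyze_region <- function(region, record, hits, profiles,
                           terpene_table = NULL, tailoring_map = NULL,
                           halogenase_signatures = NULL, motif_specs = NULL,
                           references = NULL, mite_reference = NULL) {
  cds_here <- region_cds(region, record)
  region_hits <- hits[hits$cds_id %in% cds_here$cds_id, , drop = FALSE]
  domains <- domains_from_hits(region_hits, profiles)
  domains <- order_cluster_domains(domains, record, region)
  modules <- assemble_modules(domains)
  active_sites <- if (!is.null(motif_specs) && nrow(domains) > 0) {
    check_cluster_active_sites(domains, record, motif_specs)
  } else NULL
  terpene <- if (!is.null(terpene_table)) {
    predict_terpene_products(region, region_hits, terpene_table, record)
  } else NULL
  tailoring <- if (!is.null(tailoring_map)) {
    categorize_tailoring_enzymes(region, region_hits, tailoring_map, record,
                                 halogenase_signatures = halogenase_signatures,
                                 reference = mite_reference)
  } else NULL
  similarity <- if (!is.null(references)) {
    region_similarity(region, record, references)
  } else NULL
  list(modules = modules, domains = domains, active_sites = active_sites,
       terpene = terpene, tailoring = tailoring, similarity = similarity)
}

#' Run the full detection and annotation pipeline
#'
#' @param config A `bgc_run_config` from [run_config()].
#' @return A `bgc_result_bundle`: per-record region sets with per-region
#'   analyses.
#' @export
run_pipeline <- function(config) {
  records <- read_genbank(config$input)
  if (config$circular_override != "auto") {
    records <- lapply(records, function(r) {
      r$topology <- config$circular_override
      r
    })
  }
  rules <- read_rules(config$rules)
  profiles <- read_profile_meta(config$profiles)
  hits <- if (!is.null(config$hits)) parse_hit_table(config$hits) else {
    tibble::tibble(cds_id = character(), profile_name = character(),
                   bitscore = numeric(), evalue = numeric(),
                   ali_start = integer(), ali_end = integer())
  }
  terpene_table <- if (!is.null(config$terpene_table)) {
    read_terpene_table(config$terpene_table)
  } else NULL
  tailoring_map <- if (!is.null(config$tailoring_map)) {
    read_tailoring_map(config$tailoring_map)
  } else NULL
  halogenase_signatures <- if (!is.null(config$halogenase_signatures)) {
    read_halogenase_signatures(config$halogenase_signatures)
  } else NULL
  motif_specs <- if (!is.null(config$motif_specs)) {
    read_motif_specs(config$motif_specs)
  } else NULL
  references <- if (!is.null(config$known_clusters)) {
    read_reference_clusters(config$known_clusters)
  } else NULL
  mite_reference <- if (!is.null(config$tailoring_db)) {
    read_reference_set(file.path(config$tailoring_db, "reference.faa"),
                       file.path(config$tailoring_db, "reference.tsv"))
  } else NULL

  results <- lapply(records, function(record) {
    filtered <- apply_cutoffs(hits[hits$cds_id %in% record$cds$cds_id, ,
                                   drop = FALSE], profiles)
    region_set <- detect_regions(record, filtered, rules)
    analyses <- lapply(region_set$regions, analyze_region, record = record,
                       hits = filtered, profiles = profiles,
                       terpene_table = terpene_table,
                       tailoring_map = tailoring_map,
                       halogenase_signatures = halogenase_signatures,
                       motif_specs = motif_specs, references = references,
                       mite_reference = mite_reference)
    list(record = record, region_set = region_set, analyses = analyses)
  })
  structure(list(results = results, config = config),
            class = "bgc_result_bundle")
}

#' @export
print.bgc_result_bundle <- function(x, ...) {
  cat(sprintf("<bgc_result_bundle: %d record(s)>\n", length(x$results)))
  for (res in x$results) print(res$region_set)
  invisible(x)
}

# Serialize one record's results to the canonical JSON structure.
result_record_json <- function(res) {
  report <- region_report(res$region_set)
  report$regions <- lapply(seq_along(report$regions), function(i) {
    reg <- report$regions[[i]]
    ana <- res$analyses[[i]]
    reg$modules <- lapply(seq_len(nrow(ana$modules)), function(m) {
      dom <- ana$modules$domains[[m]]
      list(module = ana$modules$module[m], role = ana$modules$role[m],
           complete = ana$modules$complete[m],
           domains = lapply(seq_len(nrow(dom)), function(d) {
             list(cds_id = dom$cds_id[d], domain_kind = dom$domain_kind[d],
                  ali_start = dom$ali_start[d], ali_end = dom$ali_end[d])
           }))
    })
    if (!is.null(ana$active_sites) && nrow(ana$active_sites) > 0) {
      reg$active_sites <- lapply(seq_len(nrow(ana$active_sites)), function(d) {
        as.list(ana$active_sites[d, c("cds_id", "domain_kind", "motif_name",
                                      "observed", "active")])
      })
    }
    if (!is.null(ana$terpene) && nrow(ana$terpene) > 0) {
      reg$terpene <- lapply(seq_len(nrow(ana$terpene)), function(d) {
        row <- as.list(ana$terpene[d, ])
        row[vapply(row, function(v) length(v) == 1 && is.na(v), logical(1))] <- NULL
        row
      })
    }
    if (!is.null(ana$tailoring)) {
      reg$tailoring <- tailoring_report(ana$tailoring)
    }
    if (!is.null(ana$similarity) && nrow(ana$similarity) > 0) {
      shown <- ana$similarity[ana$similarity$confidence != "hidden", , drop = FALSE]
      reg$similarity <- lapply(seq_len(nrow(shown)), function(d) {
        as.list(shown[d, c("cluster_id", "display_name", "similarity_percent",
                           "confidence")])
      })
    }
    reg
  })
  report
}

#' Write pipeline results to disk
#'
#' Emits `<record_id>.json` (canonical result format) and
#' `<record_id>.gbk` (annotated GenBank projection) per record.
#'
#' @param bundle A `bgc_result_bundle`.
#' @param output_dir Output directory (created on demand).
#' @param timestamps Include a timestamp field in the JSON?
#' @return Named list of written paths, invisibly.
#' @export
write_results <- function(bundle, output_dir,
                          timestamps = bundle$config$timestamps %||% TRUE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (res in bundle$results) {
    doc <- result_record_json(res)
    if (timestamps) doc$generated_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    json_path <- file.path(output_dir, paste0(res$record$record_id, ".json"))
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    gbk_path <- file.path(output_dir, paste0(res$record$record_id, ".gbk"))
    write_genbank(res$record, gbk_path, regions = res$region_set)
    paths[[res$record$record_id]] <- list(json = json_path, genbank = gbk_path)
  }
  invisible(paths)
}
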