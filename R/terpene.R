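# Table-driven terpene product prediction. The subfamily table maps each
# terpene-synthase profile to the terpenoid class and chain length of its
# product, plus (for well-characterized subfamilies) subclass, initial
# cyclization and product name(s); a specificity rank orders generic
# family profiles below specific subfamily profiles.

#' Read a terpene subfamily table
#'
#' TSV with columns `profile_name`, `terpenoid_class`, `chain_length`,
#' `subclass`, `cyclization`, `products` (semicolon-separated product
#' names, may be empty) and `specificity_rank`.
#'
#' @param path Path to the TSV.
#' @return A tibble (one row per profile).
#' @export
read_terpene_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("profile_name", "terpenoid_class", "chain_length", "subclass",
                "cyclization", "products", "specificity_rank")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("terpene table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$profile_name)) stop("duplicate profile_name in terpene table")
  tibble::as_tibble(tab)
}

#' Predict terpene products for a region
#'
#' For every gene in the region with a hit to a profile in the subfamily
#' table, the most specific matching entries (highest specificity rank;
#' ties all reported) each yield one prediction per product name — a
#' single synthase can be predicted to make several products, e.g. a
#' precursor and its derived volatile. Predictions always carry the
#' terpenoid class and chain length; subclass, cyclization and product
#' name only where the matched subfamily is specific enough. The region
#' must contain a terpene-category protocluster, otherwise the result is
#' empty.
#'
#' @param region One region of a `bgc_region_set`.
#' @param hits Cutoff-filtered hit tibble restricted to the record.
#' @param terpene_table Subfamily table (see [read_terpene_table()]).
#' @param record The `bgc_record`.
#' @param terpene_category Product category marking terpene protoclusters.
#' @return Tibble of predictions sorted by specificity rank (descending)
#'   then bitscore (descending).
#' @export
predict_terpene_products <- function(region, hits, terpene_table, record,
                                     terpene_category = "terpene") {
  empty <- tibble::tibble(
    cds_id = character(), source_profile = character(),
    terpenoid_class = character(), chain_length = integer(),
    subclass = character(), cyclization = character(),
    product_name = character(), specificity_rank = integer(),
    bitscore = numeric())
  if (!terpene_category %in% region_products(region)) return(empty)
  cds_here <- region_cds(region, record)$cds_id
  hits <- hits[hits$cds_id %in% cds_here &
                 hits$profile_name %in% terpene_table$profile_name, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  rows <- list()
  for (id in unique(hits$cds_id)) {
    h <- hits[hits$cds_id == id, , drop = FALSE]
    entry_rank <- terpene_table$specificity_rank[
      match(h$profile_name, terpene_table$profile_name)]
    best <- max(entry_rank)
    h <- h[entry_rank == best, , drop = FALSE]
    for (k in seq_len(nrow(h))) {
      entry <- terpene_table[terpene_table$profile_name == h$profile_name[k], ]
      products <- if (is.na(entry$products) || entry$products == "") {
        NA_character_
      } else {
        strsplit(entry$products, ";", fixed = TRUE)[[1]]
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cds_id = id, source_profile = entry$profile_name,
        terpenoid_class = entry$terpenoid_class,
        chain_length = as.integer(entry$chain_length),
        subclass = entry$subclass, cyclization = entry$cyclization,
        product_name = products,
        specificity_rank = as.integer(entry$specificity_rank),
        bitscore = h$bitscore[k])
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$specificity_rank),
                 dplyr::desc(.data$bitscore), .data$cds_id)
}
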