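# Tailoring-enzyme analysis: group the enzymes decorating a natural
# product scaffold by top-level Enzyme Commission category, grade
# flavin-dependent halogenase predictions by detail (family level up to
# regioselectivity), and cross-link enzymes to a reaction reference set
# when amino-acid identity reaches the 60% threshold.

ec_categories <- c("oxidoreductases", "transferases", "hydrolases",
                   "lyases", "isomerases", "ligases")

#' Read a tailoring profile-to-category map
#'
#' TSV with columns `profile_name`, `ec_category` (one of the six
#' top-level Enzyme Commission categories), `prediction_text`,
#' `detail_rank` (higher = more detailed) and `source` (`profile` or
#' `smcog`).
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_tailoring_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("profile_name", "ec_category", "prediction_text",
                "detail_rank", "source")
  missing <- setdiff(required, names(map))
  if (length(missing) > 0) {
    stop("tailoring map missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(map$ec_category), ec_categories)
  if (length(bad) > 0) {
    stop("unknown EC category in tailoring map: ", paste(bad, collapse = ", "))
  }
  tibble::as_tibble(map)
}

#' Read halogenase signature specifications
#'
#' TSV with columns `motif_name`, `pattern` (regular expression over the
#' translation), `prediction_text` and `detail_rank`. More detailed
#' predictions (e.g. tryptophan-halogenase regioselectivity) carry higher
#' ranks than substrate-level ones (e.g. a halogenated pyrrole).
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_halogenase_signatures <- function(path) {
  sig <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("motif_name", "pattern", "prediction_text", "detail_rank")
  missing <- setdiff(required, names(sig))
  if (length(missing) > 0) {
    stop("halogenase signature table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tibble::as_tibble(sig)
}

#' Grade a halogenase prediction by conserved motif signatures
#'
#' Returns the most detailed prediction whose motif matches the
#' translation, falling back to the coarse family-level text when no
#' motif matches.
#'
#' @param translation Amino-acid string of the halogenase CDS.
#' @param signatures Signature tibble (see [read_halogenase_signatures()]).
#' @param fallback_text Family-level prediction text.
#' @param fallback_rank Detail rank of the fallback (default 1).
#' @return One-row tibble with `prediction_text` and `detail_rank`.
#' @export
predict_halogenase <- function(translation, signatures,
                               fallback_text = "flavin-dependent halogenase",
                               fallback_rank = 1L) {
  hit <- signatures[vapply(signatures$pattern, function(p) {
    grepl(p, translation, perl = TRUE)
  }, logical(1)), , drop = FALSE]
  if (nrow(hit) == 0) {
    return(tibble::tibble(prediction_text = fallback_text,
                          detail_rank = as.integer(fallback_rank)))
  }
  best <- hit[which.max(hit$detail_rank), ]
  tibble::tibble(prediction_text = best$prediction_text,
                 detail_rank = as.integer(best$detail_rank))
}

#' Read a reaction reference set (protein FASTA plus metadata)
#'
#' The FASTA holds one protein per reference entry; the metadata TSV has
#' columns `entry_id`, `display_name`, `reaction_text` and `url_template`
#' (with `{id}` substituted by the entry id).
#'
#' @param fasta_path Path to the protein FASTA.
#' @param metadata_path Path to the metadata TSV.
#' @return A list with `sequences` (named character) and `metadata`
#'   (tibble).
#' @export
read_reference_set <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  sequences <- as.character(seqs)
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(), progress = FALSE)
  required <- c("entry_id", "display_name", "reaction_text", "url_template")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop("reference metadata missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$entry_id)) stop("duplicate entry_id in reference set")
  unknown <- setdiff(names(sequences), meta$entry_id)
  if (length(unknown) > 0) {
    stop("reference FASTA entries without metadata: ",
         paste(unknown, collapse = ", "))
  }
  list(sequences = sequences, metadata = tibble::as_tibble(meta))
}

#' Cross-link a tailoring enzyme to a reaction reference set
#'
#' Globally aligns the translation against every reference entry;
#' identity is identical columns over all alignment columns (gaps
#' included). Entries reaching at least 60% identity (inclusive) are
#' returned, sorted by identity descending — all passing entries, not
#' just the best.
#'
#' @param translation Amino-acid string of the enzyme.
#' @param reference Reference set from [read_reference_set()].
#' @param min_identity Identity threshold in percent (default 60).
#' @return Tibble with `entry_id`, `percent_identity`, `aligned_length`,
#'   `display_name`, `reaction_text` and `url`.
#' @export
mite_crosslink <- function(translation, reference, min_identity = 60) {
  empty <- tibble::tibble(entry_id = character(), percent_identity = numeric(),
                          aligned_length = integer(), display_name = character(),
                          reaction_text = character(), url = character())
  if (length(reference$sequences) == 0) return(empty)
  rows <- lapply(names(reference$sequences), function(id) {
    ident <- pairwise_identity(translation, reference$sequences[[id]])
    tibble::tibble(entry_id = id, percent_identity = ident,
                   aligned_length = alignment_columns(
                     translation, reference$sequences[[id]]))
  })
  res <- dplyr::bind_rows(rows)
  res <- res[res$percent_identity >= min_identity, , drop = FALSE]
  if (nrow(res) == 0) return(empty)
  res <- dplyr::arrange(res, dplyr::desc(.data$percent_identity))
  meta <- reference$metadata
  idx <- match(res$entry_id, meta$entry_id)
  res$display_name <- meta$display_name[idx]
  res$reaction_text <- meta$reaction_text[idx]
  res$url <- stringr::str_replace(meta$url_template[idx], stringr::fixed("{id}"),
                                  res$entry_id)
  res
}

#' Categorize a region's tailoring enzymes by EC category
#'
#' One annotation per gene with at least one tailoring-profile hit. Each
#' annotation collects all available predictions — profile-map entries,
#' motif-graded halogenase predictions, reference-set cross-links and
#' smCOG-style entries — and summarizes with the most detailed one
#' (highest detail rank). Only categories with members appear in the
#' grouped report.
#'
#' @param region One region of a `bgc_region_set`.
#' @param hits Cutoff-filtered hit tibble.
#' @param tailoring_map Profile map (see [read_tailoring_map()]).
#' @param record The `bgc_record`.
#' @param halogenase_signatures Optional signature tibble; applied to
#'   genes hit by profiles whose map text marks them halogenases.
#' @param reference Optional reference set for identity cross-links.
#' @param halogenase_profiles Profile names to grade with signatures.
#' @return Tibble with `cds_id`, `ec_category`, `summary` and a
#'   `predictions` list-column (tibbles with `source`, `text`,
#'   `detail_rank`).
#' @export
categorize_tailoring_enzymes <- function(region, hits, tailoring_map, record,
                                         halogenase_signatures = NULL,
                                         reference = NULL,
                                         halogenase_profiles = "flavin_halogenase") {
  empty <- tibble::tibble(cds_id = character(), ec_category = character(),
                          summary = character(), predictions = list())
  cds_here <- region_cds(region, record)
  hits <- hits[hits$cds_id %in% cds_here$cds_id &
                 hits$profile_name %in% tailoring_map$profile_name, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  rows <- list()
  for (id in unique(hits$cds_id)) {
    h <- hits[hits$cds_id == id, , drop = FALSE]
    translation <- cds_here$translation[match(id, cds_here$cds_id)]
    map_rows <- tailoring_map[match(unique(h$profile_name),
                                    tailoring_map$profile_name), , drop = FALSE]
    preds <- tibble::tibble(source = map_rows$source,
                            text = map_rows$prediction_text,
                            detail_rank = as.integer(map_rows$detail_rank))
    if (!is.null(halogenase_signatures) &&
        any(h$profile_name %in% halogenase_profiles)) {
      fallback <- map_rows[map_rows$profile_name %in% halogenase_profiles, ][1, ]
      hal <- predict_halogenase(translation, halogenase_signatures,
                                fallback_text = fallback$prediction_text,
                                fallback_rank = fallback$detail_rank)
      preds <- dplyr::bind_rows(preds, tibble::tibble(
        source = "profile", text = hal$prediction_text,
        detail_rank = hal$detail_rank))
    }
    if (!is.null(reference)) {
      links <- mite_crosslink(translation, reference)
      if (nrow(links) > 0) {
        preds <- dplyr::bind_rows(preds, tibble::tibble(
          source = "mite",
          text = sprintf("%s (%s, %.1f%% identity)", links$reaction_text,
                         links$entry_id, links$percent_identity),
          detail_rank = max(preds$detail_rank) + 1L))
      }
    }
    preds <- dplyr::distinct(preds)
    # category of the gene: from the most detailed mapped profile
    best_map <- map_rows[which.max(map_rows$detail_rank), ]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cds_id = id, ec_category = best_map$ec_category,
      summary = preds$text[which.max(preds$detail_rank)],
      predictions = list(preds))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$ec_category, .data$cds_id)
}

#' Group tailoring annotations by EC category for reporting
#' @param annotations Tibble from [categorize_tailoring_enzymes()].
#' @return Named list (category -> list of annotations); empty categories
#'   are absent.
#' @export
tailoring_report <- function(annotations) {
  if (nrow(annotations) == 0) return(structure(list(), names = character()))
  cats <- intersect(ec_categories, unique(annotations$ec_category))
  out <- lapply(cats, function(cat) {
    rows <- annotations[annotations$ec_category == cat, , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(i) {
      list(cds_id = rows$cds_id[i], summary = rows$summary[i],
           predictions = lapply(seq_len(nrow(rows$predictions[[i]])), function(j) {
             p <- rows$predictions[[i]][j, ]
             list(source = p$source, text = p$text,
                  detail_rank = p$detail_rank)
           }))
    })
  })
  names(out) <- cats
  out
}
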