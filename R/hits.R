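# Profile-HMM hit handling: the substrate every detection rule evaluates.
# Hits arrive precomputed as a TSV (a fixed subset of HMMER domtblout
# fields); an adapter for full domtblout output and a pluggable "dynamic
# profile" producer share the same output contract.

hit_columns <- c("cds_id", "profile_name", "bitscore", "evalue",
                 "ali_start", "ali_end")

#' Read a profile-hit table
#'
#' Expects a TSV with header columns `cds_id`, `profile_name`, `bitscore`,
#' `evalue`, `ali_start`, `ali_end`. Alignment coordinates are 0-based
#' half-open amino-acid offsets on the CDS translation. Row order is
#' preserved.
#'
#' @param path Path to the TSV file.
#' @return A tibble of hits.
#' @export
parse_hit_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(hit_columns, names(raw))
  if (length(missing) > 0) {
    stop("hit table missing column(s): ", paste(missing, collapse = ", "))
  }
  raw <- raw[hit_columns]
  numeric_cols <- c("bitscore", "evalue", "ali_start", "ali_end")
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad) > 0) {
      stop(sprintf("hit table row %d: non-numeric or non-finite %s '%s'",
                   bad[1], col, raw[[col]][bad[1]]))
    }
    raw[[col]] <- vals
  }
  raw$ali_start <- as.integer(raw$ali_start)
  raw$ali_end <- as.integer(raw$ali_end)
  if (any(raw$evalue < 0)) stop("hit table contains negative evalue")
  if (any(raw$ali_start < 0 | raw$ali_end <= raw$ali_start)) {
    stop("hit table contains invalid alignment interval")
  }
  tibble::as_tibble(raw)
}

#' Write a profile-hit table
#' @param hits Tibble of hits.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits[hit_columns], path, progress = FALSE)
  invisible(path)
}

#' Read profile metadata
#'
#' A profile set is a TSV with columns `profile_name`, `bitscore_cutoff`,
#' `description`, `category` and optionally `domain_kind` (for NRPS/PKS
#' domain profiles).
#'
#' @param path Path to the TSV file.
#' @return A tibble of profile metadata.
#' @export
read_profile_meta <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("profile_name", "bitscore_cutoff", "description", "category")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop("profile table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$profile_name)) stop("duplicate profile_name in profile set")
  if (any(!is.finite(meta$bitscore_cutoff))) stop("non-finite bitscore_cutoff")
  if (!"domain_kind" %in% names(meta)) meta$domain_kind <- NA_character_
  tibble::as_tibble(meta)
}

#' Filter hits by per-profile trusted cutoffs
#'
#' Keeps exactly the hits whose bitscore is greater than or equal to their
#' profile's cutoff (inclusive, following the HMMER trusted-cutoff
#' convention). The operation is idempotent and order-preserving.
#'
#' @param hits Tibble of hits.
#' @param profiles Tibble of profile metadata (see [read_profile_meta()]).
#' @return The filtered hit tibble.
#' @export
apply_cutoffs <- function(hits, profiles) {
  unknown <- setdiff(hits$profile_name, profiles$profile_name)
  if (length(unknown) > 0) {
    stop("hit(s) reference unknown profile(s): ", paste(unknown, collapse = ", "))
  }
  cutoff <- profiles$bitscore_cutoff[match(hits$profile_name, profiles$profile_name)]
  hits[hits$bitscore >= cutoff, , drop = FALSE]
}

#' Index hits by CDS
#'
#' Partitions a hit table into a named list, one element per CDS, each a
#' tibble sorted ascending by `ali_start` with ties broken by higher
#' bitscore first.
#'
#' @param hits Tibble of hits.
#' @return Named list of hit tibbles, keyed by `cds_id`.
#' @export
hits_by_cds <- function(hits) {
  if (nrow(hits) == 0) return(structure(list(), names = character()))
  hits <- dplyr::arrange(hits, .data$ali_start, dplyr::desc(.data$bitscore))
  out <- split(hits, hits$cds_id)
  out[order(names(out))]
}

#' Read a HMMER domtblout file into the hit-table contract
#'
#' Adapter for the whitespace-delimited per-domain table `hmmsearch
#' --domtblout` writes. Comment lines (`#`) are skipped; only the columns
#' this package consumes are retained. HMMER's 1-based inclusive envelope
#' coordinates are converted to 0-based half-open.
#'
#' @param path Path to a domtblout file.
#' @return A tibble of hits.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(cds_id = character(), profile_name = character(),
                          bitscore = numeric(), evalue = numeric(),
                          ali_start = integer(), ali_end = integer()))
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22) stop(sprintf("domtblout row %d: too few columns", i))
    tibble::tibble(
      cds_id = f[1], profile_name = f[4],
      bitscore = as.numeric(f[14]), evalue = as.numeric(f[13]),
      ali_start = as.integer(f[18]) - 1L, ali_end = as.integer(f[19])
    )
  })
  dplyr::bind_rows(rows)
}

#' Dynamic profile: minimum length plus required motif
#'
#' Dynamic profiles are hit producers implemented in code rather than as
#' pHMMs; they emit rows under the same hit-table contract so the rule
#' engine cannot tell them apart from pHMM hits. This one fires on every
#' CDS whose translation is at least `min_length` amino acids and contains
#' a match to `motif` (a regular expression); the alignment interval is
#' the motif match.
#'
#' @param record A `bgc_record`.
#' @param profile_name Name the emitted hits carry.
#' @param min_length Minimum translation length (aa).
#' @param motif Regular expression the translation must contain.
#' @param bitscore Bitscore assigned to emitted hits.
#' @return A tibble of hits (possibly empty).
#' @export
dynamic_profile_motif <- function(record, profile_name, min_length, motif,
                                  bitscore = 50) {
  cds <- record$cds
  rows <- lapply(seq_len(nrow(cds)), function(i) {
    tr <- cds$translation[i]
    if (nchar(tr) < min_length) return(NULL)
    m <- regexpr(motif, tr, perl = TRUE)
    if (m[1] < 0) return(NULL)
    tibble::tibble(
      cds_id = cds$cds_id[i], profile_name = profile_name,
      bitscore = bitscore, evalue = 0,
      ali_start = as.integer(m[1] - 1L),
      ali_end = as.integer(m[1] - 1L + attr(m, "match.length"))
    )
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    return(tibble::tibble(cds_id = character(), profile_name = character(),
                          bitscore = numeric(), evalue = numeric(),
                          ali_start = integer(), ali_end = integer()))
  }
  dplyr::bind_rows(rows)
}
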