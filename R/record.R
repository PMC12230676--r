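#' Create a sequence record
#'
#' A record is a contig (linear or circular) plus its protein-coding genes.
#' Genes live in a tibble so they compose with dplyr verbs; coordinates are
#' 0-based half-open, converted from GenBank's 1-based inclusive form at the
#' I/O boundary.
#'
#' @param record_id Record identifier (LOCUS name).
#' @param length Contig length in nucleotides.
#' @param topology `"linear"` or `"circular"`.
#' @param cds Tibble with columns `cds_id`, `start`, `end`, `crosses_origin`,
#'   `strand` (+1/-1) and `translation` (amino-acid string). May be empty.
#' @param sequence Optional nucleotide sequence (character scalar); when
#'   absent a placeholder is written on output.
#' @return An object of class `bgc_record`.
#' @export
bgc_record <- function(record_id, length, topology = c("linear", "circular"),
                       cds = NULL, sequence = NULL) {
  topology <- match.arg(topology)
  length <- as.integer(length)
  if (is.null(cds) || nrow(cds) == 0) {
    cds <- tibble::tibble(
      cds_id = character(), start = integer(), end = integer(),
      crosses_origin = logical(), strand = integer(), translation = character()
    )
  }
  cds <- tibble::as_tibble(cds)
  required <- c("cds_id", "start", "end", "crosses_origin", "strand", "translation")
  missing <- setdiff(required, names(cds))
  if (length(missing) > 0) {
    stop("cds table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cds$cds_id)) {
    stop("duplicate cds_id in record '", record_id, "'")
  }
  if (any(cds$crosses_origin) && topology != "circular") {
    stop("origin-spanning CDS on a non-circular record '", record_id, "'")
  }
  if (any(nchar(cds$translation) < 1)) {
    stop("CDS with empty translation in record '", record_id, "'")
  }
  # validate every location against the contig
  for (i in seq_len(nrow(cds))) {
    bgc_location(cds$start[i], cds$end[i], length, cds$crosses_origin[i])
  }
  cds <- dplyr::arrange(cds, .data$start, .data$end)
  structure(
    list(record_id = record_id, length = length, topology = topology,
         cds = cds, sequence = sequence),
    class = "bgc_record"
  )
}

#' @export
print.bgc_record <- function(x, ...) {
  cat(sprintf("<bgc_record %s: %d nt, %s, %d CDS>\n",
              x$record_id, x$length, x$topology, nrow(x$cds)))
  invisible(x)
}

#' Location of one CDS in a record
#' @param record A `bgc_record`.
#' @param cds_id CDS identifier.
#' @return A `bgc_location`.
#' @export
cds_location <- function(record, cds_id) {
  i <- match(cds_id, record$cds$cds_id)
  if (is.na(i)) stop("no CDS '", cds_id, "' in record ", record$record_id)
  bgc_location(record$cds$start[i], record$cds$end[i], record$length,
               record$cds$crosses_origin[i])
}

#' Rotate a circular record
#'
#' Shifts all CDS coordinates by `offset` nucleotides modulo the contig
#' length. Translations, identifiers and strands are unchanged. Used to
#' test rotation invariance of detection.
#'
#' @param record A circular `bgc_record`.
#' @param offset Rotation in nucleotides.
#' @return The rotated `bgc_record`.
#' @export
rotate_record <- function(record, offset) {
  if (record$topology != "circular") stop("can only rotate circular records")
  cds <- record$cds
  if (nrow(cds) > 0) {
    locs <- lapply(seq_len(nrow(cds)), function(i) {
      rotate_location(
        bgc_location(cds$start[i], cds$end[i], record$length, cds$crosses_origin[i]),
        offset
      )
    })
    cds$start <- vapply(locs, function(l) l$start, integer(1))
    cds$end <- vapply(locs, function(l) l$end, integer(1))
    cds$crosses_origin <- vapply(locs, function(l) l$crosses_origin, logical(1))
  }
  bgc_record(record$record_id, record$length, record$topology, cds,
             sequence = NULL)
}
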