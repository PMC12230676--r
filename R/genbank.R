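# GenBank flat-file reader/writer for the subset this package needs:
# LOCUS (name, length, topology), CDS features with /translation, and the
# region/protocluster features the writer adds. Coordinates are converted
# between GenBank 1-based inclusive and internal 0-based half-open at this
# boundary. No gene calling and no nucleotide analysis happens here.

#' Read GenBank flat files
#'
#' Parses one `bgc_record` per LOCUS. Topology is taken from the LOCUS
#' line. A CDS whose location is a join of a segment ending at the contig
#' end with one starting at base 1 is read as a single origin-spanning
#' feature (only legal on circular records). CDS features without an
#' obtainable `/translation` are skipped with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @return List of `bgc_record` objects. Non-CDS features are kept in each
#'   record's `extra_features` tibble.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_at <- grep("^LOCUS", lines)
  if (length(locus_at) == 0) {
    stop("not a GenBank flat file (no LOCUS line): ", path)
  }
  bounds <- c(locus_at, length(lines) + 1L)
  lapply(seq_along(locus_at), function(k) {
    chunk <- lines[bounds[k]:(bounds[k + 1] - 1L)]
    parse_genbank_record(chunk, first_line = bounds[k])
  })
}

parse_genbank_record <- function(lines, first_line = 1L) {
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  bp_at <- which(locus == "bp")
  if (length(locus) < 3 || length(bp_at) != 1 || bp_at < 3) {
    stop(sprintf("line %d: malformed LOCUS line", first_line))
  }
  record_id <- locus[2]
  len <- suppressWarnings(as.integer(locus[bp_at - 1]))
  if (is.na(len)) {
    stop(sprintf("line %d: malformed LOCUS length", first_line))
  }
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  feat_start <- grep("^FEATURES", lines)
  end_at <- grep("^(ORIGIN|//)", lines)
  feats <- list()
  if (length(feat_start) == 1) {
    stop_at <- if (length(end_at)) min(end_at[end_at > feat_start]) else length(lines) + 1L
    feats <- parse_feature_table(lines[(feat_start + 1L):(stop_at - 1L)],
                                 offset = first_line + feat_start)
  }

  sequence <- NULL
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 1) {
    seq_lines <- lines[(origin_at + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- paste(gsub("[^A-Za-z]", "", seq_lines), collapse = "")
    if (nchar(sequence) == 0) sequence <- NULL
  }

  cds_rows <- list()
  extra <- list()
  n_auto <- 0L
  for (f in feats) {
    loc <- parse_genbank_location(f$location, len, topology,
                                  line = f$line)
    if (f$key == "CDS") {
      translation <- f$qualifiers[["translation"]]
      if (is.null(translation) || nchar(translation) == 0) {
        warning(sprintf("line %d: CDS without /translation skipped", f$line))
        next
      }
      cds_id <- f$qualifiers[["locus_tag"]] %||%
        f$qualifiers[["protein_id"]] %||% f$qualifiers[["gene"]]
      if (is.null(cds_id)) {
        n_auto <- n_auto + 1L
        cds_id <- sprintf("%s_cds%03d", record_id, n_auto)
      }
      cds_rows[[length(cds_rows) + 1L]] <- tibble::tibble(
        cds_id = cds_id, start = loc$start, end = loc$end,
        crosses_origin = loc$crosses_origin, strand = loc$strand,
        translation = gsub("\\s", "", translation)
      )
    } else if (f$key != "source") {
      extra[[length(extra) + 1L]] <- tibble::tibble(
        key = f$key, start = loc$start, end = loc$end,
        crosses_origin = loc$crosses_origin, strand = loc$strand,
        qualifiers = list(f$qualifiers)
      )
    }
  }
  cds <- if (length(cds_rows)) dplyr::bind_rows(cds_rows) else NULL
  rec <- bgc_record(record_id, len, topology, cds, sequence = sequence)
  rec$extra_features <- if (length(extra)) dplyr::bind_rows(extra) else
    tibble::tibble(key = character(), start = integer(), end = integer(),
                   crosses_origin = logical(), strand = integer(),
                   qualifiers = list())
  rec
}

# Split the FEATURES block into features with raw location strings and
# parsed qualifiers. Feature keys start at column 6; continuations and
# qualifiers are indented further.
parse_feature_table <- function(lines, offset = 0L) {
  feats <- list()
  cur <- NULL
  in_qualifier <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (grepl("^ {5}\\S", line)) {
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- finish_feature(cur)
      parts <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(parts) < 2) {
        stop(sprintf("line %d: feature line without location", offset + i))
      }
      cur <- list(key = parts[1], location = paste(parts[-1], collapse = ""),
                  line = offset + i, raw_quals = character())
      in_qualifier <- FALSE
    } else if (grepl("^\\s+\\S", line)) {
      if (is.null(cur)) {
        stop(sprintf("line %d: continuation before any feature", offset + i))
      }
      txt <- trimws(line)
      if (startsWith(txt, "/")) {
        cur$raw_quals <- c(cur$raw_quals, txt)
        in_qualifier <- TRUE
      } else if (in_qualifier) {
        n <- length(cur$raw_quals)
        sep <- if (grepl("translation=", cur$raw_quals[n])) "" else " "
        cur$raw_quals[n] <- paste(cur$raw_quals[n], txt, sep = sep)
      } else {
        cur$location <- paste0(cur$location, txt)
      }
    } else {
      stop(sprintf("line %d: unparseable feature table line", offset + i))
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- finish_feature(cur)
  feats
}

finish_feature <- function(f) {
  quals <- list()
  for (q in f$raw_quals) {
    m <- regmatches(q, regexec('^/([A-Za-z_0-9]+)(?:=(.*))?$', q))[[1]]
    if (length(m) == 0) next
    key <- m[2]
    val <- m[3]
    val <- gsub('^"|"$', "", val)
    quals[[key]] <- val
  }
  f$qualifiers <- quals
  f$raw_quals <- NULL
  f
}

# Convert a GenBank location string (1-based inclusive) to 0-based
# half-open internal coordinates. Supports n..m, complement(...) and
# join(...); a two-segment join wrapping the origin of a circular contig
# becomes a single origin-spanning location.
parse_genbank_location <- function(text, contig_length, topology, line = NA) {
  strand <- 1L
  text <- gsub("\\s", "", text)
  while (grepl("^complement\\(", text)) {
    strand <- -strand
    text <- sub("^complement\\((.*)\\)$", "\\1", text)
  }
  segs <- if (grepl("^join\\(", text)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", text)
    strsplit(inner, ",")[[1]]
  } else {
    text
  }
  coords <- lapply(segs, function(s) {
    m <- regmatches(s, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", s))[[1]]
    if (length(m) == 0) {
      m1 <- regmatches(s, regexec("^(\\d+)$", s))[[1]]
      if (length(m1) == 0) {
        stop(sprintf("line %s: unparseable location segment '%s'",
                     format(line), s))
      }
      c(as.integer(m1[2]), as.integer(m1[2]))
    } else {
      c(as.integer(m[2]), as.integer(m[3]))
    }
  })
  starts1 <- vapply(coords, `[`, integer(1), 1)
  ends1 <- vapply(coords, `[`, integer(1), 2)
  wraps <- length(segs) == 2 && ends1[1] == contig_length && starts1[2] == 1L
  if (wraps) {
    if (topology != "circular") {
      stop(sprintf(
        "line %s: origin-crossing location '%s' on a linear record",
        format(line), text))
    }
    loc <- bgc_location(starts1[1] - 1L, ends1[2], contig_length,
                        crosses_origin = TRUE)
  } else {
    loc <- bgc_location(min(starts1) - 1L, max(ends1), contig_length)
  }
  list(start = loc$start, end = loc$end, crosses_origin = loc$crosses_origin,
       strand = strand)
}

format_genbank_location <- function(start, end, crosses_origin, strand,
                                    contig_length) {
  body <- if (crosses_origin) {
    sprintf("join(%d..%d,1..%d)", start + 1L, contig_length, end)
  } else {
    sprintf("%d..%d", start + 1L, end)
  }
  if (strand < 0) sprintf("complement(%s)", body) else body
}

#' Write a record (and detected regions) to GenBank format
#'
#' Detected regions and their protoclusters are written as `region` and
#' `protocluster` features; an origin-spanning feature is emitted as a
#' join of its two segments, the convention `read_genbank()` reverses.
#'
#' @param record A `bgc_record`.
#' @param path Output path.
#' @param regions Optional `bgc_region_set` from [detect_regions()].
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path, regions = NULL) {
  L <- record$length
  lines <- c(sprintf("LOCUS       %-16s %d bp    DNA     %-8s BCT 01-JAN-2000",
                     record$record_id, L, record$topology),
             sprintf("DEFINITION  %s.", record$record_id),
             "FEATURES             Location/Qualifiers",
             feature_lines("source", sprintf("1..%d", L),
                           c(organism = "synthetic construct")))
  if (!is.null(regions)) {
    for (reg in regions$regions) {
      loc <- reg$location
      lines <- c(lines, feature_lines(
        "region",
        format_genbank_location(loc$start, loc$end, loc$crosses_origin, 1L, L),
        c(region_number = as.character(reg$region_number),
          product = paste(region_products(reg), collapse = ";"))
      ))
      for (pc in reg$protoclusters) {
        lines <- c(lines, feature_lines(
          "protocluster",
          format_genbank_location(pc$full_location$start, pc$full_location$end,
                                  pc$full_location$crosses_origin, 1L, L),
          c(detection_rule = pc$rule_name, product = pc$product,
            core_location = format_genbank_location(
              pc$core_location$start, pc$core_location$end,
              pc$core_location$crosses_origin, 1L, L))
        ))
      }
    }
  }
  cds <- record$cds
  for (i in seq_len(nrow(cds))) {
    lines <- c(lines, feature_lines(
      "CDS",
      format_genbank_location(cds$start[i], cds$end[i], cds$crosses_origin[i],
                              cds$strand[i], L),
      c(locus_tag = cds$cds_id[i], translation = cds$translation[i])
    ))
  }
  if (!is.null(record$sequence)) {
    lines <- c(lines, "ORIGIN", format_origin(record$sequence), "//")
  } else {
    lines <- c(lines, "ORIGIN", "//")
  }
  writeLines(lines, path)
  invisible(path)
}

feature_lines <- function(key, location, qualifiers) {
  out <- sprintf("     %-16s%s", key, location)
  for (name in names(qualifiers)) {
    text <- sprintf('/%s="%s"', name, qualifiers[[name]])
    # wrap long qualifier values GenBank-style at column 80
    while (nchar(text) > 58) {
      out <- c(out, paste0(strrep(" ", 21), substr(text, 1, 58)))
      text <- substr(text, 59, nchar(text))
    }
    out <- c(out, paste0(strrep(" ", 21), text))
  }
  out
}

format_origin <- function(sequence) {
  n <- nchar(sequence)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(n, s + 59L))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    sprintf("%9d %s", s, paste(blocks, collapse = " "))
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
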