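# Coordinate model: 0-based half-open intervals on linear or circular
# contigs. An origin-spanning interval is stored as (start, end,
# crosses_origin = TRUE) with covered set [start, contig_length) U [0, end);
# coordinates never exceed contig_length.

#' Create a genomic location
#'
#' Locations use 0-based, half-open coordinates. On circular contigs a
#' location may span the origin of replication, in which case its covered
#' set is `[start, contig_length) U [0, end)` and `start > end` is the
#' stored form. A location covering the whole contig is represented as
#' `[0, contig_length)` with `crosses_origin = FALSE`.
#'
#' @param start 0-based inclusive start offset.
#' @param end 0-based exclusive end offset.
#' @param contig_length Length of the contig in nucleotides.
#' @param crosses_origin Does the interval wrap around the origin?
#' @return An object of class `bgc_location`.
#' @examples
#' bgc_location(10, 20, 100)
#' bgc_location(90, 5, 100, crosses_origin = TRUE)
#' @export
bgc_location <- function(start, end, contig_length, crosses_origin = FALSE) {
  start <- as.integer(start)
  end <- as.integer(end)
  contig_length <- as.integer(contig_length)
  if (is.na(start) || is.na(end) || is.na(contig_length)) {
    stop("location coordinates must be non-missing integers")
  }
  if (start < 0L || start >= contig_length) {
    stop(sprintf("start %d out of range [0, %d)", start, contig_length))
  }
  if (end <= 0L || end > contig_length) {
    stop(sprintf("end %d out of range (0, %d]", end, contig_length))
  }
  if (crosses_origin) {
    if (end > start) {
      stop("origin-spanning location requires end <= start")
    }
  } else if (start >= end) {
    stop(sprintf("non-wrapping location requires start < end (got [%d, %d))",
                 start, end))
  }
  structure(
    list(start = start, end = end, contig_length = contig_length,
         crosses_origin = isTRUE(crosses_origin)),
    class = "bgc_location"
  )
}

#' @export
print.bgc_location <- function(x, ...) {
  wrap <- if (x$crosses_origin) " (crosses origin)" else ""
  cat(sprintf("<location [%d, %d) / %d nt%s>\n",
              x$start, x$end, x$contig_length, wrap))
  invisible(x)
}

#' Covered length of a location in nucleotides
#' @param loc A `bgc_location`.
#' @return Integer number of covered nucleotides.
#' @export
loc_length <- function(loc) {
  if (loc$crosses_origin) {
    loc$contig_length - loc$start + loc$end
  } else {
    loc$end - loc$start
  }
}

# Non-wrapping arcs covering the location: matrix with columns start, end.
loc_arcs <- function(loc) {
  if (loc$crosses_origin) {
    rbind(c(loc$start, loc$contig_length), c(0L, loc$end))
  } else {
    rbind(c(loc$start, loc$end))
  }
}

#' Covered positions of a location (0-based)
#' @param loc A `bgc_location`.
#' @return Integer vector of covered offsets.
#' @export
loc_positions <- function(loc) {
  arcs <- loc_arcs(loc)
  unlist(lapply(seq_len(nrow(arcs)), function(i) {
    seq.int(arcs[i, 1], arcs[i, 2] - 1L)
  }))
}

#' Rotate a location on a circular contig
#'
#' Shifts every covered position by `offset` modulo the contig length;
#' the covered set is preserved as a set of (rotated) positions.
#'
#' @param loc A `bgc_location` on a circular contig.
#' @param offset Rotation in nucleotides (any integer).
#' @return The rotated `bgc_location`.
#' @export
rotate_location <- function(loc, offset) {
  len <- loc_length(loc)
  L <- loc$contig_length
  new_start <- (loc$start + offset) %% L
  if (new_start + len <= L) {
    bgc_location(new_start, new_start + len, L, crosses_origin = FALSE)
  } else {
    bgc_location(new_start, new_start + len - L, L, crosses_origin = TRUE)
  }
}

# Minimal circular gap between two non-wrapping arcs [s1,e1) and [s2,e2).
arc_gap <- function(s1, e1, s2, e2, L, circular) {
  if (circular) {
    fwd <- (s2 - e1) %% L
    bwd <- (s1 - e2) %% L
    # overlap check: if either "gap" walked past the other arc's span the
    # arcs intersect; detect by testing containment of endpoints
    if (arcs_overlap(s1, e1, s2, e2, L)) return(0L)
    min(fwd, bwd)
  } else {
    if (s1 < e2 && s2 < e1) return(0L)
    max(0L, max(s2 - e1, s1 - e2))
  }
}

arcs_overlap <- function(s1, e1, s2, e2, L) {
  s1 < e2 && s2 < e1
}

#' Minimal gap between two locations
#'
#' Number of nucleotides strictly between the covered sets of `a` and `b`;
#' 0 when they overlap or abut. On circular contigs both arcs around the
#' circle are considered and the smaller gap is returned.
#'
#' @param a,b `bgc_location` objects on the same contig.
#' @param circular Is the contig circular?
#' @return Integer gap in nucleotides.
#' @export
circular_gap <- function(a, b, circular = TRUE) {
  if (a$contig_length != b$contig_length) {
    stop("locations are on contigs of different length")
  }
  L <- a$contig_length
  arcs_a <- loc_arcs(a)
  arcs_b <- loc_arcs(b)
  gaps <- integer(0)
  for (i in seq_len(nrow(arcs_a))) {
    for (j in seq_len(nrow(arcs_b))) {
      gaps <- c(gaps, arc_gap(arcs_a[i, 1], arcs_a[i, 2],
                              arcs_b[j, 1], arcs_b[j, 2], L, circular))
    }
  }
  as.integer(min(gaps))
}

#' Shortest single arc covering a set of locations
#'
#' On a circular contig the result may span the origin: the union of the
#' input covered sets is merged into maximal arcs and the complement's
#' largest gap determines the covering arc. Ties are broken by the
#' smallest start coordinate. If the inputs cover the whole contig the
#' result is clamped to `[0, contig_length)` without an origin break.
#'
#' @param locations Non-empty list of `bgc_location` on one contig.
#' @param topology `"linear"` or `"circular"`.
#' @return A single `bgc_location`.
#' @export
minimal_covering_arc <- function(locations, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (length(locations) == 0) stop("cannot cover an empty set of locations")
  L <- locations[[1]]$contig_length
  if (!all(vapply(locations, function(l) l$contig_length, integer(1)) == L)) {
    stop("locations are on contigs of different length")
  }
  if (topology == "linear") {
    if (any(vapply(locations, function(l) l$crosses_origin, logical(1)))) {
      stop("origin-spanning location on a linear contig")
    }
    starts <- vapply(locations, function(l) l$start, integer(1))
    ends <- vapply(locations, function(l) l$end, integer(1))
    return(bgc_location(min(starts), max(ends), L))
  }
  # circular: merge all covered arcs, find largest complement gap
  arcs <- do.call(rbind, lapply(locations, loc_arcs))
  merged <- merge_arcs(arcs)
  n <- nrow(merged)
  # gap after arc i (to the start of the next arc, circularly); abutment at
  # the origin (an arc ending at L followed by one starting at 0) is gap 0
  nxt <- c(seq_len(n)[-1], 1L)
  gaps <- (merged[nxt, 1] - merged[, 2]) %% L
  if (max(gaps) == 0L) {
    # union covers the entire contig: whole-contig clamp
    return(bgc_location(0L, L, L))
  }
  best <- which(gaps == max(gaps))
  if (length(best) > 1) {
    # tie between equally large gaps: pick the candidate whose cyclic
    # pattern of (arc length, following gap) read from the arc after the
    # gap is lexicographically smallest. The pattern is invariant under
    # rotation, so the chosen covered set rotates with the inputs (only a
    # perfectly periodic configuration remains ambiguous; then the
    # smallest start wins).
    arc_lens <- merged[, 2] - merged[, 1]
    signature <- function(i) {
      idx <- ((nxt[i] - 1L + seq_len(n) - 1L) %% n) + 1L
      as.vector(rbind(arc_lens[idx], gaps[idx]))
    }
    sigs <- lapply(best, signature)
    ord <- do.call(order, c(as.data.frame(do.call(rbind, sigs)),
                            list(merged[nxt[best], 1])))
    best <- best[ord[1]]
  }
  # covering arc starts at the arc after the largest gap
  i <- best[1]
  s <- merged[nxt[i], 1]
  e <- merged[i, 2]
  if (s < e) bgc_location(s, e, L) else bgc_location(s, e, L, crosses_origin = TRUE)
}

# Merge possibly-overlapping arcs (non-wrapping [s,e) rows) into maximal
# disjoint arcs on the linear axis, ordered by start. Wrap-around abutment
# is handled downstream via circular gap arithmetic.
merge_arcs <- function(arcs) {
  ord <- order(arcs[, 1], arcs[, 2])
  arcs <- arcs[ord, , drop = FALSE]
  out <- arcs[1, , drop = FALSE]
  for (i in seq_len(nrow(arcs))[-1]) {
    last <- nrow(out)
    if (arcs[i, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], arcs[i, 2])
    } else {
      out <- rbind(out, arcs[i, ])
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Extend a location by flanking distances
#'
#' Used to grow a protocluster core into its neighbourhood. On circular
#' contigs the extension wraps around the origin; on linear contigs it is
#' clamped to the contig bounds. An extension meeting itself around the
#' circle is clamped to the whole contig.
#'
#' @param loc A `bgc_location`.
#' @param upstream,downstream Nucleotides to add before the start and after
#'   the end.
#' @param circular Is the contig circular?
#' @return The extended `bgc_location`.
#' @export
extend_location <- function(loc, upstream, downstream = upstream, circular = TRUE) {
  L <- loc$contig_length
  len <- loc_length(loc)
  if (len + upstream + downstream >= L) {
    if (circular) return(bgc_location(0L, L, L))
  }
  if (circular) {
    new_start <- (loc$start - upstream) %% L
    new_len <- min(L, len + upstream + downstream)
    if (new_start + new_len <= L) {
      bgc_location(new_start, new_start + new_len, L)
    } else {
      bgc_location(new_start, new_start + new_len - L, L, crosses_origin = TRUE)
    }
  } else {
    bgc_location(max(0L, loc$start - upstream),
                 min(L, loc$end + downstream), L)
  }
}

#' Do two locations share at least one covered position?
#' @param a,b `bgc_location` objects.
#' @return Logical scalar.
#' @export
loc_overlaps <- function(a, b) {
  arcs_a <- loc_arcs(a)
  arcs_b <- loc_arcs(b)
  for (i in seq_len(nrow(arcs_a))) {
    for (j in seq_len(nrow(arcs_b))) {
      if (arcs_a[i, 1] < arcs_b[j, 2] && arcs_b[j, 1] < arcs_a[i, 2]) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Do two locations cover identical position sets?
#' @param a,b `bgc_location` objects.
#' @return Logical scalar.
#' @export
loc_identical <- function(a, b) {
  a$contig_length == b$contig_length &&
    a$start == b$start && a$end == b$end &&
    a$crosses_origin == b$crosses_origin
}
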