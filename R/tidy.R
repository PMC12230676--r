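# Tidier and plot surfaces: region sets flatten to tibbles for downstream
# dplyr work, and autoplot() draws the genomic layout of detected regions.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a region set into one row per region
#'
#' @param x A `bgc_region_set`.
#' @param ... Unused.
#' @return Tibble with region number, coordinates, covered length,
#'   protocluster count and collapsed product list.
#' @method tidy bgc_region_set
#' @export
tidy.bgc_region_set <- function(x, ...) {
  rows <- lapply(x$regions, function(r) {
    tibble::tibble(
      record_id = x$record_id,
      region_number = r$region_number,
      start = r$location$start,
      end = r$location$end,
      crosses_origin = r$location$crosses_origin,
      length_nt = loc_length(r$location),
      n_protoclusters = length(r$protoclusters),
      products = paste(region_products(r), collapse = ";")
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(record_id = character(), region_number = integer(),
                          start = integer(), end = integer(),
                          crosses_origin = logical(), length_nt = integer(),
                          n_protoclusters = integer(), products = character()))
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a region set
#'
#' @param x A `bgc_region_set`.
#' @param ... Unused.
#' @return Tibble with record id, contig size/topology, region and
#'   protocluster counts, and nucleotides covered by regions.
#' @method glance bgc_region_set
#' @export
glance.bgc_region_set <- function(x, ...) {
  tibble::tibble(
    record_id = x$record_id,
    contig_length = x$contig_length,
    topology = x$topology,
    n_regions = length(x$regions),
    n_protoclusters = sum(vapply(x$regions, function(r) {
      length(r$protoclusters)
    }, integer(1))),
    nt_in_regions = sum(vapply(x$regions, function(r) {
      loc_length(r$location)
    }, integer(1)))
  )
}

#' Tidy a result bundle into one row per region across records
#' @param x A `bgc_result_bundle`.
#' @param ... Unused.
#' @return Tibble of regions over all records.
#' @method tidy bgc_result_bundle
#' @export
tidy.bgc_result_bundle <- function(x, ...) {
  dplyr::bind_rows(lapply(x$results, function(res) tidy(res$region_set)))
}

# split a possibly origin-spanning location into plottable segments
plot_segments <- function(start, end, crosses_origin, contig_length) {
  if (crosses_origin) {
    tibble::tibble(xmin = c(start, 0), xmax = c(contig_length, end))
  } else {
    tibble::tibble(xmin = start, xmax = end)
  }
}

#' Plot detected regions along the contig
#'
#' Draws region spans (split at the origin when they wrap) and the
#' protocluster cores within them.
#'
#' @param object A `bgc_region_set`.
#' @param record Optional `bgc_record`; when given, its genes are drawn
#'   underneath.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bgc_region_set
#' @export
autoplot.bgc_region_set <- function(object, record = NULL, ...) {
  L <- object$contig_length
  region_rows <- dplyr::bind_rows(lapply(object$regions, function(r) {
    seg <- plot_segments(r$location$start, r$location$end,
                         r$location$crosses_origin, L)
    seg$what <- sprintf("region %d", r$region_number)
    seg$products <- paste(region_products(r), collapse = ";")
    seg
  }))
  core_rows <- dplyr::bind_rows(lapply(object$regions, function(r) {
    dplyr::bind_rows(lapply(r$protoclusters, function(p) {
      seg <- plot_segments(p$core_location$start, p$core_location$end,
                           p$core_location$crosses_origin, L)
      seg$products <- p$product
      seg
    }))
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = region_rows,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = 1.05,
                   ymax = 1.45, fill = .data$products), alpha = 0.35) +
    ggplot2::xlim(0, L) +
    ggplot2::labs(x = "contig position (nt)", y = NULL, fill = "product",
                  title = sprintf("%s (%s, %d nt)", object$record_id,
                                  object$topology, L)) +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(0.4, 1.6)) +
    ggplot2::theme_minimal()
  if (nrow(core_rows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = core_rows,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = 1.1,
                   ymax = 1.4, fill = .data$products))
  }
  if (!is.null(record) && nrow(record$cds) > 0) {
    gene_rows <- dplyr::bind_rows(lapply(seq_len(nrow(record$cds)), function(i) {
      plot_segments(record$cds$start[i], record$cds$end[i],
                    record$cds$crosses_origin[i], L)
    }))
    p <- p + ggplot2::geom_rect(
      data = gene_rows,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = 0.6, ymax = 0.95, fill = "grey40")
  }
  p
}
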