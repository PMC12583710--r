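#' Read an scATAC fragment file
#'
#' 4-column TSV (`chrom`, `start`, `end`, `barcode`; 0-based half-open),
#' optionally gzip/bgzip-compressed, no header. Malformed lines (wrong
#' column count, non-numeric or inverted coordinates) raise a parse error
#' naming the line.
#'
#' @param path Fragment file path (`.tsv`, `.tsv.gz`, `.bed`, ...).
#' @return Fragment tibble.
#' @export
read_fragments <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), barcode = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    abort(sprintf("parse-error: fragment line %d has %d field(s), expected >= 4",
                  which(nf < 4L)[1], nf[which(nf < 4L)[1]]),
          class = "sitefx_parse_error")
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- is.na(start) | is.na(end) | start >= end
  if (any(bad)) {
    abort(sprintf("parse-error: fragment line %d has invalid coordinates",
                  which(bad)[1]),
          class = "sitefx_parse_error")
  }
  tibble::tibble(
    chrom = vapply(fields, `[[`, character(1), 1L),
    start = start, end = end,
    barcode = vapply(fields, `[[`, character(1), 4L)
  )
}

#' Write a fragment table as 4-column TSV
#'
#' @param fragments Fragment tibble.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  readr::write_tsv(fragments[, c("chrom", "start", "end", "barcode")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a barcode-to-cluster map
#'
#' 2-column TSV (`barcode`, `cluster_id`), no header.
#'
#' @param path Map path.
#' @return Tibble `barcode`, `cluster_id`.
#' @export
read_barcode_map <- function(path) {
  readr::read_tsv(path, col_names = c("barcode", "cluster_id"),
                  col_types = "cc", progress = FALSE)
}

#' Pool fragments into per-cluster sets
#'
#' Routes every fragment whose barcode is mapped to exactly one cluster;
#' fragments with unmapped barcodes are counted and dropped (never silently
#' lost: the dropped count and the per-cluster totals are attached as the
#' `pooling` attribute).
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`, `barcode`).
#' @param barcode_map Tibble `barcode`, `cluster_id` (non-empty).
#' @return Named list of per-cluster fragment tibbles (one entry per
#'   cluster in the map, empty clusters included), with a `pooling`
#'   attribute summarising input/dropped counts and the duplicate-fragment
#'   rate per cluster.
#' @export
split_by_cluster <- function(fragments, barcode_map) {
  if (nrow(barcode_map) == 0L) {
    abort("invalid-argument: empty barcode map",
          class = "sitefx_invalid_argument")
  }
  joined <- dplyr::left_join(fragments, barcode_map, by = "barcode")
  dropped <- sum(is.na(joined$cluster_id))
  clusters <- unique(barcode_map$cluster_id)
  out <- lapply(clusters, function(cl) {
    dplyr::select(
      dplyr::filter(joined, !is.na(.data$cluster_id), .data$cluster_id == cl),
      "chrom", "start", "end", "barcode")
  })
  names(out) <- clusters
  dup_rate <- vapply(out, function(f) {
    if (nrow(f) == 0L) 0 else 1 - nrow(dplyr::distinct(f)) / nrow(f)
  }, numeric(1))
  attr(out, "pooling") <- tibble::tibble(
    cluster_id = clusters,
    n_fragments = unname(vapply(out, nrow, integer(1))),
    duplicate_rate = unname(dup_rate),
    n_input = nrow(fragments),
    n_dropped = dropped
  )
  out
}

#' Convert fragments to per-strand tagAlign reads
#'
#' Splits each fragment in half to obtain one read per strand: the
#' plus-strand read covers `[start, midpoint)` and the minus-strand read
#' `[midpoint, end)`, with `midpoint = start + floor((end - start)/2)` —
#' so the two reads partition the fragment exactly and each valid fragment
#' yields exactly two reads. Fragments shorter than 2 bp cannot be split
#' and are skipped with a warning (count in the `n_skipped` attribute).
#'
#' @param fragments Fragment tibble.
#' @param sort Sort the output by (chrom, start), default FALSE.
#' @return tagAlign tibble (`chrom`, `start`, `end`, `name` = barcode,
#'   `score` = 1000, `strand`), BED6 layout.
#' @export
fragments_to_tagalign <- function(fragments, sort = FALSE) {
  len <- fragments$end - fragments$start
  short <- len < 2L
  if (any(short)) {
    warn(sprintf("%d fragment(s) shorter than 2 bp skipped", sum(short)))
    fragments <- fragments[!short, , drop = FALSE]
  }
  mid <- fragments$start + (fragments$end - fragments$start) %/% 2L
  plus <- tibble::tibble(
    chrom = fragments$chrom, start = fragments$start, end = mid,
    name = fragments$barcode, score = 1000L, strand = "+"
  )
  minus <- tibble::tibble(
    chrom = fragments$chrom, start = mid, end = fragments$end,
    name = fragments$barcode, score = 1000L, strand = "-"
  )
  out <- dplyr::bind_rows(plus, minus)
  if (sort) out <- dplyr::arrange(out, .data$chrom, .data$start)
  attr(out, "n_skipped") <- sum(short)
  out
}

#' Pool, convert, and write per-cluster tagAlign files
#'
#' The pseudobulk preprocessing pipeline in one call: split fragments by
#' cluster, convert each cluster's fragments to tagAlign reads, and write
#' one gzip-compressed BED6 file per cluster.
#'
#' @param fragments Fragment tibble (or path readable by
#'   [read_fragments()]).
#' @param barcode_map Barcode map tibble (or path).
#' @param out_dir Output directory (created if missing).
#' @param sort Sort reads by (chrom, start), default TRUE.
#' @return Tibble summarising each cluster (`cluster_id`, `n_fragments`,
#'   `n_reads`, `duplicate_rate`, `path`), invisibly.
#' @export
pseudobulk_tagalign <- function(fragments, barcode_map, out_dir,
                                sort = TRUE) {
  if (is.character(fragments)) fragments <- read_fragments(fragments)
  if (is.character(barcode_map)) barcode_map <- read_barcode_map(barcode_map)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pools <- split_by_cluster(fragments, barcode_map)
  summary <- attr(pools, "pooling")
  paths <- character(length(pools))
  n_reads <- integer(length(pools))
  for (i in seq_along(pools)) {
    ta <- fragments_to_tagalign(pools[[i]], sort = sort)
    paths[i] <- file.path(out_dir, paste0(names(pools)[i], ".tagAlign.gz"))
    readr::write_tsv(ta, paths[i], col_names = FALSE)
    n_reads[i] <- nrow(ta)
  }
  invisible(tibble::tibble(
    cluster_id = names(pools),
    n_fragments = summary$n_fragments,
    n_reads = n_reads,
    duplicate_rate = summary$duplicate_rate,
    path = paths
  ))
}
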