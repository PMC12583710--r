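#' Simulate scATAC fragment files with a barcode-to-cluster map
#'
#' Draws fragments uniformly over the genome with sonication-like lengths
#' and assigns them to per-cluster cells with unique barcodes — the raw
#' input of pseudobulk preprocessing. No Tn5 bias, peak structure, or
#' sequencing error is modelled.
#'
#' @param genome A `synthetic_genome` (chromosome names and lengths bound
#'   the fragments).
#' @param n_cells_per_cluster Named integer vector: cells per cluster id.
#' @param frags_per_cell Fragments per cell (>= 0), default 10.
#' @param frag_len_range Inclusive fragment length range, default c(50,
#'   500) (lengths >= 2 so every fragment splits into two reads).
#' @param seed Integer seed.
#'
#' @return List with `fragments` (tibble `chrom`, `start`, `end`,
#'   `barcode`; 0-based half-open, `start < end`) and `barcode_map`
#'   (tibble `barcode`, `cluster_id` covering every emitted barcode).
#' @export
simulate_fragments <- function(genome, n_cells_per_cluster,
                               frags_per_cell = 10L,
                               frag_len_range = c(50L, 500L), seed = NULL) {
  stopifnot(inherits(genome, "synthetic_genome"))
  frags_per_cell <- check_count(frags_per_cell, "frags_per_cell", min = 0L)
  if (length(n_cells_per_cluster) == 0L || is.null(names(n_cells_per_cluster))) {
    abort("invalid-argument: `n_cells_per_cluster` must be a named vector",
          class = "sitefx_invalid_argument")
  }
  stopifnot(length(frag_len_range) == 2L, frag_len_range[1] >= 2L,
            frag_len_range[2] >= frag_len_range[1])
  lens <- chrom_lengths_of(genome)
  if (min(lens) < frag_len_range[2]) {
    frag_len_range[2] <- min(lens)
  }
  with_seed(seed, {
    map <- purrr::map_dfr(names(n_cells_per_cluster), function(cl) {
      nc <- n_cells_per_cluster[[cl]]
      if (nc == 0L) return(NULL)
      tibble::tibble(
        barcode = sprintf("%s_cell%04d", cl, seq_len(nc)),
        cluster_id = cl
      )
    })
    if (nrow(map) == 0L) {
      map <- tibble::tibble(barcode = character(), cluster_id = character())
    }
    if (nrow(map) == 0L || frags_per_cell == 0L) {
      frags <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer(), barcode = character())
      return(list(fragments = frags, barcode_map = map))
    }
    n_frags <- nrow(map) * frags_per_cell
    chrom <- sample(names(lens), n_frags, replace = TRUE, prob = lens)
    flen <- sample(seq(frag_len_range[1], frag_len_range[2]), n_frags,
                   replace = TRUE)
    start <- vapply(seq_len(n_frags), function(i) {
      sample.int(lens[[chrom[i]]] - flen[i] + 1L, 1L) - 1L
    }, integer(1))
    frags <- tibble::tibble(
      chrom = chrom, start = start, end = start + flen,
      barcode = rep(map$barcode, each = frags_per_cell)
    )
    list(fragments = dplyr::arrange(frags, .data$chrom, .data$start),
         barcode_map = map)
  })
}
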