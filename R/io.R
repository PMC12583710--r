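#' Write a synthetic genome to FASTA
#'
#' @param genome A `synthetic_genome`.
#' @param path Output FASTA path.
#' @param index Also write a samtools-style `.fai` index (requires the
#'   Rsamtools package).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, index = FALSE) {
  stopifnot(inherits(genome, "synthetic_genome"))
  dna <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(dna, path, width = 80L)
  if (index) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      abort("Rsamtools is required for index = TRUE")
    }
    Rsamtools::indexFa(path)
  }
  invisible(path)
}

#' Read a FASTA genome
#'
#' @param path FASTA path.
#' @return A `synthetic_genome` (empty motif-instance table).
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(dna)
  # FASTA headers may carry descriptions after the id
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  new_synthetic_genome(seqs)
}

#' Write a variant table
#'
#' Writes either a 5-column TSV (`chrom, pos, id, ref, alt`; positions
#' 1-based) or a minimal VCF 4.2. Internally positions are 0-based; both
#' on-disk formats are 1-based.
#'
#' @param variants Tibble with columns `chrom`, `pos` (0-based), `id`,
#'   `ref`, `alt`.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  out <- tibble::tibble(
    chrom = variants$chrom,
    pos = variants$pos + 1L,
    id = variants$id,
    ref = variants$ref,
    alt = variants$alt
  )
  if (format == "tsv") {
    readr::write_tsv(out, path, col_names = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    ), con)
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       out$chrom, out$pos, out$id, out$ref, out$alt), con)
  }
  invisible(path)
}

#' Read a variant table (TSV or VCF)
#'
#' Accepts the 5-column TSV written by [write_variants()] or a VCF 4.2 file.
#' Only biallelic SNPs are supported; indels and multi-allelic records raise
#' an error.
#'
#' @param path Input path.
#' @return Tibble with columns `chrom`, `pos` (0-based), `id`, `ref`, `alt`.
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    out <- tibble::tibble(
      chrom = vapply(fields, `[[`, character(1), 1L),
      pos = as.integer(vapply(fields, `[[`, character(1), 2L)),
      id = vapply(fields, `[[`, character(1), 3L),
      ref = vapply(fields, `[[`, character(1), 4L),
      alt = vapply(fields, `[[`, character(1), 5L)
    )
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             chrom = readr::col_character(),
                             pos = readr::col_integer(),
                             id = readr::col_character(),
                             ref = readr::col_character(),
                             alt = readr::col_character()
                           ))
  }
  bad <- nchar(out$ref) != 1L | nchar(out$alt) != 1L | grepl(",", out$alt, fixed = TRUE)
  if (any(bad)) {
    abort(sprintf(
      "invalid-argument: %d record(s) are not biallelic SNPs (first: %s); indels/multi-allelics are unsupported",
      sum(bad), out$id[which(bad)[1]]
    ), class = "sitefx_invalid_argument")
  }
  out$pos <- out$pos - 1L  # to 0-based
  out
}

#' Write a variant score table
#'
#' Long table with one row per (variant, context); positions written 1-based.
#'
#' @param scores Score tibble from [score_variants()] (optionally augmented
#'   with empirical p-values).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  out <- scores
  if ("pos" %in% names(out)) {
    out$pos_1based <- out$pos + 1L
    out$pos <- NULL
  }
  readr::write_tsv(out, path)
  invisible(path)
}
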