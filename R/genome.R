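#' Genome build: ordered chromosomes with lengths
#'
#' A minimal container for the chromosome complement the panel is designed
#' against: ordered `(chrom, length_bp)` pairs. Coordinates throughout the
#' package are 0-based half-open (BED convention).
#'
#' @param chrom character vector of unique chromosome ids, in karyotype order.
#' @param length_bp integer vector of chromosome lengths (> 0).
#' @param name build name, free text.
#' @return An object of class `genome_build`: a data.frame with columns
#'   `chrom`, `length_bp` and attribute `name`.
#' @export
#' @examples
#' genome_build(c("SSC1", "SSCX"), c(274330532, 125939595), name = "pig-like")
genome_build <- function(chrom, length_bp, name = "unnamed") {
  chrom <- as.character(chrom)
  length_bp <- as.numeric(length_bp)
  if (anyDuplicated(chrom)) {
    stop("oligoband_error_genome: duplicated chromosome ids", call. = FALSE)
  }
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("oligoband_error_genome: chromosome lengths must be > 0",
         call. = FALSE)
  }
  out <- data.frame(chrom = chrom, length_bp = length_bp,
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("genome_build", "data.frame")
  out
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build '", attr(x, "name"), "': ", nrow(x),
      " chromosomes, ", format(sum(x$length_bp), big.mark = ","),
      " bp>\n", sep = "")
  invisible(x)
}

genome_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) {
    stop("oligoband_error_genome: unknown chromosome id(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  genome$length_bp[i]
}

#' Read a chromosome-sizes table (two-column TSV, .fai-style)
#'
#' Accepts the first two columns of a `samtools faidx` .fai index or any
#' headerless `chrom<TAB>length` file.
#'
#' @param path file path.
#' @param name build name.
#' @return A [genome_build()].
#' @export
read_genome_sizes <- function(path, name = basename(path)) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          select = 1:2, col.names = c("chrom", "length_bp"))
  genome_build(dt$chrom, dt$length_bp, name = name)
}
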