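#' Load candidate 39mer coordinates from BED or TSV
#'
#' Candidate oligos are the genome-homologous 39mer coordinates from which
#' probe windows are selected (typically the output of an upstream mining
#' pipeline, or of [simulate_candidates()]). BED input uses columns
#' chrom/start/end (+ optional name carrying the sequence); TSV input must
#' have a header with at least `chrom`, `start`, `end` and optionally
#' `sequence`. Coordinates are 0-based half-open.
#'
#' @param path BED (`.bed`) or TSV file.
#' @param genome a [genome_build()]; every record's chromosome must exist and
#'   its `end` must not exceed the chromosome length.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `sequence`
#'   (NA when absent), sorted by chromosome then start, deduplicated.
#' @export
load_candidates <- function(path, genome) {
  if (!file.exists(path)) {
    stop("oligoband_error_io: no such file: ", path, call. = FALSE)
  }
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 3L) {
      stop("oligoband_error_io: BED needs >= 3 columns: ", path,
           call. = FALSE)
    }
    dt <- dt[, 1:min(4L, ncol(dt))]
    data.table::setnames(dt, c("chrom", "start", "end",
                               if (ncol(dt) >= 4L) "sequence"))
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(dt))) {
      stop("oligoband_error_io: TSV must have columns chrom,start,end: ",
           path, call. = FALSE)
    }
    dt <- dt[, intersect(c("chrom", "start", "end", "sequence"),
                         names(dt)), with = FALSE]
  }
  if (!"sequence" %in% names(dt)) dt$sequence <- NA_character_
  dt$chrom <- as.character(dt$chrom)
  dt$start <- as.numeric(dt$start)
  dt$end <- as.numeric(dt$end)
  validate_candidates(dt, genome)
}

#' Validate and canonicalize a candidate table
#'
#' @param dt data.frame with `chrom`, `start`, `end` and optionally
#'   `sequence`.
#' @inheritParams load_candidates
#' @return Sorted, deduplicated `data.table`.
#' @export
validate_candidates <- function(dt, genome) {
  dt <- data.table::as.data.table(dt)
  if (!"sequence" %in% names(dt)) dt$sequence <- NA_character_
  bad <- setdiff(unique(dt$chrom), genome$chrom)
  if (length(bad)) {
    stop("oligoband_error_candidates: unknown chromosome id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  len <- genome_length(genome, dt$chrom)
  over <- which(dt$end > len | dt$start < 0)
  if (length(over)) {
    r <- dt[over[1L]]
    stop("oligoband_error_candidates: coordinate outside chromosome: ",
         r$chrom, ":", r$start, "-", r$end, " (chrom length ",
         len[over[1L]], ")", call. = FALSE)
  }
  ord <- order(match(dt$chrom, genome$chrom), dt$start, dt$end)
  dt <- dt[ord]
  dt <- unique(dt, by = c("chrom", "start", "end"))
  dt[]
}
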