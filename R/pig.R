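.pig_cache <- new.env(parent = emptyenv())

#' Pig-like demonstration fixture
#'
#' A synthetic stand-in for the domestic-pig karyotype used throughout the
#' examples and tests: 18 autosomes plus X and Y with rounded public
#' assembly lengths, the published per-chromosome probe counts (a design
#' configuration, not derived), an evenly spaced reference probe panel with
#' realistic coverage, and a seeded demonstration colour scheme.
#'
#' @return `pig_genome()`: a [genome_build()] of the 20 chromosomes.
#' @export
pig_genome <- function() {
  genome_build(
    c("SSC1", "SSC2", "SSC3", "SSC4", "SSC5", "SSC6", "SSC7", "SSC8",
      "SSC9", "SSC10", "SSC11", "SSC12", "SSC13", "SSC14", "SSC15",
      "SSC16", "SSC17", "SSC18", "SSCX", "SSCY"),
    c(274330532, 151935994, 132848913, 130910915, 104526007, 170843587,
      121844099, 138966237, 139512083, 69359453, 79169978, 61602749,
      208334590, 141755446, 140412725, 79944280, 63494081, 55982971,
      125939595, 43547828),
    name = "pig-like (synthetic stand-in)")
}

#' @rdname pig_genome
#' @return `pig_probe_counts()`: named integer vector of probes per
#'   chromosome (97 in total).
#' @export
pig_probe_counts <- function() {
  c(SSC1 = 11L, SSC2 = 6L, SSC3 = 5L, SSC4 = 5L, SSC5 = 4L, SSC6 = 6L,
    SSC7 = 5L, SSC8 = 5L, SSC9 = 5L, SSC10 = 3L, SSC11 = 3L, SSC12 = 3L,
    SSC13 = 11L, SSC14 = 5L, SSC15 = 5L, SSC16 = 3L, SSC17 = 3L,
    SSC18 = 3L, SSCX = 4L, SSCY = 2L)
}

#' @rdname pig_genome
#' @param coverage_bp probe genomic span, default 460 kb.
#' @param termini_margin_bp distance of first/last probe edges from the
#'   chromosome ends, default 6.5 Mb.
#' @param n_oligo oligos per probe window before colour trimming.
#' @return `pig_reference_panel()`: an uncoloured `probe_panel`. Probes
#'   spread between the termini margins with fixed irregular spacing
#'   (successive gaps scaled by a deterministic +-30 percent pattern),
#'   emulating the uneven interprobe distances of real panels; regular
#'   spacing would make distinct derivative decompositions geometrically
#'   indistinguishable.
#' @export
pig_reference_panel <- function(coverage_bp = 4.6e5,
                                termini_margin_bp = 6.5e6,
                                n_oligo = 3000) {
  genome <- pig_genome()
  counts <- pig_probe_counts()
  # fixed gap multipliers, cycled with a per-chromosome phase
  mult <- c(0.70, 1.30, 0.85, 1.20, 0.75, 1.25, 1.00, 0.80, 1.35, 0.95)
  rows <- lapply(names(counts), function(ch) {
    np <- counts[[ch]]
    L <- genome_length(genome, ch)
    lo <- termini_margin_bp + coverage_bp / 2
    hi <- L - termini_margin_bp - coverage_bp / 2
    mids <- if (np == 1L) (lo + hi) / 2 else {
      phase <- match(ch, names(counts)) - 1L
      g <- mult[((phase + seq_len(np - 1L) - 1L) %% length(mult)) + 1L]
      lo + cumsum(c(0, g)) / sum(g) * (hi - lo)
    }
    data.table::data.table(
      probe_id = sprintf("%s_p%d", ch, seq_len(np)),
      chrom = ch,
      start = round(mids - coverage_bp / 2),
      end = round(mids + coverage_bp / 2),
      n_oligo = n_oligo,
      colour = NA_character_,
      rank = seq_len(np),
      idx_first = NA_integer_)
  })
  panel <- data.table::rbindlist(rows)
  panel$density_oligo_per_kb <-
    panel$n_oligo / ((panel$end - panel$start) / 1000)
  data.table::setattr(panel, "genome", genome)
  data.table::setattr(panel, "class", c("probe_panel", class(panel)))
  panel[]
}

#' @rdname pig_genome
#' @param seed scheme-optimizer seed, default 17.
#' @param n_candidates schemes drawn by the optimizer, default 1000.
#' @return `pig_demo_scheme()`: the optimized demonstration `scheme`.
#' @export
pig_demo_scheme <- function(seed = 17, n_candidates = 1000) {
  key <- paste0("scheme_", seed, "_", n_candidates)
  if (is.null(.pig_cache[[key]])) {
    .pig_cache[[key]] <- optimize_scheme(pig_probe_counts(),
                                         n_candidates = n_candidates,
                                         seed = seed)
  }
  .pig_cache[[key]]
}

#' @rdname pig_genome
#' @return `pig_reference_rows()`: the published per-chromosome panel
#'   statistics shipped with the package (inputs for the overall-row
#'   computation).
#' @export
pig_reference_rows <- function() {
  path <- system.file("extdata", "pig_panel_reference.tsv",
                      package = "oligoband")
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname pig_genome
#' @param scheme a scheme for the panel (default: demo scheme).
#' @return `pig_coloured_panel()`: the reference panel with demo-scheme
#'   colours attributed (no oligo-level trimming, since the reference panel
#'   has no candidate backing; single-colour probes are set to 1500 oligos
#'   over the central half of the window).
#' @export
pig_coloured_panel <- function(scheme = pig_demo_scheme()) {
  panel <- pig_reference_panel()
  panel <- data.table::copy(panel)
  for (ch in unique(panel$chrom)) {
    pat <- scheme$patterns[[ch]]
    sel <- which(panel$chrom == ch)
    stopifnot(length(pat) == length(sel))
    panel$colour[sel] <- pat
    for (i in sel) {
      if (!is_paired_token(panel$colour[i])) {
        w <- panel$end[i] - panel$start[i]
        panel$start[i] <- panel$start[i] + round(w / 4)
        panel$end[i] <- panel$end[i] - round(w / 4)
        panel$n_oligo[i] <- 1500L
      }
    }
  }
  panel$density_oligo_per_kb <-
    panel$n_oligo / ((panel$end - panel$start) / 1000)
  panel[]
}
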