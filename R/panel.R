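#' Select probe windows along one chromosome
#'
#' Chooses `n_probes` windows, each a run of `n_oligo` consecutive candidate
#' 39mers, subject to the design rules: windows at least `termini_margin_bp`
#' from both chromosome ends, inter-window gaps at least `min_resolvable_bp`
#' (the minimal distance at which two bands remain optically separable,
#' estimated at 7-8 Mb), and, among feasible placements, each window snapped
#' to the densest (smallest-span) run near its anchor. Anchors sit at equal
#' genomic quantiles of the designable region so probes spread evenly along
#' the chromosome; the densest feasible run whose midpoint falls within half
#' an inter-anchor width of the anchor is taken (ties: closest to anchor,
#' then leftmost), falling back to all feasible runs when the neighbourhood
#' is empty.
#'
#' @param starts,ends numeric vectors of candidate 39mer coordinates
#'   (0-based half-open), sorted by start, for one chromosome.
#' @param chrom_len chromosome length in bp.
#' @param n_probes number of probe windows to place.
#' @param n_oligo oligos per window (default 3000).
#' @param min_resolvable_bp minimal inter-probe gap, default 8e6.
#' @param termini_margin_bp minimal distance of window edges from the
#'   chromosome termini, default 6e6.
#' @return Integer vector of length `n_probes`: the index of the first
#'   candidate of each selected run, in genomic order. Zero-length for
#'   `n_probes = 0`.
#' @export
select_probe_windows <- function(starts, ends, chrom_len, n_probes,
                                 n_oligo = 3000,
                                 min_resolvable_bp = 8e6,
                                 termini_margin_bp = 6e6) {
  if (n_probes == 0L) return(integer(0))
  n <- length(starts)
  if (n < n_oligo) {
    stop("oligoband_error_design: infeasible: ", n, " candidates < n_oligo ",
         n_oligo, call. = FALSE)
  }
  nrun <- n - n_oligo + 1L
  run_start <- starts[seq_len(nrun)]
  run_end <- ends[seq_len(nrun) + n_oligo - 1L]
  span <- run_end - run_start
  mid <- (run_start + run_end) / 2
  minspan <- min(span)

  design_lo <- termini_margin_bp
  design_hi <- chrom_len - termini_margin_bp
  if (design_hi - design_lo < n_probes * minspan +
      (n_probes - 1) * min_resolvable_bp) {
    stop("oligoband_error_design: infeasible: chromosome too short for ",
         n_probes, " windows with min gap ", min_resolvable_bp,
         " and termini margin ", termini_margin_bp, call. = FALSE)
  }
  w <- (design_hi - design_lo) / n_probes
  anchors <- design_lo + (seq_len(n_probes) - 0.5) * w

  chosen <- integer(n_probes)
  prev_end <- -Inf
  for (r in seq_len(n_probes)) {
    lower <- if (r == 1L) design_lo else prev_end + min_resolvable_bp
    upper <- design_hi -
      (n_probes - r) * (min_resolvable_bp + minspan)
    feas <- which(run_start >= lower & run_end <= upper)
    if (!length(feas)) {
      stop("oligoband_error_design: infeasible: no candidate run for probe ",
           r, " with start >= ", lower, " and end <= ", upper,
           " (violated: ",
           if (lower > design_hi) "termini margin" else "spacing/margin",
           ")", call. = FALSE)
    }
    near <- feas[abs(mid[feas] - anchors[r]) <= w / 2]
    pool <- if (length(near)) near else feas
    best <- pool[span[pool] == min(span[pool])]
    if (length(best) > 1L) {
      d <- abs(mid[best] - anchors[r])
      best <- best[d == min(d)]
    }
    i <- best[1L]
    chosen[r] <- i
    prev_end <- run_end[i]
  }
  chosen
}

#' Retain the densest 1500-oligo half of a 3000-oligo window
#'
#' Single-fluorophore probes keep only 1500 of the selected 3000 oligos.
#' Exactly three index-defined groups are evaluated — start-to-middle
#' `[1,1500]`, first-quarter-to-third-quarter `[751,2250]`, middle-to-end
#' `[1501,3000]` — and the group with the smallest genomic span (highest
#' density) is retained; ties go to the earliest group.
#'
#' @param starts,ends coordinates of exactly 3000 sorted candidate oligos.
#' @return Integer vector: indices (into the window) of the retained 1500.
#' @export
pick_densest_1500 <- function(starts, ends) {
  if (length(starts) != 3000L) {
    stop("oligoband_error_design: pick_densest_1500 needs exactly 3000 ",
         "oligos, got ", length(starts), call. = FALSE)
  }
  groups <- list(1:1500, 751:2250, 1501:3000)
  spans <- vapply(groups, function(g) {
    ends[g[length(g)]] - starts[g[1L]]
  }, numeric(1))
  groups[[which.min(spans)]]
}

#' Alternate a 3000-oligo window between the two fluorophores of a pair
#'
#' Paired-colour probes keep all 3000 oligos, 1500 per fluorophore,
#' alternately: odd window indices carry the first fluorophore of the token,
#' even indices the second, so both sub-probes tile the same genomic window.
#'
#' @param n_oligo window size (default 3000; any even count is accepted for
#'   degenerate tests when `strict = FALSE`).
#' @param colour a paired colour token, e.g. `"FAM+A550"`.
#' @param strict require `n_oligo == 3000`.
#' @return Named list of two integer index vectors, one per fluorophore.
#' @export
assign_pair_alternation <- function(n_oligo = 3000, colour, strict = TRUE) {
  fl <- token_fluors(colour)
  if (length(fl) != 2L) {
    stop("oligoband_error_design: assign_pair_alternation needs a paired ",
         "colour token, got ", colour, call. = FALSE)
  }
  if (strict && n_oligo != 3000L) {
    stop("oligoband_error_design: paired probes use 3000 oligos, got ",
         n_oligo, call. = FALSE)
  }
  idx <- seq_len(n_oligo)
  out <- list(idx[idx %% 2L == 1L], idx[idx %% 2L == 0L])
  names(out) <- fl
  out
}

#' Design a probe panel over all chromosomes
#'
#' Runs [select_probe_windows()] per chromosome. Colours (and the
#' single-colour densest-1500 trimming) are applied afterwards with
#' [apply_scheme_to_panel()], because colour attribution is a separate,
#' scheme-level optimization.
#'
#' @param candidates candidate table as returned by [load_candidates()] or
#'   [simulate_candidates()].
#' @param genome a [genome_build()].
#' @param probes_per_chrom named integer vector: number of probes per
#'   chromosome id (a design choice, not derived).
#' @inheritParams select_probe_windows
#' @return A `probe_panel`: data.table with columns `probe_id`, `chrom`,
#'   `start`, `end`, `n_oligo`, `colour` (NA until a scheme is applied),
#'   `density_oligo_per_kb`, `rank` (1 = p-terminal) and `idx_first`
#'   (index of the first window candidate within its chromosome's candidate
#'   table); attribute `genome`.
#' @export
design_panel <- function(candidates, genome, probes_per_chrom,
                         n_oligo = 3000, min_resolvable_bp = 8e6,
                         termini_margin_bp = 6e6) {
  cand <- data.table::as.data.table(candidates)
  rows <- lapply(names(probes_per_chrom), function(ch) {
    np <- probes_per_chrom[[ch]]
    if (np == 0L) return(NULL)
    cc <- cand[cand$chrom == ch]
    if (nrow(cc) == 0L) {
      stop("oligoband_error_design: no candidates on chromosome ", ch,
           call. = FALSE)
    }
    L <- genome_length(genome, ch)
    first <- select_probe_windows(cc$start, cc$end, L, np, n_oligo,
                                  min_resolvable_bp, termini_margin_bp)
    data.table::data.table(
      probe_id = sprintf("%s_p%d", ch, seq_along(first)),
      chrom = ch,
      start = cc$start[first],
      end = cc$end[first + n_oligo - 1L],
      n_oligo = n_oligo,
      colour = NA_character_,
      rank = seq_along(first),
      idx_first = first
    )
  })
  panel <- data.table::rbindlist(rows)
  panel$density_oligo_per_kb <- panel$n_oligo / ((panel$end - panel$start) / 1000)
  data.table::setcolorder(panel, c("probe_id", "chrom", "start", "end",
                                   "n_oligo", "colour",
                                   "density_oligo_per_kb", "rank",
                                   "idx_first"))
  data.table::setattr(panel, "genome", genome)
  data.table::setattr(panel, "class",
                      c("probe_panel", class(panel)))
  panel[]
}

#' Attribute scheme colours to a designed panel
#'
#' Writes each probe's colour token from a banding [scheme][random_scheme],
#' trims single-colour probes to their densest 1500 oligos (updating span,
#' count and density), and keeps paired-colour probes at 3000 oligos with
#' alternating fluorophore assignment.
#'
#' @param panel a `probe_panel` from [design_panel()].
#' @param scheme a scheme whose pattern lengths match the panel's per-
#'   chromosome probe counts.
#' @param candidates the candidate table the panel was designed from.
#' @return The panel with `colour` filled and single-colour probes trimmed.
#' @export
apply_scheme_to_panel <- function(panel, scheme, candidates) {
  cand <- data.table::as.data.table(candidates)
  panel <- data.table::copy(panel)
  for (ch in unique(panel$chrom)) {
    pat <- scheme$patterns[[ch]]
    sel <- which(panel$chrom == ch)
    if (is.null(pat) || length(pat) != length(sel)) {
      stop("oligoband_error_design: scheme pattern for ", ch,
           " has length ", length(pat), ", panel has ", length(sel),
           " probes", call. = FALSE)
    }
    cc <- cand[cand$chrom == ch]
    for (k in seq_along(sel)) {
      i <- sel[k]
      tok <- pat[k]
      panel$colour[i] <- tok
      if (!is_paired_token(tok)) {
        win <- panel$idx_first[i] + 0:(panel$n_oligo[i] - 1L)
        keep <- pick_densest_1500(cc$start[win], cc$end[win])
        kept <- win[keep]
        panel$start[i] <- cc$start[kept[1L]]
        panel$end[i] <- cc$end[kept[length(kept)]]
        panel$n_oligo[i] <- length(kept)
        panel$idx_first[i] <- kept[1L]
      }
    }
  }
  panel$density_oligo_per_kb <-
    panel$n_oligo / ((panel$end - panel$start) / 1000)
  panel[]
}

per_chrom_rows <- function(panel, genome,
                           interprobe = c("gap", "midpoint")) {
  interprobe <- match.arg(interprobe)
  if (nrow(panel) == 0L) {
    stop("oligoband_error_summary: empty panel (zero probes)",
         call. = FALSE)
  }
  chroms <- unique(panel$chrom)
  do.call(rbind, lapply(chroms, function(ch) {
    p <- panel[panel$chrom == ch, ]
    p <- p[order(p$rank), ]
    if (nrow(p) == 0L) {
      stop("oligoband_error_summary: zero-probe chromosome ", ch,
           call. = FALSE)
    }
    L <- genome_length(genome, ch)
    inter <- if (nrow(p) >= 2L) {
      if (interprobe == "gap") {
        mean(p$start[-1L] - p$end[-nrow(p)]) / 1e6
      } else {
        m <- (p$start + p$end) / 2
        mean(diff(m)) / 1e6
      }
    } else NA_real_
    data.frame(
      chrom = ch,
      n_probes = nrow(p),
      mean_density = mean(p$density_oligo_per_kb),
      mean_coverage_kb = mean((p$end - p$start) / 1000),
      mean_interprobe_mb = inter,
      mean_dist_ends_mb = mean(c(p$start[1L], L - p$end[nrow(p)])) / 1e6,
      stringsAsFactors = FALSE
    )
  }))
}

#' Overall (Total) row from per-chromosome panel statistics
#'
#' The overall row is the unweighted mean of the per-chromosome means with
#' the sample standard deviation (n-1 denominator) across chromosomes;
#' `n_probes` is the sum. This is the convention under which the published
#' pig panel's per-chromosome rows reproduce their printed Total row.
#'
#' @param per_chrom data.frame with columns `n_probes`, `mean_density`,
#'   `mean_coverage_kb`, `mean_interprobe_mb`, `mean_dist_ends_mb`.
#' @return One-row data.frame of totals/means plus `sd_*` columns.
#' @export
panel_overall <- function(per_chrom) {
  m <- function(x) mean(x, na.rm = TRUE)
  s <- function(x) stats::sd(x, na.rm = TRUE)
  data.frame(
    n_probes = sum(per_chrom$n_probes),
    mean_density = m(per_chrom$mean_density),
    mean_coverage_kb = m(per_chrom$mean_coverage_kb),
    mean_interprobe_mb = m(per_chrom$mean_interprobe_mb),
    mean_dist_ends_mb = m(per_chrom$mean_dist_ends_mb),
    sd_density = s(per_chrom$mean_density),
    sd_coverage_kb = s(per_chrom$mean_coverage_kb),
    sd_interprobe_mb = s(per_chrom$mean_interprobe_mb),
    sd_dist_ends_mb = s(per_chrom$mean_dist_ends_mb)
  )
}

#' Summarize a probe panel
#'
#' Per-chromosome mean oligo density (oligo/kb), coverage (kb), interprobe
#' distance (Mb; gap between consecutive probe boundaries by default, probe
#' midpoint-to-midpoint optionally) and distance from chromosome ends (Mb;
#' mean of first-probe start from the p-terminus and chromosome length minus
#' last-probe end), plus the overall row from [panel_overall()].
#' Single-probe chromosomes contribute no interprobe value.
#'
#' @inheritParams apply_scheme_to_panel
#' @param genome a [genome_build()]; defaults to the panel's own.
#' @param interprobe `"gap"` (default) or `"midpoint"`.
#' @return A `panel_summary`: list with `per_chrom` and `overall`
#'   data.frames.
#' @export
summarize_panel <- function(panel, genome = attr(panel, "genome"),
                            interprobe = c("gap", "midpoint")) {
  per <- per_chrom_rows(panel, genome, interprobe)
  out <- list(per_chrom = per, overall = panel_overall(per))
  class(out) <- "panel_summary"
  out
}

#' @export
print.panel_summary <- function(x, digits = 2, ...) {
  cat("Probe panel summary (", nrow(x$per_chrom), " chromosomes, ",
      x$overall$n_probes, " probes)\n", sep = "")
  print(format(x$per_chrom, digits = digits), row.names = FALSE)
  cat("Overall:\n")
  print(format(x$overall, digits = digits), row.names = FALSE)
  invisible(x)
}

token_rgb <- function(token) {
  map <- c("FAM" = "0,200,0", "A550" = "230,160,0", "A647" = "220,0,0",
           "FAM+A550" = "180,200,0", "FAM+A647" = "0,160,160",
           "A550+A647" = "230,80,0")
  unname(map[token])
}

#' Export a panel as TSV and BED9
#'
#' The TSV carries probe_id, chrom, start, end, n_oligo, colour and density;
#' the BED9 encodes the colour token in itemRgb. Coordinates stay 0-based
#' half-open (BED native); pass `one_based = TRUE` to emit 1-based closed
#' coordinates in the TSV.
#'
#' @inheritParams apply_scheme_to_panel
#' @param tsv,bed output paths (either may be NULL to skip).
#' @param one_based emit 1-based closed coordinates in the TSV.
#' @return Invisibly, the exported TSV table.
#' @export
write_panel <- function(panel, tsv = NULL, bed = NULL, one_based = FALSE) {
  tab <- data.table::as.data.table(panel)[
    , c("probe_id", "chrom", "start", "end", "n_oligo", "colour",
        "density_oligo_per_kb", "rank")]
  if (one_based) tab$start <- tab$start + 1
  if (!is.null(tsv)) data.table::fwrite(tab, tsv, sep = "\t")
  if (!is.null(bed)) {
    bed9 <- data.table::data.table(
      chrom = panel$chrom, start = panel$start, end = panel$end,
      name = panel$probe_id, score = 0, strand = ".",
      thickStart = panel$start, thickEnd = panel$end,
      itemRgb = token_rgb(panel$colour))
    data.table::fwrite(bed9, bed, sep = "\t", col.names = FALSE)
  }
  invisible(tab)
}
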