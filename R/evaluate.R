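#' Simulator round-trip evaluation of rearrangement calling
#'
#' `eval_rcp_recovery` simulates, per replicate, a karyotype carrying a
#' reciprocal translocation, renders the two derivative chromosomes'
#' multi-channel profiles (the traced-spread granularity at which calling
#' operates), runs the band caller and the split matcher, and scores the
#' replicate as recovered when both derivatives are explained as
#' translocations with the correct donor pair and both breakpoint
#' intervals equal the panel's flanking probe coordinates.
#'
#' @param n_reps number of replicates.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param donors,gaps the reciprocal translocation (defaults: the
#'   demonstration configuration in which donor A loses its last band and
#'   donor B its last four).
#' @param scheme,panel,genome the fixture (defaults: pig demo fixture).
#' @param config a [sim_config()] (default SNR 5).
#' @return List with `rate` (fraction of replicates fully recovered),
#'   `n_reps`, and `detail` (logical vector).
#' @export
eval_rcp_recovery <- function(n_reps = 200, seed = 1,
                              donors = c("SSC3", "SSC6"),
                              gaps = c(4L, 2L),
                              scheme = pig_demo_scheme(),
                              panel = pig_coloured_panel(scheme),
                              genome = pig_genome(),
                              config = sim_config()) {
  r <- rearrangement("rcp", donors, gaps)
  kar <- apply_rearrangement(karyotype_from_scheme(scheme), r)
  iA <- find_derivative(kar, donors[1L]); iB <- find_derivative(kar, donors[2L])
  expected <- list(
    list(donors = donors, prefix = gaps[1L], suffix = gaps[2L] + 1L),
    list(donors = rev(donors), prefix = gaps[2L], suffix = gaps[1L] + 1L))
  ok <- vapply(seq_len(n_reps), function(rep) {
    all(vapply(1:2, function(side) {
      cp <- kar$copies[[c(iA, iB)[side]]]
      sim <- simulate_profile(cp, panel, genome, config,
                              seed = seed + rep * 7L + side,
                              roi_id = cp$name)
      sig <- build_signature(call_bands(sim$profiles), roi_id = cp$name)
      call <- split_match(sig, scheme, max_err = 1, panel = panel,
                          genome = genome)
      if (is.null(call) || call$type != "translocation") return(FALSE)
      exp <- expected[[side]]
      if (!identical(call$donors, exp$donors)) return(FALSE)
      if (call$retained_prefix != exp$prefix ||
          call$suffix_start != exp$suffix) return(FALSE)
      mapped <- map_breakpoint(call, panel, genome)
      chk <- vapply(seq_len(2), function(d) {
        ch <- mapped$breakpoints$chrom[d]
        p <- panel[panel$chrom == ch, ]
        gp <- mapped$breakpoints$gap_after_rank[d]
        mapped$breakpoints$start_bp[d] == p$end[gp] &&
          mapped$breakpoints$end_bp[d] == p$start[gp + 1L]
      }, logical(1))
      all(chk)
    }, logical(1)))
  }, logical(1))
  list(rate = mean(ok), n_reps = n_reps, detail = ok)
}

find_derivative <- function(kar, ch) {
  for (i in seq_along(kar$copies)) {
    cp <- kar$copies[[i]]
    if (cp$chrom == ch && cp$derivative) return(i)
  }
  stop("oligoband_error_evaluate: no derivative of ", ch, call. = FALSE)
}

#' @rdname eval_rcp_recovery
#' @param donor insertion carrier (default SSC10, extra band between
#'   probes 1 and 2, rendered with a token distinct from both flanking
#'   bands as in the motivating case where the extra band was a distinct
#'   colour).
#' @param gap insertion gap index.
#' @export
eval_insertion_recovery <- function(n_reps = 100, seed = 1,
                                    donor = "SSC10", gap = 1L,
                                    scheme = pig_demo_scheme(),
                                    panel = pig_coloured_panel(scheme),
                                    genome = pig_genome(),
                                    config = sim_config()) {
  pat <- scheme$patterns[[donor]]
  flank <- pat[c(gap, min(gap + 1L, length(pat)))]
  ins_tok <- setdiff(colour_tokens(), flank)[1L]
  r <- rearrangement("add", donor, gap, inserted_tokens = ins_tok)
  kar <- apply_rearrangement(karyotype_from_scheme(scheme), r)
  i <- find_derivative(kar, donor)
  ok <- vapply(seq_len(n_reps), function(rep) {
    cp <- kar$copies[[i]]
    sim <- simulate_profile(cp, panel, genome, config,
                            seed = seed + rep * 11L)
    sig <- build_signature(call_bands(sim$profiles), roi_id = cp$name)
    call <- split_match(sig, scheme, max_err = 1, panel = panel,
                        genome = genome)
    !is.null(call) && call$type == "insertion" &&
      call$donors == donor && call$gap == gap
  }, logical(1))
  list(rate = mean(ok), n_reps = n_reps, detail = ok)
}

#' @rdname eval_rcp_recovery
#' @param n_heads simulated sperm heads.
#' @param freqs gamete-class mixture.
#' @param duplication_prob decondensation artefact rate.
#' @return `eval_sperm_accuracy`: list with `accuracy` (fraction of heads
#'   whose classified label matches the truth, counting `"balanced"` as
#'   correct for either alternate class) and `n_heads`.
#' @export
eval_sperm_accuracy <- function(n_heads = 1000, seed = 1,
                                donors = c("SSC3", "SSC6"),
                                gaps = c(4L, 2L),
                                freqs = c(0.25, 0.25, 0.125, 0.125,
                                          0.125, 0.125),
                                duplication_prob = 0,
                                scheme = pig_demo_scheme()) {
  r <- rearrangement("rcp", donors, gaps)
  classes <- enumerate_2_2_segregation(scheme$patterns[[donors[1L]]],
                                       scheme$patterns[[donors[2L]]], r)
  heads <- simulate_sperm_heads(
    classes, freqs, n_heads = n_heads,
    config = sim_config(duplication_prob = duplication_prob), seed = seed)
  labels <- vapply(seq_len(n_heads), function(i) {
    classify_sperm_signals(heads$observed[[i]], classes)$label
  }, character(1))
  correct <- labels == heads$truth |
    (labels == "balanced" &
       heads$truth %in% c("alternate_normal", "alternate_translocated"))
  list(accuracy = mean(correct), n_heads = n_heads)
}
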