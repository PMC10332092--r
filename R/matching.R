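enc_tok <- function(x) tokens_to_int(x)

# min edit cost of `part` against any prefix of `ref`; returns cost and the
# shortest prefix length attaining it
prefix_fit <- function(part, ref) {
  row <- .lev_prefix_row(enc_tok(part), enc_tok(ref))
  p <- which.min(row) - 1L
  list(cost = row[p + 1L], p = p)
}

# min edit cost of `part` against any suffix of `ref`; returns cost and the
# 1-based start index of the shortest suffix attaining it
suffix_fit <- function(part, ref) {
  row <- .lev_prefix_row(rev(enc_tok(part)), rev(enc_tok(ref)))
  t <- which.min(row) - 1L
  list(cost = row[t + 1L], q = length(ref) - t + 1L)
}

#' Match a signature against the reference banding patterns
#'
#' Computes the Levenshtein distance of the signature's token sequence, in
#' both orientations (chromosomes on a spread have no canonical polarity),
#' against every chromosome's reference pattern, and returns the global
#' minimum. Ties prefer forward orientation, then reference order. An empty
#' signature matches the shortest reference with `err` equal to its length
#' and is flagged low-confidence.
#'
#' @param sig a [build_signature()] result, or a character token vector.
#' @param scheme a banding `scheme`.
#' @return A `match_result`: list with `roi_id`, `best_chrom`,
#'   `orientation` (`"forward"`/`"reverse"`), `err`, `ref_tokens`,
#'   `low_confidence`.
#' @export
match_signature <- function(sig, scheme) {
  tokens <- if (inherits(sig, "signature")) sig$tokens else sig
  roi_id <- if (inherits(sig, "signature")) sig$roi_id else "roi"
  pats <- scheme$patterns
  if (!length(pats)) {
    stop("oligoband_error_match: empty scheme", call. = FALSE)
  }
  best <- NULL
  for (orient in c("forward", "reverse")) {
    tt <- if (orient == "forward") tokens else rev(tokens)
    te <- enc_tok(tt)
    for (ch in names(pats)) {
      d <- .lev_int(te, enc_tok(pats[[ch]]))
      if (is.null(best) || d < best$err) {
        best <- list(roi_id = roi_id, best_chrom = ch, orientation = orient,
                     err = d, ref_tokens = pats[[ch]],
                     low_confidence = length(tokens) == 0L)
      }
    }
  }
  class(best) <- "match_result"
  best
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match '", x$roi_id, "': ", x$best_chrom, " (", x$orientation,
      "), err ", x$err, ">\n", sep = "")
  invisible(x)
}

# predicted band fractions along a derivative composed of donor_i bands
# 1..p then donor_j bands q..n_j, with breaks at the midpoints of the
# flanking inter-probe intervals
predict_der_fracs <- function(i, p, j, q, panel, genome) {
  pi_ <- panel[panel$chrom == i, ]; pi_ <- pi_[order(pi_$rank), ]
  pj_ <- panel[panel$chrom == j, ]; pj_ <- pj_[order(pj_$rank), ]
  Li <- genome_length(genome, i); Lj <- genome_length(genome, j)
  mid_i <- (pi_$start + pi_$end) / 2
  mid_j <- (pj_$start + pj_$end) / 2
  break_i <- if (p >= nrow(pi_)) Li else (pi_$end[p] + pi_$start[p + 1L]) / 2
  break_j <- if (q <= 1L) 0 else (pj_$end[q - 1L] + pj_$start[q]) / 2
  pos <- c(mid_i[seq_len(p)], break_i + (mid_j[q:nrow(pj_)] - break_j))
  total <- break_i + (Lj - break_j)
  pos / total
}

band_centres <- function(sig) {
  if (is.null(sig$positions) || nrow(sig$positions) == 0L) return(NULL)
  rowMeans(sig$positions)
}

#' Explain an anomalous signature as a rearrangement
#'
#' Searches all derivative-chromosome decompositions of the signature: a
#' prefix matched against a prefix of donor `i`'s pattern plus a suffix
#' matched against a suffix of donor `j`'s pattern (`i != j`), in both
#' signature orientations, keeping decompositions whose total edit cost is
#' at most `max_err` and strictly below the best single-chromosome error
#' (parsimony guard). A valid single-token insertion relative to one
#' reference is preferred over a two-donor decomposition when both explain
#' the signature at equal total penalty (one breakpoint beats two). Among
#' tied decompositions, when band positions and the reference panel are
#' available, the decomposition whose predicted band fractions best fit the
#' observed band centres wins; remaining ties prefer forward orientation,
#' then donor order, then the largest retained prefix.
#'
#' @param sig a `signature` (band positions used when present) or token
#'   vector.
#' @param scheme banding `scheme`.
#' @param max_err maximal edit cost of an accepted explanation, default 1.
#' @param panel,genome optional coloured `probe_panel` and [genome_build()]
#'   enabling the positional tie-break.
#' @return A `rearrangement_call` list (`type` one of `"translocation"`,
#'   `"insertion"`, `"unknown"`), or `NULL` when the signature matches a
#'   reference exactly (normal) or deviates within `max_err` without a
#'   structural explanation (measurement artefact).
#' @export
split_match <- function(sig, scheme, max_err = 1, panel = NULL,
                        genome = NULL) {
  tokens <- if (inherits(sig, "signature")) sig$tokens else sig
  roi_id <- if (inherits(sig, "signature")) sig$roi_id else "roi"
  single <- match_signature(sig, scheme)
  if (single$err == 0L) return(NULL)
  pats <- scheme$patterns
  chroms <- names(pats)
  len <- length(tokens)

  # single-token insertion: deleting one signature token recovers a
  # reference exactly
  insertion <- NULL
  if (len >= 2L) {
    for (orient in c("forward", "reverse")) {
      tt <- if (orient == "forward") tokens else rev(tokens)
      for (ch in chroms) {
        if (length(pats[[ch]]) != len - 1L) next
        for (d in seq_len(len)) {
          if (identical(tt[-d], pats[[ch]])) {
            insertion <- list(type = "insertion", roi_id = roi_id,
                              donors = ch, orientation = orient,
                              gap = c(d - 1L),
                              inserted_token = tt[d], cost = 1L)
            break
          }
        }
        if (!is.null(insertion)) break
      }
      if (!is.null(insertion)) break
    }
  }

  # two-donor decompositions
  decomps <- list()
  if (len >= 2L) {
    for (orient in c("forward", "reverse")) {
      tt <- if (orient == "forward") tokens else rev(tokens)
      for (i in chroms) {
        for (j in chroms) {
          if (i == j) next
          for (k in 1:(len - 1L)) {
            pf <- prefix_fit(tt[1:k], pats[[i]])
            if (pf$p < 1L || pf$cost > max_err) next
            sf <- suffix_fit(tt[(k + 1L):len], pats[[j]])
            if (sf$q > length(pats[[j]]) || pf$cost + sf$cost > max_err) next
            decomps[[length(decomps) + 1L]] <- list(
              type = "translocation", roi_id = roi_id,
              donors = c(i, j), orientation = orient,
              split_sig_index = k, retained_prefix = pf$p,
              suffix_start = sf$q, cost = pf$cost + sf$cost)
          }
        }
      }
    }
  }
  # parsimony guard: never costlier than explaining via one chromosome
  decomps <- Filter(function(d) d$cost < single$err, decomps)

  best_decomp <- NULL
  if (length(decomps)) {
    costs <- vapply(decomps, `[[`, numeric(1), "cost")
    cand <- decomps[costs == min(costs)]
    if (length(cand) > 1L && !is.null(panel) && !is.null(genome) &&
        inherits(sig, "signature") && !is.null(band_centres(sig))) {
      obs <- band_centres(sig)
      fit <- vapply(cand, function(d) {
        pred <- predict_der_fracs(d$donors[1], d$retained_prefix,
                                  d$donors[2], d$suffix_start,
                                  panel, genome)
        oo <- if (d$orientation == "forward") obs else rev(1 - obs)
        if (length(pred) != length(oo)) return(Inf)
        sqrt(mean((pred - oo)^2))
      }, numeric(1))
      cand <- cand[fit == min(fit)]
    }
    ord <- order(vapply(cand, function(d) d$orientation != "forward",
                        logical(1)),
                 match(vapply(cand, function(d) d$donors[1], character(1)),
                       chroms),
                 match(vapply(cand, function(d) d$donors[2], character(1)),
                       chroms),
                 -vapply(cand, `[[`, integer(1), "retained_prefix"))
    best_decomp <- cand[[ord[1L]]]
  }

  # one breakpoint beats two at equal edit penalty
  out <- if (!is.null(insertion) &&
             (is.null(best_decomp) || best_decomp$cost + 1L >= 1L)) {
    insertion
  } else if (!is.null(best_decomp)) {
    best_decomp
  } else if (single$err > max_err) {
    list(type = "unknown", roi_id = roi_id, donors = single$best_chrom,
         cost = single$err)
  } else {
    NULL
  }
  if (!is.null(out)) class(out) <- "rearrangement_call"
  out
}

#' Map a rearrangement call to genomic breakpoint intervals
#'
#' The breakpoint on each donor lies between the last retained probe and
#' the first lost/adjacent probe; the interval bounds are those probes'
#' panel coordinates. A split beyond the terminal probe maps to an open
#' terminal interval flagged `reciprocity_undetermined`, since exchange of
#' material distal to the last probe cannot be observed.
#'
#' @param call a `rearrangement_call` from [split_match()].
#' @param panel a `probe_panel` covering the donors.
#' @param genome a [genome_build()].
#' @return The call with a `breakpoints` data.frame (`chrom`, `start_bp`,
#'   `end_bp`, `gap_after_rank`, `terminal`, `note`).
#' @export
map_breakpoint <- function(call, panel, genome) {
  gap_interval <- function(ch, gap_after) {
    p <- panel[panel$chrom == ch, ]
    p <- p[order(p$rank), ]
    n <- nrow(p)
    if (gap_after < 0L || gap_after > n) {
      stop("oligoband_error_breakpoint: gap index ", gap_after,
           " out of range for ", ch, " (", n, " probes)", call. = FALSE)
    }
    if (gap_after == 0L) {
      data.frame(chrom = ch, start_bp = 0, end_bp = p$start[1L],
                 gap_after_rank = 0L, terminal = TRUE,
                 note = "reciprocity undetermined beyond terminal probe",
                 stringsAsFactors = FALSE)
    } else if (gap_after == n) {
      data.frame(chrom = ch, start_bp = p$end[n],
                 end_bp = genome_length(genome, ch),
                 gap_after_rank = n, terminal = TRUE,
                 note = "reciprocity undetermined beyond terminal probe",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = ch, start_bp = p$end[gap_after],
                 end_bp = p$start[gap_after + 1L],
                 gap_after_rank = gap_after, terminal = FALSE,
                 note = "", stringsAsFactors = FALSE)
    }
  }
  bp <- switch(call$type,
    translocation = rbind(
      gap_interval(call$donors[1L], call$retained_prefix),
      gap_interval(call$donors[2L], call$suffix_start - 1L)),
    insertion = gap_interval(call$donors[1L], call$gap),
    stop("oligoband_error_breakpoint: cannot map a call of type ",
         call$type, call. = FALSE))
  call$breakpoints <- bp
  call
}

#' Spread-level karyotype report
#'
#' Matches every traced signature of every spread, attempts a rearrangement
#' explanation for anomalous ones, and aggregates across spreads: a
#' rearrangement is reported only when observed in at least
#' `majority_frac` of the spreads and at least `min_spreads` spreads were
#' analyzed. Complementary derivative calls (donors `(a,b)` and `(b,a)`)
#' merge into one reciprocal-translocation call. Isolated single-spread
#' anomalies with err <= 1 are demoted as probable artefacts.
#'
#' @param spreads list of spreads; each spread is a list of `signature`
#'   objects.
#' @param scheme banding `scheme`.
#' @param panel,genome optional panel/genome for breakpoint mapping and the
#'   positional tie-break.
#' @param expected_count expected chromosome count per intact spread,
#'   default 38.
#' @param min_spreads,majority_frac reporting thresholds (defaults 5, 0.8).
#' @param max_err passed to [split_match()].
#' @return A `karyotype_report`: list with `status`, `calls` (each with
#'   `supporting_spreads`), `per_spread` diagnostics.
#' @export
call_karyotype <- function(spreads, scheme, panel = NULL, genome = NULL,
                           expected_count = 38, min_spreads = 5,
                           majority_frac = 0.8, max_err = 1) {
  stopifnot(length(spreads) >= 1L)
  per_spread <- lapply(seq_along(spreads), function(si) {
    sigs <- spreads[[si]]
    matches <- lapply(sigs, match_signature, scheme = scheme)
    anomalies <- list()
    for (g in seq_along(sigs)) {
      if (matches[[g]]$err > 0L) {
        call <- split_match(sigs[[g]], scheme, max_err = max_err,
                            panel = panel, genome = genome)
        if (!is.null(call)) anomalies[[length(anomalies) + 1L]] <- call
      }
    }
    inventory <- table(vapply(matches, `[[`, character(1), "best_chrom"))
    list(n_traced = length(sigs), complete = length(sigs) >= expected_count,
         inventory = inventory, matches = matches, anomalies = anomalies)
  })
  key_of <- function(a) {
    switch(a$type,
      translocation = paste("t", a$donors[1L], a$retained_prefix,
                            a$donors[2L], a$suffix_start, sep = ":"),
      insertion = paste("ins", a$donors[1L], a$gap, sep = ":"),
      paste("unknown", paste(a$donors, collapse = ","), sep = ":"))
  }
  seen <- list()
  for (si in seq_along(per_spread)) {
    for (a in per_spread[[si]]$anomalies) {
      k <- key_of(a)
      if (is.null(seen[[k]])) seen[[k]] <- list(call = a, spreads = integer(0))
      seen[[k]]$spreads <- union(seen[[k]]$spreads, si)
    }
  }
  n_spreads <- length(spreads)
  confirmed <- list()
  if (n_spreads >= min_spreads) {
    for (k in names(seen)) {
      supp <- length(seen[[k]]$spreads)
      a <- seen[[k]]$call
      # artefact demotion: a singleton near-miss is not a call
      if (supp == 1L && !is.null(a$cost) && a$cost <= 1L &&
          n_spreads > 1L) next
      if (supp >= majority_frac * n_spreads) {
        a$supporting_spreads <- supp
        confirmed[[length(confirmed) + 1L]] <- a
      }
    }
  }
  # merge complementary derivative calls into reciprocal translocations
  calls <- list(); used <- rep(FALSE, length(confirmed))
  for (i in seq_along(confirmed)) {
    if (used[i]) next
    a <- confirmed[[i]]
    if (a$type == "translocation") {
      mate <- NULL
      for (j in seq_along(confirmed)) {
        if (j == i || used[j]) next
        b <- confirmed[[j]]
        if (b$type == "translocation" &&
            identical(sort(b$donors), sort(a$donors)) &&
            !identical(b$donors, a$donors)) { mate <- j; break }
      }
      if (!is.null(mate)) {
        b <- confirmed[[mate]]; used[mate] <- TRUE
        merged <- list(type = "reciprocal_translocation",
                       donors = sort(a$donors),
                       derivatives = list(a, b),
                       supporting_spreads = min(a$supporting_spreads,
                                                b$supporting_spreads))
        if (!is.null(panel) && !is.null(genome)) {
          am <- map_breakpoint(a, panel, genome)
          merged$breakpoints <- am$breakpoints
        }
        class(merged) <- "rearrangement_call"
        calls[[length(calls) + 1L]] <- merged
        used[i] <- TRUE
        next
      }
    }
    if (!is.null(panel) && !is.null(genome) &&
        a$type %in% c("translocation", "insertion")) {
      a <- map_breakpoint(a, panel, genome)
    }
    calls[[length(calls) + 1L]] <- a
    used[i] <- TRUE
  }
  structure(list(
    status = if (length(calls)) "rearranged" else "normal",
    calls = calls,
    n_spreads = n_spreads,
    per_spread = lapply(per_spread, function(s) {
      s$matches <- NULL; s
    })), class = "karyotype_report")
}

#' @export
print.karyotype_report <- function(x, ...) {
  cat("Karyotype report over", x$n_spreads, "spread(s):", x$status, "\n")
  for (a in x$calls) {
    cat(" -", a$type, "donors:", paste(a$donors, collapse = ";"),
        "support:", a$supporting_spreads, "\n")
  }
  invisible(x)
}

strip_chrom <- function(ch) sub("^[A-Za-z]+", "", ch)

#' Format a rearrangement call in G-band (ISCN-style) nomenclature
#'
#' Uses a user-supplied equivalence table mapping oligo-banding landmarks to
#' G-band labels. The table has columns `chrom`, `kind` (`"gap"` for an
#' inter-probe gap, `"probe"` for a probe), `index` (gap index after the
#' given rank, or probe rank) and `gband` (e.g. `"q15"`). Reciprocal
#' translocations format as `rcp(a;b)(ga;gb)` from the two donor gap labels;
#' insertions as `add(c)(pter->x::?::y->qter)` from the flanking probe
#' labels. Uncovered landmarks render as `"?"` with a warning.
#'
#' @param call a mapped `rearrangement_call`.
#' @param equivalence equivalence data.frame (or TSV path).
#' @return A single formatted string.
#' @export
to_gband_nomenclature <- function(call, equivalence) {
  if (is.character(equivalence) && length(equivalence) == 1L) {
    equivalence <- data.table::fread(equivalence, sep = "\t")
  }
  eq <- as.data.frame(equivalence)
  lookup <- function(ch, kind, index) {
    hit <- eq[eq$chrom == ch & eq$kind == kind & eq$index == index, ]
    if (nrow(hit) == 0L) {
      warning("no G-band equivalence for ", ch, " ", kind, " ", index,
              call. = FALSE)
      return("?")
    }
    hit$gband[1L]
  }
  if (call$type %in% c("reciprocal_translocation", "translocation")) {
    d <- call$donors
    gaps <- if (call$type == "translocation") {
      c(call$retained_prefix, call$suffix_start - 1L)
    } else {
      der <- call$derivatives[[1L]]
      g <- c(der$retained_prefix, der$suffix_start - 1L)
      if (identical(der$donors, d)) g else rev(g)
    }
    sprintf("rcp(%s;%s)(%s;%s)",
            strip_chrom(d[1L]), strip_chrom(d[2L]),
            lookup(d[1L], "gap", gaps[1L]), lookup(d[2L], "gap", gaps[2L]))
  } else if (call$type == "insertion") {
    ch <- call$donors[1L]
    before <- lookup(ch, "probe", call$gap)
    after <- lookup(ch, "probe", call$gap + 1L)
    sprintf("add(%s)(pter->%s::?::%s->qter)", strip_chrom(ch), before, after)
  } else {
    sprintf("?(%s)", paste(strip_chrom(call$donors), collapse = ";"))
  }
}
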