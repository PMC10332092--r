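#' Build a karyotype from a banding scheme
#'
#' A karyotype is a list of chromosome copies, each carrying its ordered
#' band tokens and per-band provenance (donor chromosome and original band
#' rank). The normal pig complement is 18 autosome pairs plus XY or XX
#' (38 chromosomes); chromosomes whose id ends in `X`/`Y` get one copy each
#' under `sex = "XY"`, two X under `"XX"` (no Y).
#'
#' @param scheme a banding `scheme` covering every chromosome.
#' @param sex `"XY"` (default) or `"XX"`.
#' @return A `karyotype`: list of copies, each
#'   `list(chrom, homolog, tokens, provenance, derivative)`.
#' @export
karyotype_from_scheme <- function(scheme, sex = c("XY", "XX")) {
  sex <- match.arg(sex)
  copies <- list()
  for (ch in names(scheme$patterns)) {
    toks <- scheme$patterns[[ch]]
    prov <- data.frame(donor = ch, rank = seq_along(toks),
                       stringsAsFactors = FALSE)
    is_x <- grepl("X$", ch); is_y <- grepl("Y$", ch)
    n_cop <- if (is_y) {
      if (sex == "XY") 1L else 0L
    } else if (is_x) {
      if (sex == "XY") 1L else 2L
    } else 2L
    for (h in seq_len(n_cop)) {
      copies[[length(copies) + 1L]] <-
        list(chrom = ch, homolog = h, tokens = toks, provenance = prov,
             derivative = FALSE)
    }
  }
  structure(list(copies = copies, sex = sex), class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  nder <- sum(vapply(x$copies, `[[`, logical(1), "derivative"))
  cat("<karyotype: ", length(x$copies), " chromosomes (", x$sex, "), ",
      nder, " derivative(s)>\n", sep = "")
  invisible(x)
}

#' Describe a chromosomal rearrangement
#'
#' Breakpoints live in inter-band gaps (probe granularity): gap index `k`
#' means between band `k` and `k+1`, with `0` before the first band and
#' `n` after the last. Types: `rcp` (reciprocal translocation; two donors,
#' exchange of the material distal to each gap), `t_nonreciprocal` (a donor
#' fragment joins an acceptor terminus; acceptor loses nothing), `add`
#' (insertion of material of stated token content at a gap of one donor).
#'
#' @param type `"rcp"`, `"t_nonreciprocal"` or `"add"`.
#' @param donors one or two chromosome ids (for `t_nonreciprocal`:
#'   `c(donor, acceptor)`).
#' @param gaps integer gap index per donor (length 2 for `rcp`, 1
#'   otherwise).
#' @param inserted_tokens token vector for `add`.
#' @param segment for `t_nonreciprocal`: `"p"` (bands `1..k` break off) or
#'   `"q"` (bands `k+1..n`).
#' @param attach_to for `t_nonreciprocal`: acceptor terminus, `"qter"` or
#'   `"pter"`.
#' @return A `rearrangement` list.
#' @export
rearrangement <- function(type = c("rcp", "t_nonreciprocal", "add"),
                          donors, gaps, inserted_tokens = NULL,
                          segment = "p", attach_to = "qter") {
  type <- match.arg(type)
  if (type == "rcp" && (length(donors) != 2L || length(gaps) != 2L)) {
    stop("oligoband_error_rearrangement: rcp needs two donors and two gaps",
         call. = FALSE)
  }
  if (type == "add" && is.null(inserted_tokens)) {
    stop("oligoband_error_rearrangement: add needs inserted tokens",
         call. = FALSE)
  }
  if (type == "t_nonreciprocal" && length(donors) != 2L) {
    stop("oligoband_error_rearrangement: t_nonreciprocal needs donor and ",
         "acceptor", call. = FALSE)
  }
  structure(list(type = type, donors = donors, gaps = gaps,
                 inserted_tokens = inserted_tokens, segment = segment,
                 attach_to = attach_to),
            class = "rearrangement")
}

check_gap <- function(k, n, ch) {
  if (k < 0L || k > n) {
    stop("oligoband_error_rearrangement: gap ", k, " invalid for ", ch,
         " with ", n, " bands", call. = FALSE)
  }
}

# prefer the normal copy; fall back to the derivative of the same homolog
# (so that re-applying a reciprocal translocation at the same gaps inverts it)
find_copy <- function(kar, ch, homolog = 1L) {
  fallback <- NA_integer_
  for (i in seq_along(kar$copies)) {
    cp <- kar$copies[[i]]
    if (cp$chrom == ch && cp$homolog == homolog) {
      if (!cp$derivative) return(i)
      fallback <- i
    }
  }
  if (!is.na(fallback)) return(fallback)
  stop("oligoband_error_rearrangement: no copy of ", ch,
       " (homolog ", homolog, ") in karyotype", call. = FALSE)
}

#' Apply a rearrangement to a karyotype
#'
#' One homolog of each donor is replaced by the corresponding derivative;
#' all other copies are untouched. For `rcp`, the distal segments beyond
#' the two gaps are swapped with orientation preserved. For
#' `t_nonreciprocal`, the acceptor gains the donor's broken-off segment at
#' the stated terminus (a p-side fragment joining a q-terminus is appended
#' in reversed band order, since the fragment joins by its broken end).
#' For `add`, the inserted tokens appear at the stated gap with donor
#' recorded as `"?"`.
#'
#' @param kar a `karyotype`.
#' @param r a [rearrangement()].
#' @return The modified `karyotype`; derivatives are flagged and named
#'   (e.g. `der(SSC3)`).
#' @export
apply_rearrangement <- function(kar, r) {
  prov_of <- function(cp) cp$provenance
  if (r$type == "rcp") {
    ia <- find_copy(kar, r$donors[1L]); ib <- find_copy(kar, r$donors[2L])
    A <- kar$copies[[ia]]; B <- kar$copies[[ib]]
    ka <- r$gaps[1L]; kb <- r$gaps[2L]
    check_gap(ka, length(A$tokens), A$chrom)
    check_gap(kb, length(B$tokens), B$chrom)
    idxA <- seq_len(ka); idxB <- seq_len(kb)
    derA_tok <- c(A$tokens[idxA], B$tokens[setdiff(seq_along(B$tokens), idxB)])
    derB_tok <- c(B$tokens[idxB], A$tokens[setdiff(seq_along(A$tokens), idxA)])
    derA_prov <- rbind(A$provenance[idxA, , drop = FALSE],
                       B$provenance[setdiff(seq_along(B$tokens), idxB), ,
                                    drop = FALSE])
    derB_prov <- rbind(B$provenance[idxB, , drop = FALSE],
                       A$provenance[setdiff(seq_along(A$tokens), idxA), ,
                                    drop = FALSE])
    kar$copies[[ia]] <- list(chrom = A$chrom, homolog = A$homolog,
                             tokens = derA_tok, provenance = derA_prov,
                             derivative = TRUE,
                             name = paste0("der(", A$chrom, ")"))
    kar$copies[[ib]] <- list(chrom = B$chrom, homolog = B$homolog,
                             tokens = derB_tok, provenance = derB_prov,
                             derivative = TRUE,
                             name = paste0("der(", B$chrom, ")"))
  } else if (r$type == "t_nonreciprocal") {
    id <- find_copy(kar, r$donors[1L]); ia <- find_copy(kar, r$donors[2L])
    D <- kar$copies[[id]]; A <- kar$copies[[ia]]
    k <- r$gaps[1L]
    check_gap(k, length(D$tokens), D$chrom)
    seg_idx <- if (r$segment == "p") seq_len(k) else
      setdiff(seq_along(D$tokens), seq_len(k))
    keep_idx <- setdiff(seq_along(D$tokens), seg_idx)
    seg_tok <- D$tokens[seg_idx]; seg_prov <- D$provenance[seg_idx, ,
                                                           drop = FALSE]
    flip <- (r$segment == "p" && r$attach_to == "qter") ||
      (r$segment == "q" && r$attach_to == "pter")
    if (flip) {
      seg_tok <- rev(seg_tok)
      seg_prov <- seg_prov[rev(seq_len(nrow(seg_prov))), , drop = FALSE]
    }
    if (r$attach_to == "qter") {
      acc_tok <- c(A$tokens, seg_tok)
      acc_prov <- rbind(A$provenance, seg_prov)
    } else {
      acc_tok <- c(seg_tok, A$tokens)
      acc_prov <- rbind(seg_prov, A$provenance)
    }
    kar$copies[[id]] <- list(chrom = D$chrom, homolog = D$homolog,
                             tokens = D$tokens[keep_idx],
                             provenance = D$provenance[keep_idx, ,
                                                       drop = FALSE],
                             derivative = TRUE,
                             name = paste0("der(", D$chrom, ")"))
    kar$copies[[ia]] <- list(chrom = A$chrom, homolog = A$homolog,
                             tokens = acc_tok, provenance = acc_prov,
                             derivative = TRUE,
                             name = paste0("der(", A$chrom, ")"))
  } else {  # add
    ia <- find_copy(kar, r$donors[1L])
    A <- kar$copies[[ia]]
    k <- r$gaps[1L]
    check_gap(k, length(A$tokens), A$chrom)
    ins_prov <- data.frame(donor = "?",
                           rank = seq_along(r$inserted_tokens),
                           stringsAsFactors = FALSE)
    kar$copies[[ia]] <- list(
      chrom = A$chrom, homolog = A$homolog,
      tokens = append(A$tokens, r$inserted_tokens, after = k),
      provenance = rbind(A$provenance[seq_len(k), , drop = FALSE],
                         ins_prov,
                         A$provenance[setdiff(seq_along(A$tokens),
                                              seq_len(k)), , drop = FALSE]),
      derivative = TRUE,
      name = paste0("der(", A$chrom, ")"))
  }
  kar
}

#' Banding pattern of a (derivative) chromosome copy
#'
#' @param copy one element of `karyotype$copies`.
#' @return Ordered token vector, directly comparable by
#'   [match_signature()] / [split_match()].
#' @export
derivative_signature <- function(copy) copy$tokens

#' Genomic band positions along a chromosome copy
#'
#' Maps each band to its fraction of the copy's total length, using the
#' panel's probe coordinates; for derivatives, segment lengths follow the
#' provenance with breaks at the midpoints of the flanking inter-probe
#' intervals. Inserted `"?"` material is given a nominal 1 Mb extent.
#'
#' @param copy a karyotype copy.
#' @param panel a coloured `probe_panel`.
#' @param genome a [genome_build()].
#' @return List with `fracs` (band midpoints, fractions of copy length)
#'   and `length_bp`.
#' @export
copy_band_positions <- function(copy, panel, genome) {
  prov <- copy$provenance
  # split provenance into maximal same-donor runs of consecutive ranks
  runs <- list(); cur <- 1L
  if (nrow(prov) > 1L) {
    for (i in 2:nrow(prov)) {
      contiguous <- prov$donor[i] == prov$donor[i - 1L] &&
        abs(prov$rank[i] - prov$rank[i - 1L]) == 1L
      if (!contiguous) { runs[[length(runs) + 1L]] <- cur:(i - 1L); cur <- i }
    }
  }
  runs[[length(runs) + 1L]] <- cur:nrow(prov)
  offset <- 0; pos <- numeric(0)
  for (ri in seq_along(runs)) {
    rows <- prov[runs[[ri]], , drop = FALSE]
    if (rows$donor[1L] == "?") {
      seg_len <- 1e6 * nrow(rows)
      pos <- c(pos, offset + (seq_len(nrow(rows)) - 0.5) * 1e6)
      offset <- offset + seg_len
      next
    }
    ch <- rows$donor[1L]
    p <- panel[panel$chrom == ch, ]; p <- p[order(p$rank), ]
    L <- genome_length(genome, ch)
    mids <- (p$start + p$end) / 2
    rk <- rows$rank
    lo_rank <- min(rk); hi_rank <- max(rk)
    seg_start <- if (lo_rank == 1L) 0 else
      (p$end[lo_rank - 1L] + p$start[lo_rank]) / 2
    seg_end <- if (hi_rank == nrow(p)) L else
      (p$end[hi_rank] + p$start[hi_rank + 1L]) / 2
    rev_run <- length(rk) > 1L && rk[1L] > rk[length(rk)]
    band_off <- if (!rev_run) mids[rk] - seg_start else seg_end - mids[rk]
    pos <- c(pos, offset + band_off)
    offset <- offset + (seg_end - seg_start)
  }
  list(fracs = pos / offset, length_bp = offset)
}
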