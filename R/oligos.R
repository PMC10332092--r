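#' Scan a genome for candidate 39mers
#'
#' Simplified stand-in for an alignment-backed mining pipeline: every 39 bp
#' window passing all of the following is a candidate. Soft-masked
#' (lowercase) and N bases are treated as masked and excluded; GC fraction
#' and nearest-neighbor Tm must fall in their windows; homopolymer runs must
#' not exceed `homopolymer_max`; and every constituent k-mer must occur at
#' most `kmer_max_count` times genome-wide (hash-based uniqueness screen
#' standing in for alignment). Scan order is deterministic (chromosomes in
#' input order, positions left to right) and the result is invariant to
#' chromosome processing order.
#'
#' @param fasta path to a FASTA file (read via Biostrings), or a named
#'   character vector of chromosome sequences.
#' @param gc_window numeric length-2, allowed GC fraction, default
#'   `c(0.2, 0.8)`.
#' @param tm_window numeric length-2, allowed Tm (C) under [tm_nn()],
#'   default `c(60, 90)`.
#' @param homopolymer_max maximal run of one base, default 5.
#' @param kmer_k uniqueness k-mer length, default 18.
#' @param kmer_max_count maximal genome-wide count per k-mer, default 1.
#' @return data.table with `chrom`, `start`, `end` (0-based half-open),
#'   `sequence` (uppercase).
#' @export
filter_39mers <- function(fasta, gc_window = c(0.2, 0.8),
                          tm_window = c(60, 90), homopolymer_max = 5,
                          kmer_k = 18, kmer_max_count = 1) {
  if (gc_window[1] > gc_window[2] || tm_window[1] > tm_window[2]) {
    stop("oligoband_error_params: inverted filter window bounds",
         call. = FALSE)
  }
  seqs <- read_sequences(fasta)
  if (!length(seqs) || all(nchar(seqs) == 0L)) {
    stop("oligoband_error_io: empty FASTA input", call. = FALSE)
  }
  W <- 39L
  # genome-wide k-mer counts over unmasked sequence
  all_kmers <- unlist(lapply(seqs, function(s) {
    su <- toupper(s)
    L <- nchar(su)
    if (L < kmer_k) return(character(0))
    substring(su, 1:(L - kmer_k + 1L), kmer_k:L)
  }), use.names = FALSE)
  kc <- table(all_kmers)

  out <- lapply(names(seqs), function(ch) {
    s <- seqs[[ch]]
    L <- nchar(s)
    if (L < W) return(NULL)
    bases <- strsplit(s, "")[[1L]]
    up <- toupper(bases)
    masked <- bases %in% c("a", "c", "g", "t", "N", "n") |
      !up %in% c("A", "C", "G", "T")
    gc <- up %in% c("G", "C")
    cm <- c(0, cumsum(masked))
    cg <- c(0, cumsum(gc))
    # dinucleotide dH/dS cumulative sums for windowed Tm
    di <- paste0(up[-L], up[-1L])
    dh <- .nn_dh[di]; ds <- .nn_ds[di]
    dh[is.na(dh)] <- 0; ds[is.na(ds)] <- 0
    ch_cum <- c(0, cumsum(dh)); cs_cum <- c(0, cumsum(ds))
    # positions where a run of homopolymer_max+1 identical bases starts
    runlen <- homopolymer_max + 1L
    if (L >= runlen) {
      same <- up[-L] == up[-1L]
      csame <- c(0, cumsum(same))
      runstart <- (csame[(runlen):L] - csame[1:(L - runlen + 1L)]) ==
        (runlen - 1L)
    } else runstart <- logical(0)
    crun <- c(0, cumsum(runstart))
    # per-position k-mer over-count flag
    nk <- L - kmer_k + 1L
    kbad <- if (nk >= 1L) {
      km <- substring(toupper(s), 1:nk, kmer_k:L)
      as.integer(kc[km]) > kmer_max_count
    } else logical(0)
    ckb <- c(0, cumsum(kbad))

    i <- 1:(L - W + 1L)
    ok <- (cm[i + W] - cm[i]) == 0                       # no masked base
    gcw <- (cg[i + W] - cg[i]) / W
    ok <- ok & gcw >= gc_window[1] & gcw <= gc_window[2]
    dhw <- ch_cum[i + W - 1L] - ch_cum[i]                # 38 stacks
    dsw <- cs_cum[i + W - 1L] - cs_cum[i]
    tm <- (dhw + 0.2) * 1000 / ((dsw - 5.7) + 1.987 * log(50e-9 / 4)) -
      273.15 + 16.6 * log10(0.39)
    ok <- ok & tm >= tm_window[1] & tm <= tm_window[2]
    hi <- pmin(i + W - runlen, length(runstart))
    nrun <- ifelse(hi >= i, crun[hi + 1L] - crun[i], 0)
    ok <- ok & nrun == 0                                  # no homopolymer
    khi <- pmin(i + W - kmer_k, length(kbad))
    nbad <- ifelse(khi >= i, ckb[khi + 1L] - ckb[i], 0)
    ok <- ok & nbad == 0                                  # k-mer uniqueness
    keep <- i[ok]
    if (!length(keep)) return(NULL)
    data.table::data.table(chrom = ch, start = keep - 1L,
                           end = keep - 1L + W,
                           sequence = substring(toupper(s), keep,
                                                keep + W - 1L))
  })
  res <- data.table::rbindlist(out)
  if (!nrow(res)) {
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), sequence = character(0)))
  }
  res[]
}

read_sequences <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("oligoband_error_io: Biostrings is required to read FASTA files; ",
           "alternatively pass a named character vector of sequences",
           call. = FALSE)
    }
    ss <- Biostrings::readDNAStringSet(fasta)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (is.character(fasta) && !is.null(names(fasta))) return(fasta)
  stop("oligoband_error_io: fasta must be a file path or a named character ",
       "vector of sequences", call. = FALSE)
}

has_gc_clamp <- function(seq) {
  n <- nchar(seq)
  all(strsplit(substring(seq, n - 1L, n), "")[[1L]] %in% c("G", "C"))
}

#' Select a mutually compatible orthogonal 20mer set
#'
#' Retains a subset of candidate 20mers in which every member's
#' self-dimerization and every pairwise hetero-dimerization free energy is
#' at or above `dg_threshold` (default -9 kcal/mol), then attributes roles:
#' sequences with a 3'-terminal G/C dinucleotide (GC clamp) are preferred as
#' forward and chromosome-specific reverse primers; the remainder become
#' fluorophore handles. Selection is greedy in input order by default; an
#' exact maximum-compatible-subset search is available for candidate sets of
#' at most 30. An optional genome screen drops any candidate sharing a
#' 15-mer (either strand) with the genome.
#'
#' @param candidates character vector of 20mers.
#' @param reverse_chroms chromosome ids needing a reverse primer each.
#' @param n_forward number of forward primers, default 1.
#' @param handle_fluors fluorophores needing a handle, default all three.
#' @param dg_threshold dimer dG threshold (kcal/mol), default -9.
#' @param genome optional named character vector of genome sequences for the
#'   orthogonality screen.
#' @param screen_k k-mer length of the genome screen, default 15.
#' @param method `"greedy"` or `"exact"` (exact only for <= 30 candidates).
#' @return An `orthogonal_set`: list with `forward`, `reverse` (named by
#'   chromosome), `handles` (named by fluorophore), `detection` (reverse
#'   complements of the handles, named by fluorophore), `dg_threshold`,
#'   `retained` (all compatible sequences).
#' @export
select_orthogonal_set <- function(candidates, reverse_chroms,
                                  n_forward = 1,
                                  handle_fluors = fluorophores(),
                                  dg_threshold = -9, genome = NULL,
                                  screen_k = 15,
                                  method = c("greedy", "exact")) {
  method <- match.arg(method)
  candidates <- toupper(candidates)
  if (any(nchar(candidates) != 20L)) {
    stop("oligoband_error_orthogonal: all candidates must be 20mers",
         call. = FALSE)
  }
  if (!is.null(genome)) {
    gk <- unique(unlist(lapply(genome, function(s) {
      su <- toupper(s); L <- nchar(su)
      if (L < screen_k) return(character(0))
      substring(su, 1:(L - screen_k + 1L), screen_k:L)
    }), use.names = FALSE))
    hits <- vapply(candidates, function(cs) {
      kms <- substring(cs, 1:(20 - screen_k + 1L), screen_k:20)
      kmr <- substring(revcomp(cs), 1:(20 - screen_k + 1L), screen_k:20)
      any(c(kms, kmr) %in% gk)
    }, logical(1))
    candidates <- candidates[!hits]
  }
  ok_self <- vapply(candidates,
                    function(cs) dimer_free_energy(cs, cs) >= dg_threshold,
                    logical(1))
  candidates <- candidates[ok_self]

  retained <- if (method == "exact") {
    if (length(candidates) > 30L) {
      stop("oligoband_error_orthogonal: exact search limited to 30 ",
           "candidates, got ", length(candidates), call. = FALSE)
    }
    exact_compatible(candidates, dg_threshold)
  } else {
    kept <- character(0)
    for (cs in candidates) {
      if (all(vapply(kept,
                     function(k) dimer_free_energy(cs, k) >= dg_threshold,
                     logical(1)))) {
        kept <- c(kept, cs)
      }
    }
    kept
  }

  n_rev <- length(reverse_chroms)
  n_handles <- length(handle_fluors)
  need <- n_forward + n_rev + n_handles
  if (length(retained) < need) {
    stop("oligoband_error_orthogonal: need ", need,
         " compatible sequences, achieved ", length(retained),
         call. = FALSE)
  }
  clamp <- vapply(retained, has_gc_clamp, logical(1))
  ordered <- c(retained[clamp], retained[!clamp])  # primers drawn first
  forward <- ordered[seq_len(n_forward)]
  reverse <- ordered[n_forward + seq_len(n_rev)]
  names(reverse) <- reverse_chroms
  # handles preferentially from the non-clamp pool
  rest <- setdiff(retained, c(forward, reverse))
  rest <- c(rest[!vapply(rest, has_gc_clamp, logical(1))],
            rest[vapply(rest, has_gc_clamp, logical(1))])
  handles <- rest[seq_len(n_handles)]
  names(handles) <- handle_fluors
  detection <- vapply(handles, revcomp, character(1))
  structure(list(forward = unname(forward), reverse = reverse,
                 handles = handles, detection = detection,
                 dg_threshold = dg_threshold, retained = retained),
            class = "orthogonal_set")
}

# exact maximum compatible subset by recursive branch and bound
exact_compatible <- function(cands, thr) {
  n <- length(cands)
  if (n == 0L) return(character(0))
  comp <- matrix(TRUE, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- dimer_free_energy(cands[i], cands[j]) >= thr
      comp[i, j] <- ok; comp[j, i] <- ok
    }
  }
  best <- integer(0)
  rec <- function(chosen, pool) {
    if (length(chosen) + length(pool) <= length(best)) return()
    if (!length(pool)) {
      if (length(chosen) > length(best)) best <<- chosen
      return()
    }
    p <- pool[1L]
    rec(c(chosen, p), pool[-1L][comp[p, pool[-1L]]])
    rec(chosen, pool[-1L])
  }
  rec(integer(0), seq_len(n))
  cands[best]
}

#' Oligo layouts
#'
#' An oligo is assembled from ordered segments. Two layouts ship: the
#' four-segment layout (reverse-primer binding 20 nt + genome-homologous
#' 39 nt + forward-primer binding 20 nt + detection handle 20 nt, 99 nt
#' total) and the default three-segment 79 nt layout (reverse binding +
#' homology + detection handle; the forward-binding segment is dropped so
#' the total matches the 79 nt synthesis length). [validate_layout()]
#' compares the declared total with the segment sum and reports any
#' mismatch rather than silently fixing it.
#'
#' @param name layout name.
#' @param roles character vector of segment roles in order, from
#'   `reverse_binding`, `homology`, `forward_binding`, `detection_handle`.
#' @param lengths integer segment lengths (homology must be 39).
#' @param declared_total_nt declared synthesis length.
#' @return An `oligo_layout` list.
#' @export
oligo_layout <- function(name, roles, lengths, declared_total_nt) {
  stopifnot(length(roles) == length(lengths))
  structure(list(name = name,
                 segments = data.frame(role = roles, length_nt = lengths,
                                       stringsAsFactors = FALSE),
                 declared_total_nt = declared_total_nt),
            class = "oligo_layout")
}

#' @rdname oligo_layout
#' @param which `"79nt"` (default) or `"fig_layout"` for the four-segment
#'   variant.
#' @export
default_layout <- function(which = c("79nt", "four_segment")) {
  which <- match.arg(which)
  if (which == "79nt") {
    oligo_layout("79nt",
                 c("reverse_binding", "homology", "detection_handle"),
                 c(20L, 39L, 20L), 79L)
  } else {
    oligo_layout("four_segment",
                 c("reverse_binding", "homology", "forward_binding",
                   "detection_handle"),
                 c(20L, 39L, 20L, 20L), 99L)
  }
}

#' @rdname oligo_layout
#' @param layout an `oligo_layout`.
#' @export
validate_layout <- function(layout) {
  msgs <- character(0)
  hom <- layout$segments$length_nt[layout$segments$role == "homology"]
  if (length(hom) != 1L || hom != 39L) {
    msgs <- c(msgs, "homology segment must be present once with length 39")
  }
  total <- sum(layout$segments$length_nt)
  if (total != layout$declared_total_nt) {
    msgs <- c(msgs, sprintf(
      "segment lengths sum to %d but declared total is %d",
      total, layout$declared_total_nt))
  }
  list(ok = length(msgs) == 0L, messages = msgs,
       segment_sum = total, declared = layout$declared_total_nt)
}

#' Assemble one synthesis-ready oligo
#'
#' Concatenates, in layout order: the reverse complement of the chromosome's
#' reverse primer (reverse-binding segment), the genome-homologous 39mer,
#' optionally the reverse complement of the forward primer, and the handle
#' sequence of the probe's fluorophore (to which the dye-labelled detection
#' oligo hybridizes).
#'
#' @param sequence39 the 39 nt genome-homologous sequence.
#' @param layout an [oligo_layout()].
#' @param set an [select_orthogonal_set()] result.
#' @param chrom chromosome id (selects the reverse primer).
#' @param fluor fluorophore (selects the handle).
#' @return List with `final` (the full sequence) and `segments` (named by
#'   role).
#' @export
assemble_oligo <- function(sequence39, layout, set, chrom, fluor) {
  sequence39 <- toupper(sequence39)
  .check_acgt(sequence39, "39mer")
  if (nchar(sequence39) != 39L) {
    stop("oligoband_error_assembly: homology sequence must be 39 nt, got ",
         nchar(sequence39), call. = FALSE)
  }
  if (!chrom %in% names(set$reverse)) {
    stop("oligoband_error_assembly: no reverse primer for chromosome ",
         chrom, call. = FALSE)
  }
  if (!fluor %in% names(set$handles)) {
    stop("oligoband_error_assembly: no handle for fluorophore ", fluor,
         call. = FALSE)
  }
  segs <- character(nrow(layout$segments))
  names(segs) <- layout$segments$role
  for (i in seq_len(nrow(layout$segments))) {
    role <- layout$segments$role[i]
    seg <- switch(role,
      reverse_binding = revcomp(set$reverse[[chrom]]),
      homology = sequence39,
      forward_binding = revcomp(set$forward[1L]),
      detection_handle = unname(set$handles[[fluor]]),
      stop("oligoband_error_assembly: unknown segment role ", role,
           call. = FALSE))
    if (nchar(seg) != layout$segments$length_nt[i]) {
      stop("oligoband_error_assembly: segment '", role, "' has length ",
           nchar(seg), ", layout declares ", layout$segments$length_nt[i],
           call. = FALSE)
    }
    segs[i] <- seg
  }
  list(final = paste(segs, collapse = ""), segments = segs)
}

#' Recover the internal 39mer by simulated priming
#'
#' Checks that the assembled sequence begins with the reverse-binding
#' segment of its chromosome's primer and extracts the homology segment at
#' the layout offset.
#'
#' @inheritParams assemble_oligo
#' @param final assembled sequence.
#' @return The recovered 39 nt string (errors if priming fails).
#' @export
simulated_priming <- function(final, layout, set, chrom) {
  off <- 0L
  for (i in seq_len(nrow(layout$segments))) {
    role <- layout$segments$role[i]
    len <- layout$segments$length_nt[i]
    seg <- substring(final, off + 1L, off + len)
    if (role == "reverse_binding" &&
        seg != revcomp(set$reverse[[chrom]])) {
      stop("oligoband_error_assembly: reverse primer does not prime this ",
           "oligo", call. = FALSE)
    }
    if (role == "homology") return(seg)
    off <- off + len
  }
  stop("oligoband_error_assembly: layout has no homology segment",
       call. = FALSE)
}

#' Assemble all oligos of a coloured panel
#'
#' For each probe, takes its oligos from the candidate table (trimmed window
#' for single-colour probes; full window with alternating fluorophores for
#' paired colours, odd indices to the first fluorophore of the token) and
#' assembles final sequences.
#'
#' @param panel a coloured `probe_panel` (after [apply_scheme_to_panel()]).
#' @param candidates candidate table with sequences.
#' @param layout an [oligo_layout()].
#' @param set an `orthogonal_set`.
#' @return data.table: `chrom`, `probe_id`, `colour`, `fluor`, `start`,
#'   `end`, `sequence39`, `final_sequence`.
#' @export
assemble_panel_oligos <- function(panel, candidates, layout, set) {
  cand <- data.table::as.data.table(candidates)
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    p <- panel[i, ]
    cc <- cand[cand$chrom == p$chrom]
    win <- p$idx_first + 0:(p$n_oligo - 1L)
    if (anyNA(cc$sequence[win])) {
      stop("oligoband_error_assembly: candidates lack sequences for probe ",
           p$probe_id, call. = FALSE)
    }
    fl <- token_fluors(p$colour)
    fluor <- if (length(fl) == 2L) {
      alt <- assign_pair_alternation(p$n_oligo, p$colour, strict = FALSE)
      f <- character(p$n_oligo)
      f[alt[[1L]]] <- names(alt)[1L]
      f[alt[[2L]]] <- names(alt)[2L]
      f
    } else rep(fl, p$n_oligo)
    fin <- vapply(seq_along(win), function(k) {
      assemble_oligo(cc$sequence[win[k]], layout, set, p$chrom,
                     fluor[k])$final
    }, character(1))
    data.table::data.table(chrom = p$chrom, probe_id = p$probe_id,
                           colour = p$colour, fluor = fluor,
                           start = cc$start[win], end = cc$end[win],
                           sequence39 = toupper(cc$sequence[win]),
                           final_sequence = fin)
  })
  data.table::rbindlist(rows)
}

T7_PROMOTER <- "TAATACGACTCACTATAG"

#' Write synthesis order sheets
#'
#' Emits a per-library TSV (chrom, probe, colour, fluorophore, 39mer,
#' genomic position, final sequence) plus a primers/detection-oligo TSV in
#' which reverse primers carry the T7 promoter prefix at export and
#' detection oligos carry their 3' dye annotation.
#'
#' @param oligos output of [assemble_panel_oligos()].
#' @param set an `orthogonal_set`.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
emit_order_sheets <- function(oligos, set, outdir) {
  if (!nrow(oligos)) {
    stop("oligoband_error_io: no oligos to emit", call. = FALSE)
  }
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok) {
    stop("oligoband_error_io: cannot create output directory ", outdir,
         call. = FALSE)
  }
  lib_path <- file.path(outdir, "oligo_library.tsv")
  data.table::fwrite(oligos, lib_path, sep = "\t")
  pr <- data.table::rbindlist(list(
    data.table::data.table(type = "forward", name = "forward_primer",
                           sequence = set$forward, dye = NA_character_),
    data.table::data.table(type = "reverse",
                           name = paste0("reverse_", names(set$reverse)),
                           sequence = paste0(T7_PROMOTER, set$reverse),
                           dye = NA_character_),
    data.table::data.table(type = "handle",
                           name = paste0("handle_", names(set$handles)),
                           sequence = unname(set$handles),
                           dye = NA_character_),
    data.table::data.table(type = "detection",
                           name = paste0("detect_", names(set$detection)),
                           sequence = unname(set$detection),
                           dye = names(set$detection))
  ))
  pr_path <- file.path(outdir, "primers_detection.tsv")
  data.table::fwrite(pr, pr_path, sep = "\t")
  invisible(c(library = lib_path, primers = pr_path))
}

#' @rdname emit_order_sheets
#' @param path a library TSV written by `emit_order_sheets`.
#' @export
read_order_sheet <- function(path) {
  data.table::fread(path, sep = "\t")
}
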