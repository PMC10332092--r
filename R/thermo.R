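# Nearest-neighbor DNA thermodynamics (unified dinucleotide parameters,
# 1 M NaCl, 37 C). Values are the widely used unified NN set; dG37 in
# kcal/mol, dH in kcal/mol, dS in cal/(mol K). Keys are the 5'->3' top
# strand dinucleotide of a Watson-Crick stack; the table is complete under
# the reverse-complement symmetry dG(XY) = dG(rc(XY)).

.nn_dg37 <- c(
  AA = -1.00, AC = -1.44, AG = -1.28, AT = -0.88,
  CA = -1.45, CC = -1.84, CG = -2.17, CT = -1.28,
  GA = -1.30, GC = -2.24, GG = -1.84, GT = -1.44,
  TA = -0.58, TC = -1.30, TG = -1.45, TT = -1.00)

.nn_dh <- c(
  AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
  CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
  GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
  TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)

.nn_ds <- c(
  AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
  CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
  GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
  TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)

.nn_init_dg <- 1.96  # duplex initiation, kcal/mol

.check_acgt <- function(x, what = "sequence") {
  if (grepl("[^ACGT]", x)) {
    stop("oligoband_error_sequence: non-ACGT character in ", what, ": ", x,
         call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param x string over A,C,G,T.
#' @return Reverse complement string.
#' @export
revcomp <- function(x) {
  .check_acgt(toupper(x))
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(toupper(x), "")[[1L]]), collapse = ""))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Nearest-neighbor melting temperature estimate
#'
#' Tm = dH / (dS + R ln(C/4)) - 273.15, unified NN parameters, with a
#' simple monovalent-salt correction `16.6 log10([Na+])`. Intended as a
#' relative filter criterion for 39mer selection, not an absolute
#' prediction.
#'
#' @param seq DNA string.
#' @param conc_m total strand concentration (mol/L), default 50e-9.
#' @param na_m monovalent cation concentration (mol/L), default 0.39
#'   (2x SSC hybridization conditions).
#' @return Tm in degrees Celsius.
#' @export
tm_nn <- function(seq, conc_m = 50e-9, na_m = 0.39) {
  seq <- toupper(seq)
  .check_acgt(seq)
  n <- nchar(seq)
  if (n < 2L) stop("oligoband_error_sequence: need length >= 2",
                   call. = FALSE)
  di <- substring(seq, 1:(n - 1L), 2:n)
  dh <- sum(.nn_dh[di]) + 0.2       # initiation dH
  ds <- sum(.nn_ds[di]) - 5.7       # initiation dS
  tm <- dh * 1000 / (ds + 1.987 * log(conc_m / 4)) - 273.15
  tm + 16.6 * log10(na_m)
}

#' Minimum dimerization free energy of two oligos
#'
#' Slides the two strands against each other over every ungapped antiparallel
#' offset, marks Watson-Crick complementary positions, and scores each
#' alignment as the duplex-initiation penalty plus the sum of unified
#' nearest-neighbor stacking terms over adjacent complementary pairs
#' (37 C, kcal/mol). Returns the minimum (most negative) over all offsets;
#' 0 when no offset produces a stacked duplex. Self-dimerization is
#' `dimer_free_energy(a, a)`; the function is symmetric in its arguments.
#'
#' @param a,b DNA strings over A,C,G,T, length >= 2.
#' @return dG in kcal/mol (<= 0; more negative = stronger dimer).
#' @export
#' @examples
#' dimer_free_energy(strrep("A", 20), strrep("A", 20))  # 0, no A.A pairing
dimer_free_energy <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  .check_acgt(a); .check_acgt(b)
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  if (length(av) < 2L || length(bv) < 2L) {
    stop("oligoband_error_sequence: need length >= 2", call. = FALSE)
  }
  # antiparallel: align a (5'->3') against reversed b; position i of a
  # pairs with reversed-b position i - off
  br <- rev(bv)
  n <- length(av); m <- length(br)
  best <- 0
  for (off in (-(m - 1L)):(n - 1L)) {
    i0 <- max(1L, 1L + off)
    i1 <- min(n, m + off)
    if (i1 - i0 < 1L) next
    i <- i0:i1
    paired <- av[i] == comp_base(br[i - off])
    if (sum(paired) < 2L) next
    # stacks: consecutive paired positions
    st <- which(paired[-length(paired)] & paired[-1L])
    if (!length(st)) next
    di <- paste0(av[i[st]], av[i[st] + 1L])
    dg <- .nn_init_dg + sum(.nn_dg37[di])
    if (dg < best) best <- dg
  }
  best
}
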