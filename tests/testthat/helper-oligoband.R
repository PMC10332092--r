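# shared fixtures and independent oracles

# memoization-free recursive edit distance (exponential; keep lengths small)
lev_recursive <- function(a, b) {
  if (length(a) == 0L) return(length(b))
  if (length(b) == 0L) return(length(a))
  sub <- lev_recursive(a[-length(a)], b[-length(b)]) +
    (a[length(a)] != b[length(b)])
  del <- lev_recursive(a[-length(a)], b) + 1L
  ins <- lev_recursive(a, b[-length(b)]) + 1L
  min(sub, del, ins)
}

# independent C-level oracle: map tokens to single letters, use utils::adist
lev_adist <- function(a, b) {
  alph <- unique(c(colour_tokens(), a, b))
  enc <- function(x) paste(letters[match(x, alph)], collapse = "")
  as.integer(utils::adist(enc(a), enc(b)))
}

random_tokens <- function(n) sample(colour_tokens(), n, replace = TRUE)

# tiny deterministic scheme over 5 chromosomes for matching tests
toy_scheme <- function() {
  structure(list(patterns = list(
    C1 = c("FAM", "A550", "A647", "FAM+A550", "A647"),
    C2 = c("A550", "A550", "FAM"),
    C3 = c("A647", "FAM", "FAM+A647", "A550"),
    C4 = c("FAM+A550", "A647", "A550", "FAM", "A550", "A647"),
    C5 = c("A550+A647", "FAM")
  ), seed = NA, score = NULL), class = "scheme")
}

toy_genome <- function() {
  genome_build(paste0("C", 1:5),
               c(120e6, 80e6, 100e6, 140e6, 60e6), name = "toy")
}

# evenly spaced coloured panel matching toy_scheme pattern lengths
toy_panel <- function(scheme = toy_scheme(), genome = toy_genome(),
                      coverage = 4.5e5, margin = 6e6) {
  rows <- lapply(names(scheme$patterns), function(ch) {
    pat <- scheme$patterns[[ch]]
    L <- genome$length_bp[genome$chrom == ch]
    np <- length(pat)
    mids <- seq(margin + coverage / 2, L - margin - coverage / 2,
                length.out = np)
    data.table::data.table(
      probe_id = sprintf("%s_p%d", ch, seq_len(np)), chrom = ch,
      start = round(mids - coverage / 2), end = round(mids + coverage / 2),
      n_oligo = 3000L, colour = pat, rank = seq_len(np),
      idx_first = NA_integer_)
  })
  panel <- data.table::rbindlist(rows)
  panel$density_oligo_per_kb <-
    panel$n_oligo / ((panel$end - panel$start) / 1000)
  data.table::setattr(panel, "genome", genome)
  data.table::setattr(panel, "class", c("probe_panel", class(panel)))
  panel[]
}

find_der <- function(kar, ch) {
  which(vapply(kar$copies, function(cp) {
    cp$chrom == ch && cp$derivative
  }, logical(1)))[1]
}

# noise-light config for deterministic round trips
quiet_config <- function(...) {
  sim_config(snr = 1000, background_sd = 1, flip_prob = 0, ...)
}
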