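test_that("filter_39mers rejects repeats, keeps forced islands", {
  # degenerate repeat fails the k-mer uniqueness screen
  rep_seq <- c(chrR = strrep("ACGT", 25))
  expect_equal(nrow(filter_39mers(rep_seq)), 0L)

  # one unmasked 39-mer island flanked by soft-masked bases
  set.seed(3)
  island <- paste(sample(c("A", "C", "G", "T"), 39, TRUE), collapse = "")
  seqs <- c(chrI = paste0(tolower(strrep("ACGT", 10)), island,
                          tolower(strrep("TGCA", 10))))
  hits <- filter_39mers(seqs, tm_window = c(0, 200), gc_window = c(0, 1))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$sequence, island)
  expect_equal(hits$start, 40L)

  expect_error(filter_39mers(c(x = "")), "empty")
  expect_error(filter_39mers(seqs, gc_window = c(0.8, 0.2)), "inverted")
})

test_that("filter_39mers equals a brute-force predicate scan", {
  set.seed(12)
  g <- c(A = paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = ""),
         B = paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""))
  got <- filter_39mers(g, gc_window = c(0.3, 0.7), tm_window = c(65, 85),
                       homopolymer_max = 4, kmer_k = 12, kmer_max_count = 1)
  # oracle: plain per-window predicate evaluation
  all_k <- unlist(lapply(g, function(s) {
    substring(s, 1:(nchar(s) - 11), 12:nchar(s))
  }), use.names = FALSE)
  kc <- table(all_k)
  oracle <- list()
  for (ch in names(g)) {
    s <- g[[ch]]
    for (i in 1:(nchar(s) - 38)) {
      w <- substring(s, i, i + 38)
      gc <- sum(strsplit(w, "")[[1]] %in% c("G", "C")) / 39
      if (gc < 0.3 || gc > 0.7) next
      tm <- tm_nn(w)
      if (tm < 65 || tm > 85) next
      if (max(rle(strsplit(w, "")[[1]])$lengths) > 4) next
      kms <- substring(w, 1:28, 12:39)
      if (any(as.integer(kc[kms]) > 1)) next
      oracle[[length(oracle) + 1]] <- data.frame(chrom = ch, start = i - 1)
    }
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$start, oracle$start)
  expect_equal(got$chrom, oracle$chrom)

  # invariance to chromosome processing order
  got2 <- filter_39mers(g[c("B", "A")], gc_window = c(0.3, 0.7),
                        tm_window = c(65, 85), homopolymer_max = 4,
                        kmer_k = 12, kmer_max_count = 1)
  expect_equal(data.table::setorder(data.table::copy(got), chrom, start),
               data.table::setorder(got2, chrom, start))
})

test_that("dimer_free_energy: no pairing, perfect duplex, symmetry", {
  polyA <- strrep("A", 20)
  expect_equal(dimer_free_energy(polyA, polyA), 0)

  s <- "ATGCGTACGTTAGCCATGGA"
  dg <- dimer_free_energy(s, revcomp(s))
  # hand computation: initiation + all 19 stacks of s
  tab <- c(AA = -1.00, AC = -1.44, AG = -1.28, AT = -0.88, CA = -1.45,
           CC = -1.84, CG = -2.17, CT = -1.28, GA = -1.30, GC = -2.24,
           GG = -1.84, GT = -1.44, TA = -0.58, TC = -1.30, TG = -1.45,
           TT = -1.00)
  expected <- 1.96 + sum(tab[substring(s, 1:19, 2:20)])
  expect_equal(dg, expected)
  expect_lt(dg, -9)

  expect_error(dimer_free_energy("ACGN", "ACGT"), "non-ACGT")

  set.seed(31)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    expect_equal(dimer_free_energy(a, b), dimer_free_energy(b, a))
  }
})

test_that("dimer_free_energy equals an exhaustive offset oracle", {
  # independent oracle: direct enumeration over every pairing register
  oracle <- function(a, b) {
    tab <- c(AA = -1.00, AC = -1.44, AG = -1.28, AT = -0.88, CA = -1.45,
             CC = -1.84, CG = -2.17, CT = -1.28, GA = -1.30, GC = -2.24,
             GG = -1.84, GT = -1.44, TA = -0.58, TC = -1.30, TG = -1.45,
             TT = -1.00)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    av <- strsplit(a, "")[[1]]
    bv <- rev(strsplit(b, "")[[1]])
    best <- 0
    for (off in (-(length(bv) - 1)):(length(av) - 1)) {
      pairs <- logical(length(av))
      for (i in seq_along(av)) {
        j <- i - off
        if (j >= 1 && j <= length(bv)) {
          pairs[i] <- comp[[bv[j]]] == av[i]
        }
      }
      dg <- NA
      for (i in seq_len(length(av) - 1)) {
        if (pairs[i] && pairs[i + 1]) {
          st <- tab[[paste0(av[i], av[i + 1])]]
          dg <- if (is.na(dg)) 1.96 + st else dg + st
        }
      }
      if (!is.na(dg) && dg < best) best <- dg
    }
    best
  }
  set.seed(17)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1), TRUE),
               collapse = "")
    expect_equal(dimer_free_energy(a, b), oracle(a, b))
  }
})

test_that("select_orthogonal_set retains only compatible sequences", {
  # three mutually non-complementary 20mers are all retained
  trio <- c(strrep("AC", 10), strrep("CA", 10), strrep("CCCCA", 4))
  expect_true(all(outer(trio, trio, Vectorize(dimer_free_energy)) >= -9))
  set <- select_orthogonal_set(trio, reverse_chroms = "T1", n_forward = 1,
                               handle_fluors = "FAM")
  expect_setequal(set$retained, trio)

  # a reverse-complement pair cannot co-exist
  a <- "ATGCGTACGTTAGCCATGGA"
  cands <- c(a, revcomp(a), trio)
  set2 <- select_orthogonal_set(cands, reverse_chroms = "T1",
                                n_forward = 1, handle_fluors = "FAM")
  expect_lte(sum(c(a, revcomp(a)) %in% set2$retained), 1L)

  expect_error(select_orthogonal_set(trio[1:2], reverse_chroms = c("T1", "T2"),
                                     n_forward = 1),
               "achieved")
})

test_that("retained pairs all pass the threshold (exhaustive check)", {
  set.seed(23)
  cands <- vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  }, character(1))
  set <- select_orthogonal_set(cands, reverse_chroms = paste0("T", 1:3))
  kept <- set$retained
  for (i in seq_along(kept)) {
    for (j in i:length(kept)) {
      expect_gte(dimer_free_energy(kept[i], kept[j]), -9)
    }
  }
  # genome screen drops a candidate embedded in the genome
  g <- c(chr = paste0(strrep("T", 30), cands[1], strrep("G", 30)))
  set3 <- select_orthogonal_set(cands, reverse_chroms = "T1", genome = g)
  expect_false(cands[1] %in% set3$retained)
})

test_that("exact compatible-set search is at least as large as greedy", {
  set.seed(29)
  cands <- vapply(1:14, function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  }, character(1))
  greedy <- select_orthogonal_set(cands, reverse_chroms = character(0),
                                  n_forward = 1, handle_fluors = "FAM")
  exact <- select_orthogonal_set(cands, reverse_chroms = character(0),
                                 n_forward = 1, handle_fluors = "FAM",
                                 method = "exact")
  expect_gte(length(exact$retained), length(greedy$retained))
})

test_that("layouts validate and assembly embeds the 39mer at its offset", {
  l79 <- default_layout("79nt")
  v <- validate_layout(l79)
  expect_true(v$ok)
  l4 <- default_layout("four_segment")
  expect_true(validate_layout(l4)$ok)
  expect_equal(validate_layout(l4)$segment_sum, 99L)
  # a mis-declared total is reported, not fixed
  bad <- oligo_layout("bad", l4$segments$role, l4$segments$length_nt, 79L)
  vb <- validate_layout(bad)
  expect_false(vb$ok)
  expect_match(vb$messages, "sum to 99")

  set.seed(37)
  cands <- vapply(1:60, function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  }, character(1))
  set <- select_orthogonal_set(cands, reverse_chroms = c("T1", "T2"))
  mer <- paste(sample(c("A", "C", "G", "T"), 39, TRUE), collapse = "")

  a79 <- assemble_oligo(mer, l79, set, "T1", "FAM")
  expect_equal(nchar(a79$final), 79L)
  expect_equal(substring(a79$final, 21, 59), mer)
  expect_equal(paste(a79$segments, collapse = ""), a79$final)

  a99 <- assemble_oligo(mer, l4, set, "T2", "A647")
  expect_equal(nchar(a99$final), 99L)
  expect_equal(substring(a99$final, 21, 59), mer)
  expect_equal(substring(a99$final, 1, 20), revcomp(set$reverse[["T2"]]))
  expect_equal(substring(a99$final, 80, 99), unname(set$handles[["A647"]]))

  expect_equal(simulated_priming(a79$final, l79, set, "T1"), mer)
  expect_error(simulated_priming(a79$final, l79, set, "T2"), "prime")
})

test_that("panel assembly and order sheets round-trip", {
  set.seed(41)
  genome <- genome_build("T1", 50e6)
  cand <- simulate_candidates(genome, sim_config(candidate_rate = 1 / 5000),
                              seed = 9, with_sequence = TRUE)
  # tiny panel: two probes of 10 oligos each
  panel <- data.table::data.table(
    probe_id = c("T1_p1", "T1_p2"), chrom = "T1",
    start = cand$start[c(100, 400)], end = cand$end[c(109, 409)],
    n_oligo = 10L, colour = c("FAM", "A550+A647"),
    density_oligo_per_kb = 1, rank = 1:2, idx_first = c(100L, 400L))
  set <- select_orthogonal_set(
    vapply(1:60, function(i) paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                                   collapse = ""), character(1)),
    reverse_chroms = "T1")
  oligos <- assemble_panel_oligos(panel, cand, default_layout("79nt"), set)
  expect_equal(nrow(oligos), 20L)
  expect_true(all(substring(oligos$final_sequence, 21, 59) ==
                    oligos$sequence39))
  # paired probe alternates its two fluorophores
  fl2 <- oligos$fluor[oligos$probe_id == "T1_p2"]
  expect_equal(fl2, rep(c("A550", "A647"), 5))

  out <- file.path(tempdir(), "orders")
  paths <- emit_order_sheets(oligos, set, out)
  lib <- read_order_sheet(paths[["library"]])
  expect_equal(nrow(lib), nrow(oligos))
  expect_identical(lib$final_sequence, oligos$final_sequence)
  pr <- data.table::fread(paths[["primers"]])
  rev_rows <- pr[pr$type == "reverse"]
  expect_true(all(startsWith(rev_rows$sequence, "TAATACGACTCACTATAG")))
  expect_equal(sum(pr$type == "detection"), 3L)
})
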