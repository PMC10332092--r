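test_that("load_candidates parses, sorts, validates and deduplicates", {
  genome <- genome_build("T1", 10e6)
  bed <- tempfile(fileext = ".bed")
  writeLines(c("T1\t5000\t5039", "T1\t100\t139", "T1\t2000\t2039"), bed)
  cand <- load_candidates(bed, genome)
  expect_equal(nrow(cand), 3L)
  expect_equal(cand$start, c(100, 2000, 5000))

  writeLines(c("T1\t9999999\t10000038"), bed)
  expect_error(load_candidates(bed, genome), "coordinate outside")
  writeLines(c("T9\t0\t39"), bed)
  expect_error(load_candidates(bed, genome), "unknown chromosome")

  # 50,000-record synthetic file: count preserved, order = independent sort
  set.seed(4)
  starts <- sample.int(9e6, 5e4)
  tsv <- tempfile(fileext = ".tsv")
  data.table::fwrite(data.frame(chrom = "T1", start = starts,
                                end = starts + 39), tsv, sep = "\t")
  cand <- load_candidates(tsv, genome)
  expect_equal(nrow(cand), length(unique(starts)))
  expect_equal(cand$start, sort(unique(starts)))
})

test_that("select_probe_windows honours spacing/termini and snaps dense", {
  # uniform candidates every 150 bp over 100 Mb
  starts <- seq(0, 100e6 - 39, by = 150)
  ends <- starts + 39
  idx <- select_probe_windows(starts, ends, 100e6, n_probes = 3,
                              n_oligo = 3000, min_resolvable_bp = 8e6,
                              termini_margin_bp = 6e6)
  expect_length(idx, 3L)
  ws <- starts[idx]; we <- ends[idx + 2999L]
  expect_true(all(we - ws == 2999 * 150 + 39))  # ~450 kb spans
  expect_true(all(ws >= 6e6) && all(we <= 100e6 - 6e6))
  expect_true(all(ws[-1L] - we[-3L] >= 8e6))

  expect_length(select_probe_windows(starts, ends, 100e6, 0), 0L)
  expect_error(select_probe_windows(starts[1:100], ends[1:100], 100e6, 1),
               "infeasible")
  expect_error(select_probe_windows(starts, ends, 25e6, 3),
               "infeasible")
})

test_that("window snaps to a dense cluster when constraints allow", {
  # 10,000 candidates: sparse background + one dense cluster at 40-41 Mb
  set.seed(11)
  bg <- sort(sample(seq(6e6, 94e6), 7000))
  cl <- sort(sample(seq(40e6, 41e6), 3000))
  starts <- sort(c(bg, cl)); ends <- starts + 39
  idx <- select_probe_windows(starts, ends, 100e6, n_probes = 1,
                              n_oligo = 3000, min_resolvable_bp = 8e6,
                              termini_margin_bp = 6e6)
  ws <- starts[idx]; we <- ends[idx + 2999L]
  # exhaustive oracle over all feasible runs
  nrun <- length(starts) - 3000L + 1L
  rs <- starts[seq_len(nrun)]; re <- ends[seq_len(nrun) + 2999L]
  feas <- rs >= 6e6 & re <= 94e6
  expect_equal(we - ws, min((re - rs)[feas]))
  expect_true(ws >= 39e6 && we <= 42e6)  # sits on the cluster
})

test_that("pick_densest_1500 evaluates the three index groups", {
  # uniform spacing: all spans tie, earliest group wins
  st <- seq(0, by = 100, length.out = 3000); en <- st + 39
  expect_equal(pick_densest_1500(st, en), 1:1500)

  # middle half twice as dense
  gaps <- rep(100, 2999); gaps[750:2249] <- 50
  st <- c(0, cumsum(gaps)); en <- st + 39
  expect_equal(pick_densest_1500(st, en), 751:2250)

  # density increasing toward the end
  gaps <- seq(200, 50, length.out = 2999)
  st <- c(0, cumsum(gaps)); en <- st + 39
  g3 <- 1501:3000
  spans <- c(en[1500] - st[1], en[2250] - st[751], en[3000] - st[1501])
  expect_equal(which.min(spans), 3L)
  expect_equal(pick_densest_1500(st, en), g3)

  expect_error(pick_densest_1500(st[1:100], en[1:100]), "exactly 3000")
})

test_that("assign_pair_alternation interleaves strictly and conserves", {
  alt <- assign_pair_alternation(3000, "FAM+A550")
  expect_equal(lengths(alt), c(FAM = 1500L, A550 = 1500L))
  expect_equal(alt$FAM, seq(1, 2999, by = 2))
  expect_equal(alt$A550, seq(2, 3000, by = 2))
  expect_equal(sort(c(alt$FAM, alt$A550)), 1:3000)
  alt2 <- assign_pair_alternation(2, "FAM+A647", strict = FALSE)
  expect_equal(lengths(alt2), c(FAM = 1L, A647 = 1L))
  expect_error(assign_pair_alternation(3000, "FAM"), "paired")
})

test_that("design_panel conserves candidates and respects spacing", {
  genome <- genome_build(c("T1", "T2"), c(90e6, 60e6))
  cand <- simulate_candidates(genome, sim_config(candidate_rate = 1 / 400),
                              seed = 7)
  panel <- design_panel(cand, genome, c(T1 = 3L, T2 = 2L),
                        min_resolvable_bp = 8e6, termini_margin_bp = 6e6)
  expect_equal(nrow(panel), 5L)
  for (ch in c("T1", "T2")) {
    p <- panel[panel$chrom == ch, ]
    cc <- cand[cand$chrom == ch]
    for (i in seq_len(nrow(p))) {
      win <- cc[p$idx_first[i] + 0:(p$n_oligo[i] - 1L)]
      expect_equal(win$start[1L], p$start[i])         # subset of candidates
      expect_equal(win$end[nrow(win)], p$end[i])
    }
    if (nrow(p) > 1L) {
      expect_true(all(p$start[-1L] - p$end[-nrow(p)] >= 8e6))
    }
    # no oligo in two probes
    owned <- unlist(lapply(seq_len(nrow(p)), function(i)
      p$idx_first[i] + 0:(p$n_oligo[i] - 1L)))
    expect_false(anyDuplicated(owned) > 0)
  }
  # density identity
  expect_equal(panel$density_oligo_per_kb * (panel$end - panel$start) / 1000,
               as.numeric(panel$n_oligo))
})

test_that("summary matches a brute-force oracle on random panels", {
  one_gap <- data.table::data.table(
    probe_id = c("a", "b"), chrom = "T1", start = c(10e6, 20.5e6),
    end = c(10.5e6, 21e6), n_oligo = 3000L, colour = NA_character_,
    density_oligo_per_kb = 6, rank = 1:2, idx_first = NA_integer_)
  g <- genome_build("T1", 40e6)
  data.table::setattr(one_gap, "class", c("probe_panel", class(one_gap)))
  s <- summarize_panel(one_gap, g)
  expect_equal(s$per_chrom$mean_interprobe_mb, 10)

  set.seed(21)
  for (rep in 1:100) {
    nchrom <- sample(3:6, 1)
    genome <- genome_build(paste0("R", seq_len(nchrom)),
                           runif(nchrom, 60e6, 200e6))
    rows <- lapply(seq_len(nchrom), function(i) {
      np <- sample(2:6, 1)
      L <- genome$length_bp[i]
      mids <- sort(runif(np, 7e6, L - 7e6))
      w <- runif(np, 3e5, 6e5)
      data.table::data.table(
        probe_id = sprintf("R%d_p%d", i, 1:np), chrom = genome$chrom[i],
        start = mids - w / 2, end = mids + w / 2,
        n_oligo = sample(c(1500L, 3000L), np, replace = TRUE),
        colour = NA_character_, rank = 1:np, idx_first = NA_integer_)
    })
    panel <- data.table::rbindlist(rows)
    panel$density_oligo_per_kb <-
      panel$n_oligo / ((panel$end - panel$start) / 1000)
    data.table::setattr(panel, "class", c("probe_panel", class(panel)))
    s <- summarize_panel(panel, genome)
    # brute-force recomputation with plain loops
    for (i in seq_len(nchrom)) {
      p <- panel[panel$chrom == genome$chrom[i], ]
      dens <- cov <- inter <- c()
      for (k in seq_len(nrow(p))) {
        dens <- c(dens, p$n_oligo[k] / ((p$end[k] - p$start[k]) / 1000))
        cov <- c(cov, (p$end[k] - p$start[k]) / 1000)
        if (k > 1) inter <- c(inter, (p$start[k] - p$end[k - 1]) / 1e6)
      }
      row <- s$per_chrom[s$per_chrom$chrom == genome$chrom[i], ]
      expect_equal(row$mean_density, mean(dens))
      expect_equal(row$mean_coverage_kb, mean(cov))
      expect_equal(row$mean_interprobe_mb, mean(inter))
      expect_equal(row$mean_dist_ends_mb,
                   mean(c(p$start[1], genome$length_bp[i] -
                            p$end[nrow(p)])) / 1e6)
    }
    expect_equal(s$overall$n_probes, sum(s$per_chrom$n_probes))
    expect_equal(s$overall$mean_density, mean(s$per_chrom$mean_density))
    expect_equal(s$overall$sd_interprobe_mb,
                 sd(s$per_chrom$mean_interprobe_mb))
  }
})

test_that("zero-probe chromosomes are rejected, single-probe handled", {
  panel <- toy_panel()
  expect_error(per_chrom <- summarize_panel(
    panel[panel$chrom == "no_such", ], toy_genome()))
  one <- panel[panel$chrom == "C1" & panel$rank == 1, ]
  data.table::setattr(one, "class", c("probe_panel", class(one)))
  s <- summarize_panel(one, toy_genome())
  expect_true(is.na(s$per_chrom$mean_interprobe_mb))
})

test_that("panel export writes TSV and BED9 with colour RGB", {
  panel <- toy_panel()
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_panel(panel, tsv = tsv, bed = bed)
  back <- data.table::fread(tsv)
  expect_equal(nrow(back), nrow(panel))
  bed9 <- data.table::fread(bed, header = FALSE)
  expect_equal(ncol(bed9), 9L)
  expect_true(all(grepl("^\\d+,\\d+,\\d+$", bed9$V9)))
})
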