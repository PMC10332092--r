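make_test_image <- function(h = 60, w = 200, value = 0) {
  chn <- c("FAM", "A550", "A647", "DAPI")
  array(value, dim = c(h, w, length(chn)),
        dimnames = list(NULL, NULL, chn))
}

test_that("extract_profile: constant image, geometry, reversal", {
  img <- make_test_image(value = 7)
  path <- data.frame(x = c(10, 190), y = c(30, 30))
  pr <- extract_profile(img, path, half_width_px = 3)
  expect_true(all(abs(pr$samples - 7) < 1e-9))

  # a band of known extent along a straight path
  img2 <- make_test_image()
  img2[25:35, 80:100, "FAM"] <- 50
  pr2 <- extract_profile(img2, path, half_width_px = 3)
  on <- which(pr2$samples[, "FAM"] > 25)
  # path starts at x=10 with 1 px steps: samples 71..91 cover x 80..100
  expect_true(abs(min(on) - 71) <= 1 && abs(max(on) - 91) <= 1)

  rev_path <- data.frame(x = c(190, 10), y = c(30, 30))
  pr3 <- extract_profile(img2, rev_path, half_width_px = 3)
  expect_equal(pr3$samples[, "FAM"], rev(pr2$samples[, "FAM"]),
               tolerance = 1e-6)

  expect_error(extract_profile(img, data.frame(x = c(1, 300), y = c(30, 30))),
               "exits the image")
  expect_error(extract_profile(img[, , 1], path), "single-channel")
})

test_that("call_bands: noise only, single peak, paired colours", {
  set.seed(5)
  n <- 256
  noise <- matrix(rnorm(n * 3, 100, 10), n, 3,
                  dimnames = list(NULL, c("FAM", "A550", "A647")))
  expect_equal(nrow(call_bands(channel_profiles(noise))), 0L)

  one <- noise
  one[, "A550"] <- one[, "A550"] + 80 * exp(-((1:n - 128)^2) / (2 * 4))
  bands <- call_bands(channel_profiles(one))
  expect_equal(nrow(bands), 1L)
  expect_equal(bands$token, "A550")
  expect_true(bands$start_frac < 0.5 && bands$end_frac > 0.45)

  two <- noise
  bump <- 80 * exp(-((1:n - 60)^2) / (2 * 4))
  two[, "FAM"] <- two[, "FAM"] + bump
  two[, "A647"] <- two[, "A647"] + bump
  bands2 <- call_bands(channel_profiles(two))
  expect_equal(nrow(bands2), 1L)
  expect_equal(bands2$token, "FAM+A647")

  zeroes <- matrix(0, n, 3, dimnames = list(NULL, c("FAM", "A550", "A647")))
  expect_equal(nrow(call_bands(channel_profiles(zeroes))), 0L)
})

test_that("sub-resolution same-colour probes fuse into one band", {
  scheme <- toy_scheme(); panel <- toy_panel(); genome <- toy_genome()
  # C4 has 6 probes; move probes 3 and 4 to sub-merge separation and give
  # them one colour
  panel <- data.table::copy(panel)
  sel <- which(panel$chrom == "C4")
  L <- genome$length_bp[genome$chrom == "C4"]
  panel$start[sel[4]] <- panel$end[sel[3]] + 0.005 * L
  panel$end[sel[4]] <- panel$start[sel[4]] + 4.5e5
  scheme$patterns$C4[4] <- scheme$patterns$C4[3]
  kar <- karyotype_from_scheme(scheme, sex = "XX")
  cp <- kar$copies[[which(vapply(kar$copies, `[[`, character(1), "chrom")
                          == "C4")[1]]]
  sim <- simulate_profile(cp, panel, genome, quiet_config(), seed = 2)
  sig <- build_signature(call_bands(sim$profiles), roi_id = "C4")
  expect_length(sig$tokens, 5L)   # 6 probes, 5 apparent bands
  m <- match_signature(sig, scheme)
  expect_equal(m$best_chrom, "C4")
  expect_lte(m$err, 1L)
})

test_that("build_signature orders bands and rejects overlaps", {
  b <- data.frame(start_frac = c(0.6, 0.1, 0.3), end_frac = c(0.7, 0.2, 0.4),
                  token = c("FAM", "A550", "FAM"),
                  channels = c("FAM", "A550", "FAM"), peak = 1)
  sig <- build_signature(b)
  expect_equal(sig$tokens, c("A550", "FAM", "FAM"))
  # permutation invariance
  sig2 <- build_signature(b[c(3, 1, 2), ])
  expect_equal(sig2$tokens, sig$tokens)
  expect_length(build_signature(b[0, ])$tokens, 0L)
  bad <- data.frame(start_frac = c(0.1, 0.15), end_frac = c(0.2, 0.3),
                    token = "FAM", channels = "FAM", peak = 1)
  expect_error(build_signature(bad), "overlapping")
})

test_that("match_signature finds exact, reversed and near matches", {
  scheme <- toy_scheme()
  m <- match_signature(scheme$patterns$C3, scheme)
  expect_equal(m$best_chrom, "C3")
  expect_equal(m$orientation, "forward")
  expect_equal(m$err, 0L)

  mr <- match_signature(rev(scheme$patterns$C4), scheme)
  expect_equal(mr$best_chrom, "C4")
  expect_equal(mr$orientation, "reverse")
  expect_equal(mr$err, 0L)

  # single substitution, verified against a brute-force oracle
  set.seed(13)
  for (i in 1:30) {
    ch <- sample(names(scheme$patterns), 1)
    sig <- scheme$patterns[[ch]]
    pos <- sample(length(sig), 1)
    sig[pos] <- sample(setdiff(colour_tokens(), sig[pos]), 1)
    m2 <- match_signature(sig, scheme)
    oracle <- Inf
    for (cc in names(scheme$patterns)) {
      oracle <- min(oracle, lev_adist(sig, scheme$patterns[[cc]]),
                    lev_adist(rev(sig), scheme$patterns[[cc]]))
    }
    expect_equal(m2$err, oracle)
    expect_lte(m2$err, 1L)
  }

  # empty signature: low confidence, err = shortest reference
  me <- match_signature(character(0), scheme)
  expect_true(me$low_confidence)
  expect_equal(me$err, 2L)
})

test_that("err == 0 iff the signature equals a reference in some orientation", {
  scheme <- toy_scheme()
  set.seed(19)
  for (i in 1:50) {
    sig <- random_tokens(sample(1:7, 1))
    m <- match_signature(sig, scheme)
    is_ref <- any(vapply(scheme$patterns, function(p) {
      identical(sig, p) || identical(rev(sig), p)
    }, logical(1)))
    expect_equal(m$err == 0L, is_ref)
  }
})

test_that("split_match explains derivatives, insertions, and guards", {
  scheme <- toy_scheme()
  # derivative: C1 bands 1-2 + C4 bands 3-6
  der <- c(scheme$patterns$C1[1:2], scheme$patterns$C4[3:6])
  call <- split_match(der, scheme, max_err = 1)
  expect_equal(call$type, "translocation")
  expect_equal(call$donors, c("C1", "C4"))
  expect_equal(call$split_sig_index, 2L)
  expect_equal(call$retained_prefix, 2L)
  expect_equal(call$suffix_start, 3L)
  expect_equal(call$cost, 0L)

  # insertion between bands 1 and 2
  ins <- append(scheme$patterns$C1, "A550+A647", after = 1)
  icall <- split_match(ins, scheme, max_err = 1)
  expect_equal(icall$type, "insertion")
  expect_equal(icall$donors, "C1")
  expect_equal(icall$gap, 1L)
  expect_equal(icall$inserted_token, "A550+A647")

  # a normal signature yields no call
  expect_null(split_match(scheme$patterns$C2, scheme))
  # reversed derivative also resolves
  rcall <- split_match(rev(der), scheme, max_err = 1)
  expect_equal(rcall$type, "translocation")
  expect_equal(rcall$donors, c("C1", "C4"))
})

test_that("split_match agrees with a brute-force decomposition oracle", {
  scheme <- toy_scheme()
  chroms <- names(scheme$patterns)
  brute_best_cost <- function(sig) {
    best <- Inf
    for (orient in 1:2) {
      tt <- if (orient == 1) sig else rev(sig)
      for (i in chroms) for (j in chroms) {
        if (i == j) next
        pi <- scheme$patterns[[i]]; pj <- scheme$patterns[[j]]
        if (length(tt) < 2) next
        for (k in 1:(length(tt) - 1)) {
          for (p in 1:length(pi)) for (q in 1:length(pj)) {
            cost <- lev_adist(tt[1:k], pi[1:p]) +
              lev_adist(tt[(k + 1):length(tt)], pj[q:length(pj)])
            if (cost < best) best <- cost
          }
        }
      }
    }
    best
  }
  set.seed(23)
  for (rep in 1:15) {
    # corrupt a random derivative with zero or one substitution
    i <- sample(chroms, 1); j <- sample(setdiff(chroms, i), 1)
    pi <- scheme$patterns[[i]]; pj <- scheme$patterns[[j]]
    ka <- sample(length(pi) - 0, 1); qb <- sample(length(pj), 1)
    sig <- c(pi[1:ka], pj[qb:length(pj)])
    call <- split_match(sig, scheme, max_err = 1)
    single_err <- match_signature(sig, scheme)$err
    bc <- brute_best_cost(sig)
    if (!is.null(call) && call$type == "translocation") {
      expect_equal(call$cost, bc)
      expect_lt(call$cost, single_err)  # parsimony guard
    } else if (!is.null(call) && call$type == "insertion") {
      expect_equal(single_err, 1L)      # one inserted token explains it
    } else {
      # no decomposition beat the single-chromosome explanation
      expect_true(bc >= single_err || single_err == 0)
    }
  }
})

test_that("map_breakpoint returns panel coordinates and terminal flags", {
  scheme <- toy_scheme(); panel <- toy_panel(); genome <- toy_genome()
  der <- c(scheme$patterns$C1[1:2], scheme$patterns$C4[3:6])
  call <- split_match(der, scheme, max_err = 1, panel = panel,
                      genome = genome)
  mapped <- map_breakpoint(call, panel, genome)
  bp <- mapped$breakpoints
  p1 <- panel[panel$chrom == "C1", ]
  p4 <- panel[panel$chrom == "C4", ]
  expect_equal(bp$start_bp[1], p1$end[2])
  expect_equal(bp$end_bp[1], p1$start[3])
  expect_equal(bp$start_bp[2], p4$end[2])
  expect_equal(bp$end_bp[2], p4$start[3])
  expect_false(any(bp$terminal))

  # terminal split: C2 full pattern + all of C5 (split after last C2 band;
  # two translocated bands so a single-token insertion cannot explain it)
  der2 <- c(scheme$patterns$C2, scheme$patterns$C5)
  call2 <- split_match(der2, scheme, max_err = 1)
  expect_equal(call2$type, "translocation")
  mapped2 <- map_breakpoint(call2, panel, genome)
  term <- mapped2$breakpoints[mapped2$breakpoints$chrom == "C2", ]
  expect_true(term$terminal)
  expect_equal(term$end_bp, genome$length_bp[genome$chrom == "C2"])
  expect_match(term$note, "reciprocity")
})

test_that("call_karyotype aggregates across spreads with majority rule", {
  scheme <- toy_scheme()
  normal_sigs <- lapply(names(scheme$patterns), function(ch) {
    structure(list(tokens = scheme$patterns[[ch]],
                   positions = NULL, roi_id = ch), class = "signature")
  })
  spreads5 <- replicate(5, normal_sigs, simplify = FALSE)
  rep1 <- call_karyotype(spreads5, scheme, expected_count = 5)
  expect_equal(rep1$status, "normal")
  expect_length(rep1$calls, 0L)

  # the same derivative pair in all 5 spreads -> one reciprocal call
  derA <- c(scheme$patterns$C1[1:2], scheme$patterns$C4[3:6])
  derB <- c(scheme$patterns$C4[1:2], scheme$patterns$C1[3:5])
  rearranged <- lapply(spreads5, function(sp) {
    sp[[1]] <- structure(list(tokens = derA, positions = NULL,
                              roi_id = "derC1"), class = "signature")
    sp[[4]] <- structure(list(tokens = derB, positions = NULL,
                              roi_id = "derC4"), class = "signature")
    sp
  })
  rep2 <- call_karyotype(rearranged, scheme, panel = toy_panel(),
                         genome = toy_genome(), expected_count = 5)
  expect_equal(rep2$status, "rearranged")
  expect_length(rep2$calls, 1L)
  expect_equal(rep2$calls[[1]]$type, "reciprocal_translocation")
  expect_setequal(rep2$calls[[1]]$donors, c("C1", "C4"))
  expect_equal(rep2$calls[[1]]$supporting_spreads, 5L)

  # a single-spread spurious anomaly stays below the majority threshold
  one_bad <- spreads5
  one_bad[[3]][[2]] <- structure(
    list(tokens = append(scheme$patterns$C2, "FAM", 1),
         positions = NULL, roi_id = "odd"), class = "signature")
  rep3 <- call_karyotype(one_bad, scheme, expected_count = 5)
  expect_equal(rep3$status, "normal")
})

test_that("G-band nomenclature formats rcp and add strings", {
  scheme <- toy_scheme(); panel <- toy_panel(); genome <- toy_genome()
  eq <- data.frame(
    chrom = c("C1", "C4", "C1", "C1"),
    kind = c("gap", "gap", "probe", "probe"),
    index = c(2L, 2L, 1L, 2L),
    gband = c("q15", "q10", "p11", "p10"))
  der <- c(scheme$patterns$C1[1:2], scheme$patterns$C4[3:6])
  call <- map_breakpoint(split_match(der, scheme), panel, genome)
  expect_equal(to_gband_nomenclature(call, eq), "rcp(1;4)(q15;q10)")

  ins <- append(scheme$patterns$C1, "A550+A647", after = 1)
  icall <- map_breakpoint(split_match(ins, scheme), panel, genome)
  expect_equal(to_gband_nomenclature(icall, eq),
               "add(1)(pter->p11::?::p10->qter)")

  empty <- eq[0, ]
  # both donor lookups warn on an empty table
  expect_warning(expect_warning(
    s <- to_gband_nomenclature(call, empty), "equivalence"), "equivalence")
  expect_equal(s, "rcp(1;4)(?;?)")
})

test_that("profile extraction + band calling is path-reversal invariant", {
  img <- make_test_image(h = 80, w = 240)
  set.seed(47)
  img <- img + array(rnorm(length(img), 100, 5), dim = dim(img))
  for (ctr in c(60, 120, 180)) {
    img[36:44, (ctr - 3):(ctr + 3), "FAM"] <- 100 +
      matrix(60, 9, 7)
  }
  fwd <- data.frame(x = c(20, 220), y = c(40, 40))
  rev_ <- data.frame(x = c(220, 20), y = c(40, 40))
  sig_f <- build_signature(call_bands(extract_profile(img, fwd)))
  sig_r <- build_signature(call_bands(extract_profile(img, rev_)))
  expect_equal(sig_f$tokens, rev(sig_r$tokens))
  expect_equal(length(sig_f$tokens), 3L)
})
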