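#' Simulation configuration
#'
#' Bundles the tunable parameters of the synthetic-data generators. The
#' defaults state the emulated world: candidate 39mers as a homogeneous
#' Poisson process at one per 150 bp; band profiles of 256 arc-length
#' samples with Gaussian background (mean 100, sd 10) and band amplitude
#' `snr x background_sd` with `snr = 5` (the lower edge of the regime in
#' which banding is read reliably); bands rendered at their genomic
#' midpoints as Gaussian spots whose full width at half maximum is
#' `band_fwhm_frac` of the trace (default 0.035 — a fluorescent spot of
#' roughly 0.5 micron on a metaphase chromosome a few microns long,
#' matching how oligo bands visibly tile a chromosome), floored at
#' `band_min_px = 3` rendered pixels since the genomic span itself
#' (0.3-0.6 Mb) is sub-resolution and visibility is signal-, not span-,
#' driven; zero channel crosstalk; sperm heads around the 5 micron
#' decondensation optimum.
#'
#' @param ... overrides of the defaults listed above.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    candidate_rate = 1 / 150,      # candidates per bp
    n_samples = 256L,              # profile samples per trace
    background_mean = 100,
    background_sd = 10,
    snr = 5,                       # band amplitude = snr * background_sd
    px_per_mb = 1,                 # spread-image scale
    band_min_px = 3,               # minimal rendered band width, px
    band_fwhm_frac = 0.035,        # band FWHM as fraction of the trace
    crosstalk = 0,                 # linear channel-mixing fraction
    bend_amplitude = 0.15,         # chromosome curvature in spread images
    flip_prob = 0.5,               # random trace orientation
    head_width_um = 5,             # sperm decondensation optimum
    head_width_sd = 0.5,
    decondensation = 1,
    duplication_prob = 0)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("oligoband_error_config: unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  if (cfg$snr <= 0) stop("oligoband_error_config: snr must be > 0",
                         call. = FALSE)
  structure(cfg, class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Simulate a candidate 39mer table
#'
#' Homogeneous Poisson positions along each chromosome at
#' `config$candidate_rate`, optionally with dense clusters (each cluster
#' multiplies the local rate over a stated interval). Deterministic per
#' seed.
#'
#' @param genome a [genome_build()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param clusters optional data.frame `chrom`, `start`, `end`, `factor`.
#' @param with_sequence attach random 39 nt sequences (for assembly tests).
#' @return Candidate `data.table` (`chrom`, `start`, `end`, `sequence`).
#' @export
simulate_candidates <- function(genome, config = sim_config(), seed = 1,
                                clusters = NULL, with_sequence = FALSE) {
  rate <- config$candidate_rate
  with_seed(seed, {
    out <- lapply(seq_len(nrow(genome)), function(i) {
      ch <- genome$chrom[i]; L <- genome$length_bp[i]
      if (rate <= 0) return(NULL)
      n <- stats::rpois(1L, rate * L)
      starts <- sort(floor(stats::runif(n, 0, L - 39)))
      if (!is.null(clusters)) {
        cl <- clusters[clusters$chrom == ch, , drop = FALSE]
        for (r in seq_len(nrow(cl))) {
          extra_rate <- rate * (cl$factor[r] - 1)
          ne <- stats::rpois(1L, extra_rate * (cl$end[r] - cl$start[r]))
          starts <- sort(c(starts, floor(stats::runif(ne, cl$start[r],
                                                      cl$end[r] - 39))))
        }
      }
      starts <- unique(starts)
      if (!length(starts)) return(NULL)
      data.table::data.table(chrom = ch, start = starts, end = starts + 39,
                             sequence = if (with_sequence) {
                               random_seqs(length(starts), 39L)
                             } else NA_character_)
    })
    res <- data.table::rbindlist(out)
    if (nrow(res)) validate_candidates(res, genome) else res
  })
}

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

gaussian_bump <- function(n, centre, sigma) {
  x <- seq_len(n)
  exp(-((x - centre)^2) / (2 * sigma^2))
}

render_profile <- function(tokens, fracs, config) {
  n <- config$n_samples
  chn <- fluorophores()
  amp <- config$snr * config$background_sd
  sig <- matrix(0, n, length(chn), dimnames = list(NULL, chn))
  sigma <- max(config$band_min_px, config$band_fwhm_frac * n) / 2.355
  for (b in seq_along(tokens)) {
    for (fl in token_fluors(tokens[b])) {
      sig[, fl] <- sig[, fl] + amp * gaussian_bump(n, fracs[b] * n, sigma)
    }
  }
  if (config$crosstalk > 0) {
    mix <- matrix(config$crosstalk, 3, 3); diag(mix) <- 1
    sig <- sig %*% mix
    colnames(sig) <- chn
  }
  dapi <- amp * 0.5 * pmin(1, pmin(seq_len(n), n + 1 - seq_len(n)) / (0.05 * n))
  out <- cbind(sig, DAPI = dapi)
  out + matrix(stats::rnorm(length(out), config$background_mean,
                            config$background_sd), nrow = n)
}

#' Simulate a traced-chromosome band profile
#'
#' Renders each band as a Gaussian bump (amplitude `snr x background_sd`)
#' at its genomic midpoint mapped to an arc-length fraction; paired-colour
#' tokens light both of their channels; a smooth DAPI envelope covers the
#' full trace; Gaussian background noise is added everywhere. The trace
#' orientation is flipped with probability `flip_prob` and recorded in the
#' ground truth.
#'
#' @param copy a karyotype copy (normal or derivative).
#' @param panel coloured `probe_panel`.
#' @param genome a [genome_build()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param roi_id trace id.
#' @return List `profiles` (a [channel_profiles()]) and `truth`
#'   (`chrom`, `derivative`, `tokens`, `fracs`, `flipped`).
#' @export
simulate_profile <- function(copy, panel, genome, config = sim_config(),
                             seed = 1, roi_id = copy$chrom) {
  pos <- copy_band_positions(copy, panel, genome)
  with_seed(seed, {
    flipped <- stats::runif(1) < config$flip_prob
    fr <- if (flipped) rev(1 - pos$fracs) else pos$fracs
    toks <- if (flipped) rev(copy$tokens) else copy$tokens
    samples <- render_profile(toks, fr, config)
    list(profiles = channel_profiles(samples, roi_id = roi_id),
         truth = list(chrom = copy$chrom, derivative = copy$derivative,
                      tokens = toks, fracs = fr, flipped = flipped,
                      tokens_pq = copy$tokens))
  })
}

#' Simulate a full spread as traced profiles
#'
#' One profile per chromosome copy of the karyotype; the "spread" is the
#' set of traces an analyst would produce from one metaphase image.
#'
#' @inheritParams simulate_profile
#' @param kar a `karyotype`.
#' @return List with `profiles` (list of [channel_profiles()]) and
#'   `truth` (per-trace ground truth).
#' @export
simulate_spread <- function(kar, panel, genome, config = sim_config(),
                            seed = 1) {
  out <- lapply(seq_along(kar$copies), function(i) {
    cp <- kar$copies[[i]]
    simulate_profile(cp, panel, genome, config, seed = seed * 1000L + i,
                     roi_id = sprintf("roi%02d_%s_h%d", i, cp$chrom,
                                      cp$homolog))
  })
  list(profiles = lapply(out, `[[`, "profiles"),
       truth = lapply(out, `[[`, "truth"))
}

smooth_curve <- function(n_pts, x0, y0, angle, length_px, bend) {
  t <- seq(0, 1, length.out = n_pts)
  a <- angle + bend * sin(pi * t)
  dx <- cos(a) * (length_px / (n_pts - 1))
  dy <- sin(a) * (length_px / (n_pts - 1))
  data.frame(x = x0 + c(0, cumsum(dx[-1L])), y = y0 + c(0, cumsum(dy[-1L])))
}

#' Simulate a multi-channel spread image with traces
#'
#' Draws each chromosome copy as a smooth curve on a
#' `height x width x {FAM,A550,A647,DAPI}` array, renders its bands as
#' Gaussian spots along the curve, and returns the true traces (the
#' analyzer's ROI input) plus ground truth. Curves are placed with retries
#' to stay inside the image; with `overlap_prob` placement does not avoid
#' other chromosomes.
#'
#' @inheritParams simulate_spread
#' @param height,width image size in pixels.
#' @param overlap_prob probability a chromosome is placed ignoring overlap
#'   avoidance (recorded in truth).
#' @param max_retries placement retries per chromosome before failing.
#' @return List `image` (array), `traces` (list of data.frames `x`, `y`),
#'   `truth`.
#' @export
simulate_spread_image <- function(kar, panel, genome,
                                  config = sim_config(), seed = 1,
                                  height = 512, width = 512,
                                  overlap_prob = 0, max_retries = 50) {
  chn <- c(fluorophores(), "DAPI")
  img <- array(0, dim = c(height, width, length(chn)),
               dimnames = list(NULL, NULL, chn))
  if (!length(kar$copies)) {
    return(list(image = img + config$background_mean, traces = list(),
                truth = list()))
  }
  amp <- config$snr * config$background_sd
  occupied <- matrix(FALSE, height, width)
  traces <- list(); truth <- list()
  with_seed(seed, {
    for (i in seq_along(kar$copies)) {
      cp <- kar$copies[[i]]
      pos <- copy_band_positions(cp, panel, genome)
      len_px <- max(30, pos$length_bp / 1e6 * config$px_per_mb)
      placed <- FALSE
      ignore_overlap <- stats::runif(1) < overlap_prob
      for (try in seq_len(max_retries)) {
        x0 <- stats::runif(1, 20, width - 20)
        y0 <- stats::runif(1, 20, height - 20)
        ang <- stats::runif(1, 0, 2 * pi)
        crv <- smooth_curve(max(20L, ceiling(len_px / 2)), x0, y0, ang,
                            len_px, config$bend_amplitude * pi)
        if (any(crv$x < 8 | crv$x > width - 8 |
                crv$y < 8 | crv$y > height - 8)) next
        cells <- cbind(pmax(1, pmin(height, round(crv$y))),
                       pmax(1, pmin(width, round(crv$x))))
        if (!ignore_overlap && any(occupied[cells])) next
        placed <- TRUE
        occupied[cells] <- TRUE
        break
      }
      if (!placed) {
        stop("oligoband_error_simulate: could not place chromosome ",
             cp$chrom, " after ", max_retries, " retries", call. = FALSE)
      }
      flipped <- stats::runif(1) < config$flip_prob
      fr <- if (flipped) rev(1 - pos$fracs) else pos$fracs
      toks <- if (flipped) rev(cp$tokens) else cp$tokens
      # DAPI body along the whole curve
      cum <- c(0, cumsum(sqrt(diff(crv$x)^2 + diff(crv$y)^2)))
      total <- cum[length(cum)]
      body_t <- seq(0, total, by = 1)
      bx <- stats::approx(cum, crv$x, xout = body_t)$y
      by <- stats::approx(cum, crv$y, xout = body_t)$y
      img[, , "DAPI"] <- img[, , "DAPI"] +
        splat_spots(height, width, bx, by, amp * 0.5, sigma = 2.5)
      for (b in seq_along(toks)) {
        s <- fr[b] * total
        sx <- stats::approx(cum, crv$x, xout = s)$y
        sy <- stats::approx(cum, crv$y, xout = s)$y
        for (fl in token_fluors(toks[b])) {
          img[, , fl] <- img[, , fl] +
            splat_spots(height, width, sx, sy, amp,
                        sigma = config$band_min_px / 2.355 + 1)
        }
      }
      traces[[i]] <- crv
      truth[[i]] <- list(chrom = cp$chrom, derivative = cp$derivative,
                         tokens = toks, flipped = flipped,
                         overlap_allowed = ignore_overlap)
    }
    img <- img + array(stats::rnorm(length(img), config$background_mean,
                                    config$background_sd), dim = dim(img))
    list(image = img, traces = traces, truth = truth)
  })
}

splat_spots <- function(h, w, xs, ys, amp, sigma) {
  out <- matrix(0, h, w)
  r <- ceiling(3 * sigma)
  for (k in seq_along(xs)) {
    cx <- xs[k]; cy <- ys[k]
    x0 <- max(1, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
    y0 <- max(1, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
    gx <- exp(-((x0:x1 - cx)^2) / (2 * sigma^2))
    gy <- exp(-((y0:y1 - cy)^2) / (2 * sigma^2))
    out[y0:y1, x0:x1] <- out[y0:y1, x0:x1] + amp * outer(gy, gx)
  }
  out
}

#' Simulate sperm-head signal multisets
#'
#' Heads are drawn from the stated gamete-class mixture; with probability
#' `duplication_prob x decondensation` one random signal per head is
#' duplicated (the over-decondensation artefact); head widths are drawn
#' around the 5 micron optimum.
#'
#' @param classes output of [enumerate_2_2_segregation()].
#' @param freqs class mixture frequencies (must sum to 1).
#' @param n_heads number of heads.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List with `observed` (list of key/count data.frames), `truth`
#'   (class labels), `duplicated` (logical), `head_width_um`.
#' @export
simulate_sperm_heads <- function(classes, freqs, n_heads = 1000,
                                 config = sim_config(), seed = 1) {
  if (abs(sum(freqs) - 1) > 1e-8) {
    stop("oligoband_error_simulate: class frequencies must sum to 1",
         call. = FALSE)
  }
  with_seed(seed, {
    idx <- sample(seq_along(classes), n_heads, replace = TRUE, prob = freqs)
    p_dup <- min(1, config$duplication_prob * config$decondensation)
    dup <- stats::runif(n_heads) < p_dup
    observed <- lapply(seq_len(n_heads), function(i) {
      ms <- classes[[idx[i]]]$expected_signals
      if (dup[i] && nrow(ms)) {
        j <- sample(nrow(ms), 1L)
        ms$count[j] <- ms$count[j] + 1L
      }
      ms
    })
    list(observed = observed,
         truth = vapply(idx, function(i) classes[[i]]$label, character(1)),
         duplicated = dup,
         head_width_um = stats::rnorm(n_heads, config$head_width_um,
                                      config$head_width_sd))
  })
}

#' Write / read a multi-channel image as plain text
#'
#' One whitespace-delimited matrix block per channel, preceded by a
#' `#channel <name> <nrow> <ncol>` header line. A portable text stand-in
#' for multi-channel TIFF.
#'
#' @param image `height x width x channels` array with channel names.
#' @param path file path.
#' @return `write_image_txt`: invisibly the path; `read_image_txt`: the
#'   array.
#' @export
write_image_txt <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in dimnames(image)[[3L]]) {
    m <- image[, , ch]
    writeLines(sprintf("#channel %s %d %d", ch, nrow(m), ncol(m)), con)
    utils::write.table(round(m, 3), con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_image_txt
#' @export
read_image_txt <- function(path) {
  lines <- readLines(path)
  heads <- grep("^#channel ", lines)
  mats <- list()
  for (i in seq_along(heads)) {
    hd <- strsplit(lines[heads[i]], " ")[[1L]]
    nr <- as.integer(hd[3L])
    block <- lines[(heads[i] + 1L):(heads[i] + nr)]
    mats[[hd[2L]]] <- do.call(rbind, lapply(strsplit(block, " +"),
                                            as.numeric))
  }
  arr <- array(0, dim = c(nrow(mats[[1L]]), ncol(mats[[1L]]), length(mats)),
               dimnames = list(NULL, NULL, names(mats)))
  for (ch in names(mats)) arr[, , ch] <- mats[[ch]]
  arr
}
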