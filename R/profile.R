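#' Multi-channel intensity profiles along a traced chromosome
#'
#' @param samples numeric matrix, one row per equal arc-length step, one
#'   named column per channel (fluorophores and optionally `DAPI`).
#' @param step_px arc-length step in pixels (informational).
#' @param roi_id trace identifier.
#' @return A `channel_profiles` object.
#' @export
channel_profiles <- function(samples, step_px = 1, roi_id = "roi") {
  samples <- as.matrix(samples)
  if (is.null(colnames(samples))) {
    stop("oligoband_error_profile: sample matrix needs channel column names",
         call. = FALSE)
  }
  structure(list(samples = samples, step_px = step_px, roi_id = roi_id),
            class = "channel_profiles")
}

#' @export
print.channel_profiles <- function(x, ...) {
  cat("<channel_profiles '", x$roi_id, "': ", nrow(x$samples),
      " samples x ", ncol(x$samples), " channels (",
      paste(colnames(x$samples), collapse = ", "), ")>\n", sep = "")
  invisible(x)
}

bilinear <- function(mat, y, x) {
  y0 <- floor(y); x0 <- floor(x)
  y1 <- pmin(y0 + 1, nrow(mat)); x1 <- pmin(x0 + 1, ncol(mat))
  fy <- y - y0; fx <- x - x0
  mat[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    mat[cbind(y1, x0)] * fy * (1 - fx) +
    mat[cbind(y0, x1)] * (1 - fy) * fx +
    mat[cbind(y1, x1)] * fy * fx
}

#' Extract channel intensity profiles along a traced path
#'
#' Resamples the traced polyline at equal arc-length steps and, at each
#' step, averages each channel's (bilinearly interpolated) intensity over a
#' segment perpendicular to the path of half-width `half_width_px`. The
#' DAPI channel, when present in the image, is extracted alongside the
#' fluorophore channels for extent/centromere context.
#'
#' @param image numeric array `height x width x channels` with channel
#'   names in `dimnames(image)[[3]]`.
#' @param path data.frame/matrix with columns `x` (column coordinate) and
#'   `y` (row coordinate) of at least 2 distinct points, inside the image.
#' @param half_width_px half-width of the perpendicular averaging segment.
#' @param step_px arc-length sampling step in pixels.
#' @param roi_id trace id.
#' @return A [channel_profiles()].
#' @export
extract_profile <- function(image, path, half_width_px = 3, step_px = 1,
                            roi_id = "roi") {
  if (length(dim(image)) == 2L) {
    stop("oligoband_error_profile: single-channel matrix given; a ",
         "height x width x channels array with channel names is required",
         call. = FALSE)
  }
  chn <- dimnames(image)[[3L]]
  if (is.null(chn)) {
    stop("oligoband_error_profile: image lacks channel names", call. = FALSE)
  }
  px <- as.numeric(path$x); py <- as.numeric(path$y)
  if (length(px) < 2L) {
    stop("oligoband_error_profile: a traced path needs >= 2 points",
         call. = FALSE)
  }
  keep <- c(TRUE, diff(px) != 0 | diff(py) != 0)
  px <- px[keep]; py <- py[keep]
  seglen <- sqrt(diff(px)^2 + diff(py)^2)
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step_px)
  if (s[length(s)] < total) s <- c(s, total)
  xi <- stats::approx(cum, px, xout = s)$y
  yi <- stats::approx(cum, py, xout = s)$y
  # tangents by central differences
  tx <- c(xi[2] - xi[1], diff(xi, lag = 2) / 2,
          xi[length(xi)] - xi[length(xi) - 1])
  ty <- c(yi[2] - yi[1], diff(yi, lag = 2) / 2,
          yi[length(yi)] - yi[length(yi) - 1])
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  nx <- -ty / nrm; ny <- tx / nrm
  offs <- seq(-half_width_px, half_width_px, by = 1)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  sx <- outer(xi, offs, function(a, o) a + 0) + outer(nx, offs)
  sy <- outer(yi, offs, function(a, o) a + 0) + outer(ny, offs)
  if (any(sx < 1 | sx > w | sy < 1 | sy > h)) {
    stop("oligoband_error_profile: path (with half-width ", half_width_px,
         ") exits the image bounds", call. = FALSE)
  }
  samples <- vapply(chn, function(ch) {
    vals <- bilinear(image[, , ch], as.vector(sy), as.vector(sx))
    rowMeans(matrix(vals, nrow = length(xi)))
  }, numeric(length(xi)))
  channel_profiles(samples, step_px = step_px, roi_id = roi_id)
}

moving_average <- function(x, k = 3L) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# sigma-clipped background level and scale; initialized from the lower
# quantiles (a channel's bands can cover half of a derivative trace, so a
# median-initialized clip never escapes the contamination), then refined
# by clipping above level + 3 scale
clipped_background <- function(x) {
  q <- stats::quantile(x, c(0.05, 0.25), names = FALSE)
  m <- q[2L]
  s <- (q[2L] - q[1L]) / 0.9704   # z(0.25) - z(0.05) for a Gaussian
  if (s == 0) return(c(m, 0))
  for (i in 1:6) {
    keep <- x < m + 3 * s
    if (!any(keep)) break
    m <- stats::median(x[keep])
    s2 <- stats::mad(x[keep])
    if (s2 == 0) break
    s <- s2
  }
  c(m, s)
}

# split a run at internal valleys that dip below half the height of the
# lower of the two flanking peaks (relative to the background median)
split_run_at_valleys <- function(x, seg, med) {
  if (length(seg) < 5L) return(list(seg))
  xv <- x[seg]
  k <- length(xv)
  is_max <- c(FALSE, xv[2:(k - 1)] >= xv[1:(k - 2)] &
                xv[2:(k - 1)] >= xv[3:k], FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2L) return(list(seg))
  cuts <- integer(0)
  last_peak <- peaks[1L]
  for (p in peaks[-1L]) {
    valley <- last_peak + which.min(xv[last_peak:p]) - 1L
    lower <- min(xv[last_peak], xv[p])
    if (xv[valley] - med < 0.5 * (lower - med)) {
      cuts <- c(cuts, valley)
      last_peak <- p
    } else if (xv[p] > xv[last_peak]) {
      last_peak <- p
    }
  }
  if (!length(cuts)) return(list(seg))
  bounds <- c(0L, cuts, k)
  lapply(seq_len(length(bounds) - 1L), function(i) {
    seg[(bounds[i] + 1L):bounds[i + 1L]]
  })
}

runs_above <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

#' Call colour bands from channel profiles
#'
#' Per fluorophore channel, the profile is smoothed with a moving average
#' matched to the nominal band width, then thresholded at
#' `bg + k_sigma x sigma_bg`, where the background level and scale come
#' from iterative sigma clipping (median/MAD recomputed on samples below
#' `bg + 3 sigma`, five rounds) so that bright bands covering a large
#' fraction of the trace do not inflate the threshold; maximal
#' above-threshold runs of at least `min_band_frac` of the profile
#' length become channel bands, each trimmed to its full width at half
#' maximum (threshold-based extents grow with band brightness, FWHM
#' extents do not), with runs split at valleys separating distinct peaks. Channel bands overlapping reciprocally by at
#' least 50 percent are fused into one band whose token carries both
#' fluorophores (paired colours); finally, band calls whose centres are
#' closer than `merge_frac` of the trace length fuse into one call (same
#' colour: one wider band; different colours: a composite token of the two
#' strongest fluorophores).
#'
#' @param profiles a [channel_profiles()]; the `DAPI` channel is ignored
#'   for calling.
#' @param k_sigma threshold multiplier on the background scale, default
#'   4.5 (about 4.5 sigma of the smoothed background: negligible false
#'   positives under the run-length rule, while a band of amplitude
#'   5 x background sd keeps a comfortable detection margin).
#' @param min_band_frac minimal run length as a fraction of the profile,
#'   default 0.01 (at least 2 samples).
#' @param merge_frac centre-to-centre fusion distance as a fraction of the
#'   trace, default 0.02.
#' @param smooth_k moving-average window (samples), default 5 — matched to
#'   the nominal rendered band width so thresholding acts on a
#'   noise-suppressed profile.
#' @return data.frame of band calls: `start_frac`, `end_frac`, `token`,
#'   `channels` (comma-joined), `peak` (max intensity over its channels);
#'   zero rows when nothing is above threshold.
#' @export
call_bands <- function(profiles, k_sigma = 4.5, min_band_frac = 0.01,
                       merge_frac = 0.02, smooth_k = 5L) {
  sm <- profiles$samples
  chn <- setdiff(colnames(sm), "DAPI")
  if (!length(chn)) {
    stop("oligoband_error_bands: no fluorophore channel in profiles",
         call. = FALSE)
  }
  n <- nrow(sm)
  minlen <- max(2L, ceiling(min_band_frac * n))
  ch_runs <- list()
  for (ch in chn) {
    x <- moving_average(sm[, ch], smooth_k)
    bg <- clipped_background(x)
    med <- bg[1L]
    thr <- med + k_sigma * bg[2L]
    rr <- runs_above(x > thr)
    if (nrow(rr)) {
      rr <- rr[rr[, "end"] - rr[, "start"] + 1L >= minlen, , drop = FALSE]
      for (q in seq_len(nrow(rr))) {
        seg <- rr[q, "start"]:rr[q, "end"]
        # a bright pair of neighbouring bands can share one threshold run:
        # split at valleys dipping below half of the lower flanking peak
        for (sub in split_run_at_valleys(x, seg, med)) {
          # refine the extent to full width at half maximum:
          # threshold-based extents grow with band brightness, FWHM
          # extents do not
          pk <- sub[which.max(x[sub])]
          half <- med + (x[pk] - med) / 2
          lo <- pk; while (lo > 1L && x[lo - 1L] > half) lo <- lo - 1L
          hi <- pk; while (hi < n && x[hi + 1L] > half) hi <- hi + 1L
          ch_runs[[length(ch_runs) + 1L]] <- list(
            channel = ch, start = lo, end = hi,
            peak = max(sm[sub, ch]))
        }
      }
    }
  }
  if (!length(ch_runs)) {
    return(data.frame(start_frac = numeric(0), end_frac = numeric(0),
                      token = character(0), channels = character(0),
                      peak = numeric(0), stringsAsFactors = FALSE))
  }
  # fuse cross-channel runs with >= 50% reciprocal overlap (union-find)
  m <- length(ch_runs)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      a <- ch_runs[[i]]; b <- ch_runs[[j]]
      ov <- min(a$end, b$end) - max(a$start, b$start) + 1L
      la <- a$end - a$start + 1L; lb <- b$end - b$start + 1L
      if (ov >= 0.5 * la && ov >= 0.5 * lb) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(m), find, integer(1))
  bands <- lapply(unique(comp), function(g) {
    rs <- ch_runs[comp == g]
    chs <- vapply(rs, `[[`, character(1), "channel")
    pk <- vapply(rs, `[[`, numeric(1), "peak")
    # a channel may contribute several runs in one component; keep max peak
    agg <- tapply(pk, chs, max)
    list(start = min(vapply(rs, `[[`, numeric(1), "start")),
         end = max(vapply(rs, `[[`, numeric(1), "end")),
         channels = names(agg), peaks = as.numeric(agg))
  })
  token_of <- function(channels, peaks) {
    if (length(channels) > 2L) {
      keep <- order(peaks, decreasing = TRUE)[1:2]
      channels <- channels[keep]
    }
    make_token(channels)
  }
  bands <- bands[order(vapply(bands, function(b) (b$start + b$end) / 2,
                              numeric(1)))]
  # fuse sub-resolution neighbours
  i <- 1L
  while (i < length(bands)) {
    a <- bands[[i]]; b <- bands[[i + 1L]]
    ca <- (a$start + a$end) / 2; cb <- (b$start + b$end) / 2
    if ((cb - ca) / n < merge_frac) {
      chs <- c(a$channels, b$channels)
      pks <- c(a$peaks, b$peaks)
      agg <- tapply(pks, chs, max)
      bands[[i]] <- list(start = min(a$start, b$start),
                         end = max(a$end, b$end),
                         channels = names(agg), peaks = as.numeric(agg))
      bands[[i + 1L]] <- NULL
    } else i <- i + 1L
  }
  data.frame(
    start_frac = vapply(bands, function(b) (b$start - 1) / n, numeric(1)),
    end_frac = vapply(bands, function(b) b$end / n, numeric(1)),
    token = vapply(bands, function(b) token_of(b$channels, b$peaks),
                   character(1)),
    channels = vapply(bands, function(b) paste(b$channels, collapse = ","),
                      character(1)),
    peak = vapply(bands, function(b) max(b$peaks), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Build an ordered signature from band calls
#'
#' @param bands band-call data.frame from [call_bands()] (any row order).
#' @param roi_id trace id.
#' @return A `signature`: list with `tokens`, `positions` (two-column
#'   matrix of start/end fractions) and `roi_id`.
#' @export
build_signature <- function(bands, roi_id = "roi") {
  if (nrow(bands) == 0L) {
    return(structure(list(tokens = character(0),
                          positions = matrix(numeric(0), ncol = 2),
                          roi_id = roi_id), class = "signature"))
  }
  o <- order(bands$start_frac)
  bands <- bands[o, ]
  if (nrow(bands) > 1L) {
    if (any(bands$start_frac[-1L] < bands$end_frac[-nrow(bands)] - 1e-9)) {
      stop("oligoband_error_signature: overlapping bands after merging",
           call. = FALSE)
    }
  }
  structure(list(tokens = bands$token,
                 positions = cbind(bands$start_frac, bands$end_frac),
                 roi_id = roi_id),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat("<signature '", x$roi_id, "': ",
      paste(x$tokens, collapse = " | "), ">\n", sep = "")
  invisible(x)
}
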