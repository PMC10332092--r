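#' Import/export traced-chromosome profiles as TSV
#'
#' Long format: `roi_id`, `idx` (1-based sample index) and one column per
#' channel. A trace TSV dialect (`roi_id`, `idx`, `x`, `y`) is read with
#' [read_traces_tsv()].
#'
#' @param profiles a [channel_profiles()] or list of them.
#' @param path TSV path.
#' @return `write_profiles_tsv`: invisibly the path;
#'   `read_profiles_tsv`: a list of [channel_profiles()].
#' @export
write_profiles_tsv <- function(profiles, path) {
  if (inherits(profiles, "channel_profiles")) profiles <- list(profiles)
  rows <- data.table::rbindlist(lapply(profiles, function(p) {
    data.table::data.table(roi_id = p$roi_id,
                           idx = seq_len(nrow(p$samples)),
                           as.data.frame(p$samples))
  }))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  chn <- setdiff(names(dt), c("roi_id", "idx"))
  lapply(split(dt, dt$roi_id), function(d) {
    d <- d[order(d$idx)]
    channel_profiles(as.matrix(d[, chn, with = FALSE]),
                     roi_id = d$roi_id[1L])
  })
}

#' @rdname write_profiles_tsv
#' @param traces list of data.frames with `x`, `y` (named by roi).
#' @export
write_traces_tsv <- function(traces, path) {
  if (is.null(names(traces))) {
    names(traces) <- sprintf("roi%02d", seq_along(traces))
  }
  rows <- data.table::rbindlist(lapply(names(traces), function(id) {
    data.table::data.table(roi_id = id,
                           idx = seq_len(nrow(traces[[id]])),
                           x = traces[[id]]$x, y = traces[[id]]$y)
  }))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
read_traces_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  lapply(split(dt, dt$roi_id), function(d) {
    d <- d[order(d$idx)]
    data.frame(x = d$x, y = d$y)
  })
}
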