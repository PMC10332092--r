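#' Levenshtein distance between two colour-token sequences
#'
#' Standard unit-cost edit distance (substitution/insertion/deletion all
#' cost 1) computed by dynamic programming at C level. Token identity is
#' exact string equality; any labels are accepted.
#'
#' @param a,b character vectors of tokens (may be empty).
#' @return Integer edit distance.
#' @export
#' @examples
#' levenshtein(c("FAM", "A550"), c("FAM", "A647"))  # 1
levenshtein <- function(a, b) {
  alph <- unique(c(colour_tokens(), a, b))
  .lev_int(tokens_to_int(a, alph), tokens_to_int(b, alph))
}

#' Draw one random banding scheme
#'
#' Each band of each chromosome is drawn uniformly and independently from
#' the six-token alphabet. An optional constraint forbids identical adjacent
#' tokens within a chromosome (off by default, mirroring the unconstrained
#' random generation of candidate schemes).
#'
#' @param probe_counts named integer vector: bands per chromosome (>= 1).
#' @param seed integer seed; the draw is deterministic per seed.
#' @param forbid_adjacent_repeat disallow equal consecutive tokens on a
#'   chromosome.
#' @return A `scheme`: list with `patterns` (named list of token vectors),
#'   `seed`, and `score` (NULL until scored).
#' @export
random_scheme <- function(probe_counts, seed = NULL,
                          forbid_adjacent_repeat = FALSE) {
  stopifnot(all(probe_counts >= 1L))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  toks <- colour_tokens()
  patterns <- lapply(probe_counts, function(k) {
    p <- sample(toks, k, replace = TRUE)
    if (forbid_adjacent_repeat && k > 1L) {
      for (i in 2:k) {
        while (p[i] == p[i - 1L]) p[i] <- sample(toks, 1L)
      }
    }
    p
  })
  names(patterns) <- names(probe_counts)
  structure(list(patterns = patterns, seed = seed, score = NULL),
            class = "scheme")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Score a scheme by pairwise Levenshtein distances
#'
#' @param scheme a `scheme` with at least two chromosomes.
#' @return List `(min_pairwise, sum_pairwise)` over all unordered
#'   chromosome pairs.
#' @export
scheme_score <- function(scheme) {
  pats <- scheme$patterns
  n <- length(pats)
  if (n < 2L) {
    stop("oligoband_error_scheme: scoring needs >= 2 chromosomes",
         call. = FALSE)
  }
  enc <- lapply(pats, tokens_to_int)
  mn <- Inf; sm <- 0L
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- .lev_int(enc[[i]], enc[[j]])
      sm <- sm + d
      if (d < mn) mn <- d
    }
  }
  list(min_pairwise = as.integer(mn), sum_pairwise = as.integer(sm))
}

#' Optimize the karyotype colour scheme
#'
#' Generates `n_candidates` random schemes and returns the lexicographic
#' best: maximal minimum pairwise Levenshtein distance, ties broken by
#' maximal sum of pairwise distances, then by lowest candidate index.
#' Maximizing the minimum directly encodes unambiguous chromosome
#' identification; the returned scheme records its seed and score.
#'
#' @inheritParams random_scheme
#' @param n_candidates number of random schemes to draw (default 1000).
#' @param seed seed for the candidate stream; candidate `i` is drawn with
#'   sub-seed `seed + i - 1`.
#' @return The best `scheme`, with `score` and `candidate_index` filled.
#' @export
optimize_scheme <- function(probe_counts, n_candidates = 1000, seed = 1,
                            forbid_adjacent_repeat = FALSE) {
  stopifnot(n_candidates >= 1)
  best <- NULL
  for (i in seq_len(n_candidates)) {
    s <- random_scheme(probe_counts, seed = seed + i - 1L,
                       forbid_adjacent_repeat = forbid_adjacent_repeat)
    sc <- scheme_score(s)
    if (is.null(best) ||
        sc$min_pairwise > best$score$min_pairwise ||
        (sc$min_pairwise == best$score$min_pairwise &&
         sc$sum_pairwise > best$score$sum_pairwise)) {
      s$score <- sc
      s$candidate_index <- i
      best <- s
    }
  }
  best
}

#' @export
print.scheme <- function(x, ...) {
  cat("<banding scheme: ", length(x$patterns), " chromosomes",
      if (!is.null(x$seed)) paste0(", seed ", x$seed),
      if (!is.null(x$score)) paste0(", min/sum pairwise ",
                                    x$score$min_pairwise, "/",
                                    x$score$sum_pairwise),
      ">\n", sep = "")
  invisible(x)
}

#' Read/write schemes as JSON or TSV
#'
#' JSON stores patterns, seed and score; TSV stores one row per band
#' (`chrom`, `band_rank`, `token`).
#'
#' @param scheme a `scheme`.
#' @param path output/input file.
#' @return `write_scheme*`: invisibly the path; `read_scheme_json`: a
#'   `scheme`.
#' @export
write_scheme_json <- function(scheme, path) {
  jsonlite::write_json(
    list(patterns = scheme$patterns, seed = scheme$seed,
         score = scheme$score),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(patterns = as.list(x$patterns), seed = x$seed,
                 score = x$score),
            class = "scheme")
}

#' @rdname write_scheme_json
#' @export
write_scheme_tsv <- function(scheme, path) {
  rows <- data.table::rbindlist(lapply(names(scheme$patterns), function(ch) {
    data.table::data.table(chrom = ch,
                           band_rank = seq_along(scheme$patterns[[ch]]),
                           token = scheme$patterns[[ch]])
  }))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}
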