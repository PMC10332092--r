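signal_multiset <- function(prov_list) {
  rows <- do.call(rbind, prov_list)
  rows <- rows[rows$donor != "?", , drop = FALSE]
  key <- paste(rows$donor, rows$rank, sep = ":")
  tab <- table(key)
  data.frame(key = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

multiset_equal <- function(a, b) {
  a <- a[order(a$key), ]; b <- b[order(b$key), ]
  nrow(a) == nrow(b) && all(a$key == b$key) && all(a$count == b$count)
}

multiset_distance <- function(a, b) {
  keys <- union(a$key, b$key)
  ca <- a$count[match(keys, a$key)]; ca[is.na(ca)] <- 0L
  cb <- b$count[match(keys, b$key)]; cb[is.na(cb)] <- 0L
  sum(abs(ca - cb))
}

#' Enumerate 2:2 meiotic segregation products of a reciprocal translocation
#'
#' In a reciprocal-translocation heterozygote the two normal chromosomes
#' (A, B) and the two derivatives (derA, derB) pair as a quadrivalent at
#' meiosis I. The six 2-chromosome subsets are the 2:2 segregation
#' products: alternate ({A,B} and {derA,derB}; balanced), adjacent-I
#' ({A,derB}, {derA,B}; one derivative plus the other pair's normal) and
#' adjacent-II ({A,derA}, {B,derB}; both centromeres of one pair). 3:1 and
#' 4:0 segregations are out of model. Each class carries the expected
#' probe-signal multiset, keyed by `(donor chromosome, band rank)`.
#'
#' @param patternA,patternB reference token vectors of the two donors.
#' @param r a reciprocal [rearrangement()] giving the two gap indices.
#' @param chromA,chromB donor chromosome ids (defaults from `r`).
#' @return List of 6 `gamete_class` objects: `label`, `chromosomes`,
#'   `balanced`, `expected_signals` (key/count data.frame).
#' @export
enumerate_2_2_segregation <- function(patternA, patternB, r,
                                      chromA = r$donors[1L],
                                      chromB = r$donors[2L]) {
  if (r$type != "rcp") {
    stop("oligoband_error_segregation: 2:2 quadrivalent segregation needs ",
         "a reciprocal rearrangement, got ", r$type, call. = FALSE)
  }
  ka <- r$gaps[1L]; kb <- r$gaps[2L]
  check_gap(ka, length(patternA), chromA)
  check_gap(kb, length(patternB), chromB)
  provA <- data.frame(donor = chromA, rank = seq_along(patternA),
                      stringsAsFactors = FALSE)
  provB <- data.frame(donor = chromB, rank = seq_along(patternB),
                      stringsAsFactors = FALSE)
  derA <- rbind(provA[seq_len(ka), , drop = FALSE],
                provB[setdiff(seq_along(patternB), seq_len(kb)), ,
                      drop = FALSE])
  derB <- rbind(provB[seq_len(kb), , drop = FALSE],
                provA[setdiff(seq_along(patternA), seq_len(ka)), ,
                      drop = FALSE])
  members <- list(A = provA, B = provB, derA = derA, derB = derB)
  full <- signal_multiset(list(provA, provB))
  labels <- list(
    alternate_normal = c("A", "B"),
    alternate_translocated = c("derA", "derB"),
    adjacent_I_a = c("A", "derB"),
    adjacent_I_b = c("derA", "B"),
    adjacent_II_a = c("A", "derA"),
    adjacent_II_b = c("B", "derB"))
  lapply(names(labels), function(lb) {
    pair <- labels[[lb]]
    ms <- signal_multiset(members[pair])
    structure(list(label = lb, chromosomes = pair,
                   balanced = multiset_equal(ms, full),
                   expected_signals = ms),
              class = "gamete_class")
  })
}

#' Classify an observed sperm-head signal multiset
#'
#' Assigns the nearest gamete class by total absolute difference of signal
#' counts. When two or more classes tie at the minimum: if all tied classes
#' have identical expected multisets and are balanced (the alternate-normal
#' vs alternate-translocated pair is indistinguishable at probe
#' granularity), the merged label `"balanced"` is returned; otherwise
#' `"ambiguous"`. Distances above `tolerance` are also `"ambiguous"`.
#' A nonzero distance within tolerance flags a probable decondensation
#' artefact.
#'
#' @param observed data.frame with `key` (`donor:rank`) and `count`, or a
#'   character vector of keys (one per observed signal).
#' @param classes output of [enumerate_2_2_segregation()].
#' @param tolerance maximal multiset difference accepted, default 1.
#' @return List with `label`, `distance`, `artefact_flag`.
#' @export
classify_sperm_signals <- function(observed, classes, tolerance = 1) {
  if (is.character(observed)) {
    tab <- table(observed)
    observed <- data.frame(key = names(tab), count = as.integer(tab),
                           stringsAsFactors = FALSE)
  }
  d <- vapply(classes, function(cl) {
    multiset_distance(observed, cl$expected_signals)
  }, numeric(1))
  dmin <- min(d)
  hits <- which(d == dmin)
  if (dmin > tolerance) {
    return(list(label = "ambiguous", distance = dmin,
                artefact_flag = FALSE))
  }
  if (length(hits) > 1L) {
    same <- all(vapply(hits[-1L], function(h) {
      multiset_equal(classes[[h]]$expected_signals,
                     classes[[hits[1L]]]$expected_signals)
    }, logical(1)))
    bal <- all(vapply(hits, function(h) classes[[h]]$balanced, logical(1)))
    if (same && bal) {
      return(list(label = "balanced", distance = dmin,
                  artefact_flag = dmin > 0))
    }
    return(list(label = "ambiguous", distance = dmin,
                artefact_flag = dmin > 0))
  }
  list(label = classes[[hits]]$label, distance = dmin,
       artefact_flag = dmin > 0)
}

#' Export gamete classes as a TSV table
#'
#' @param classes output of [enumerate_2_2_segregation()].
#' @param path output TSV.
#' @return Invisibly the path.
#' @export
write_gamete_classes <- function(classes, path) {
  rows <- data.table::rbindlist(lapply(classes, function(cl) {
    data.table::data.table(label = cl$label,
                           chromosomes = paste(cl$chromosomes,
                                               collapse = "+"),
                           balanced = cl$balanced,
                           signal = cl$expected_signals$key,
                           count = cl$expected_signals$count)
  }))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}
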