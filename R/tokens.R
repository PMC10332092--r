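#' The six-colour banding alphabet
#'
#' Oligo-banding colours each probe with one of three fluorophores (6-FAM,
#' ATTO 550, ATTO 647N) used singly, or with one of the three possible pairs,
#' yielding a six-token alphabet. Tokens are canonical short strings; paired
#' tokens join the two fluorophore codes with `"+"` in the fixed order
#' FAM < A550 < A647.
#'
#' @return Character vector of the six canonical colour tokens.
#' @export
#' @examples
#' colour_tokens()
colour_tokens <- function() {
  c("FAM", "A550", "A647", "FAM+A550", "FAM+A647", "A550+A647")
}

#' @rdname colour_tokens
#' @export
fluorophores <- function() c("FAM", "A550", "A647")

#' Build a colour token from a set of fluorophores
#'
#' @param fluors character vector of 1 or 2 fluorophore codes from
#'   `fluorophores()`.
#' @return A canonical colour token string.
#' @export
make_token <- function(fluors) {
  fl <- fluorophores()
  fluors <- unique(fluors)
  if (!all(fluors %in% fl)) {
    stop("oligoband_error_token: unknown fluorophore(s): ",
         paste(setdiff(fluors, fl), collapse = ", "), call. = FALSE)
  }
  if (!length(fluors) %in% 1:2) {
    stop("oligoband_error_token: a colour token uses 1 or 2 fluorophores, got ",
         length(fluors), call. = FALSE)
  }
  paste(fl[fl %in% fluors], collapse = "+")
}

#' Fluorophores making up a colour token
#'
#' @param token a canonical colour token.
#' @return Character vector of 1 or 2 fluorophore codes.
#' @export
token_fluors <- function(token) {
  stopifnot(length(token) == 1L)
  if (!token %in% colour_tokens()) {
    stop("oligoband_error_token: not a valid colour token: ", token,
         call. = FALSE)
  }
  strsplit(token, "+", fixed = TRUE)[[1L]]
}

#' Is a token a two-fluorophore (paired) colour?
#' @param token a canonical colour token.
#' @return Logical scalar.
#' @export
is_paired_token <- function(token) length(token_fluors(token)) == 2L

# Integer encoding of token sequences for the C-level edit distance.
# Unknown tokens get fresh codes past the alphabet so distances still work
# on arbitrary labels (used by the test oracles).
tokens_to_int <- function(tokens, alphabet = colour_tokens()) {
  if (length(tokens) == 0L) return(integer(0))
  idx <- match(tokens, alphabet)
  if (anyNA(idx)) {
    extra <- unique(tokens[is.na(idx)])
    idx[is.na(idx)] <- length(alphabet) + match(tokens[is.na(idx)], extra)
  }
  as.integer(idx)
}
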