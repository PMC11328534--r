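#' Generate one-edit spelling variants of a surface
#'
#' Clinical notes carry one-letter typos ("trimethoprim" written for the
#' drug "trimetoprim"). Variants are produced by exactly one
#' single-character substitution or one single-character insertion; every
#' variant is at Levenshtein distance 1 from the input. Deletions are not
#' generated by default because typos of interest modify or add a letter;
#' set `ops = c("substitution", "insertion", "deletion")` for classical
#' distance-1 neighbourhoods.
#'
#' @param surface Non-empty string (lowercase surfaces expected).
#' @param alphabet Character vector of single characters to substitute or
#'   insert; defaults to the 26 lowercase ASCII letters.
#' @param ops Edit operations to apply; any subset of `"substitution"`,
#'   `"insertion"`, `"deletion"`.
#' @return Character vector of unique variants, the original excluded.
#' @examples
#' "trimethoprim" %in% expand_one_edit_variants("trimetoprim")
#' @export
expand_one_edit_variants <- function(surface,
                                     alphabet = letters,
                                     ops = c("substitution", "insertion")) {
  stopifnot(is.character(surface), length(surface) == 1, nzchar(surface))
  if (length(alphabet) == 0) stop("empty alphabet", call. = FALSE)
  ops <- match.arg(ops, c("substitution", "insertion", "deletion"),
                   several.ok = TRUE)
  n <- nchar(surface)
  out <- character(0)
  if ("substitution" %in% ops) {
    for (i in seq_len(n)) {
      out <- c(out, paste0(
        substr(surface, 1, i - 1), alphabet, substr(surface, i + 1, n)
      ))
    }
  }
  if ("insertion" %in% ops) {
    for (i in 0:n) {
      out <- c(out, paste0(
        substr(surface, 1, i), alphabet, substr(surface, i + 1, n)
      ))
    }
  }
  if ("deletion" %in% ops) {
    for (i in seq_len(n)) {
      out <- c(out, paste0(substr(surface, 1, i - 1), substr(surface, i + 1, n)))
    }
  }
  setdiff(unique(out), surface)
}

# TRUE where token is reachable from surface by exactly one substitution or
# one insertion (the variant generator's operation set); deletion is
# assigned a blocking cost so "amoxicilin" does not match "amoxicilline".
one_edit_match <- function(surface, tokens,
                           ops = c("substitution", "insertion")) {
  costs <- list(insertions = 1L, deletions = 1000L, substitutions = 1L)
  if ("deletion" %in% ops) costs$deletions <- 1L
  d <- utils::adist(surface, tokens, costs = costs)[1, ]
  len_ok <- nchar(tokens) >= nchar(surface) - ("deletion" %in% ops)
  d == 1L & len_ok & tokens != surface
}
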