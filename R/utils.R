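`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a classed condition
#' @noRd
pcmc_abort <- function(msg, class) {
  stop(structure(class = c(class, "pcmc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "pcmc_invalid") {
  if (!isTRUE(ok)) pcmc_abort(msg, class)
  invisible(TRUE)
}

#' Canonical unordered dyad key
#' @noRd
dyad_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

dyad_split <- function(key) {
  parts <- strsplit(key, "\r", fixed = TRUE)
  data.frame(id_a = vapply(parts, `[`, "", 1L),
             id_b = vapply(parts, `[`, "", 2L))
}

#' Empty data frame with prescribed columns
#' @noRd
empty_df <- function(proto) {
  as.data.frame(lapply(proto, function(f) vector(f, 0L)),
                stringsAsFactors = FALSE)
}

#' Normalize a probability vector, guarding against printed rounding
#' @noRd
normalize_probs <- function(p) {
  assert_that(all(p >= 0) && sum(p) > 0, "probabilities must be nonnegative")
  p / sum(p)
}

#' Derive a stream seed from a master seed (kept below 2^31)
#' @noRd
substream_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147480000L
}
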