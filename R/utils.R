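# Internal helpers shared across modules.

abort_hrmelt <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("hrmelt_", class), "hrmelt_error"), ...)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed report tables use conventional
#' half-up rounding, so percentages such as 30/279 = 10.7527 print as 10.75
#' (two decimals) and 10.8 (one decimal).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 10.75), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Reverse complement of plain character DNA (A/C/G/T/N/-).
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Character matrix (records x columns) from equal-length sequences.
seq_matrix <- function(sequences) {
  if (length(sequences) == 0) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  t(vapply(
    strsplit(toupper(sequences), "", fixed = TRUE),
    identity,
    character(nchar(sequences[[1]]))
  ))
}

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")
MISSING_STATES <- c("N", "-")

# Hamming distance ignoring columns where either sequence has N or a gap.
hamming_distance <- function(a, b) {
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(va) != length(vb)) {
    abort_hrmelt("sequences must have equal length", "input_error")
  }
  keep <- !(va %in% MISSING_STATES) & !(vb %in% MISSING_STATES)
  sum(va[keep] != vb[keep])
}
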