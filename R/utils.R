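# internal helpers shared across modules

IOB_TAGSET <- c("O", "B-LIVER", "I-LIVER")
LIVER_TAGS <- c("B-LIVER", "I-LIVER")

#' Round half up for presentation
#'
#' Tables in regulatory reporting conventionally round half up; R's
#' `round()` rounds half to even. Stored metric values are kept at full
#' precision and only rounded with this helper at presentation time.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# normalize internal whitespace and trim; used for dedup and matching
squish <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_prob <- function(x, lo = 0, hi = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo && x <= hi
}

# run expr under a fixed RNG seed, restoring caller RNG state afterwards
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
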