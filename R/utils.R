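# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; reported percentages here use
#' the conventional half-up rule (76.85 -> 76.9).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to \code{digits} places.
#' @keywords internal
roundHalfUp <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage at one decimal place, half-up
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places (default 1).
#' @return percentage on the 0--100 scale, or \code{NA_real_} when the
#'   denominator is zero.
#' @export
#' @examples
#' pctHalfUp(823, 1071)   # 76.8
#' pctHalfUp(91, 101)     # 90.1
pctHalfUp <- function(num, den, digits = 1) {
  if (length(den) == 1L && den == 0) return(NA_real_)
  out <- roundHalfUp(100 * num / den, digits)
  out[den == 0] <- NA_real_
  out
}

# SHA-256 of files via the system binary; returns named character vector.
fileSha256 <- function(paths) {
  stopifnot(all(file.exists(paths)))
  out <- vapply(paths, function(p) {
    res <- system2("sha256sum", shQuote(p), stdout = TRUE)
    strsplit(res, " ")[[1]][1]
  }, character(1))
  names(out) <- basename(paths)
  out
}

# Derive a per-stage seed from the global seed so adding a stage does not
# shift the random streams of the others. Kept below 2^31 - 1.
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == floor(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587)
}

# Integer-ish scalar check used by constructors.
isCount <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

isProb <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}
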