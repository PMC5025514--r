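# shared internal helpers

#' Round half away from zero
#'
#' Base R rounds half to even; reported map-density statistics use the
#' conventional half-up rounding at two decimals, so this is exposed for
#' reproducibility of printed tables.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded half-up
#' @export
#' @examples
#' roundHalfUp(c(0.125, 11.985), 2)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertScalarIn <- function(x, choices, what) {
  if (length(x) != 1L || !x %in% choices)
    stop(what, " must be one of: ", paste(choices, collapse = ", "),
         call. = FALSE)
  x
}

.isProb <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)

# sorted two-allele key, e.g. "A/T"
.allelePair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "/")
}

.TRANSITIONS <- c("A/G", "C/T")
.AT_CG <- c("A/T", "C/G")
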