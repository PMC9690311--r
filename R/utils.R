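# Shared numeric helpers.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all displayed percentages, in
#' contrast to [round()]'s round-half-to-even. Only ever applied to
#' non-negative percentages here, but implemented symmetrically.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)      # 1, where round(0.5) is 0
#' round_half_up(18.75, 1) # 18.8
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# kJ per kcal (thermochemical calorie, the labelling convention)
KJ_PER_KCAL <- 4.184

`%||%` <- function(x, y) if (is.null(x)) y else x

is_flag01 <- function(x) is.numeric(x) & !is.na(x) & x %in% c(0, 1)

stop_nc <- function(...) stop(..., call. = FALSE)
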