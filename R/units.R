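#' Unit conversion helpers
#'
#' All internal computation is in SI (m, s, kg, K). These converters live at
#' the I/O boundary so that bench units (ml/min, mg/ml, cm2, mm, minutes)
#' never leak into the model equations.
#'
#' @param x numeric vector in the source unit.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
ml_min_to_m3_s <- function(x) x * 1e-6 / 60

#' @rdname units
#' @export
ml_to_m3 <- function(x) x * 1e-6

#' @rdname units
#' @export
mg_ml_to_kg_m3 <- function(x) x            # mg/ml == kg/m3

#' @rdname units
#' @export
min_to_s <- function(x) x * 60

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
cm2_to_m2 <- function(x) x * 1e-4

#' @rdname units
#' @export
celsius_to_kelvin <- function(x) x + 273.15

# mPa.s (the tabulated unit) equals cP; Wilke-Chang wants cP.
mPa_s_to_cP <- function(x) x

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be a positive finite number", name), call. = FALSE)
  }
  invisible(x)
}
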