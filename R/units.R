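# Internal units are K, mol/L and kcal; file and figure interfaces use degC,
# mM and uM and convert at the boundary.

#' Gas constant in kcal mol-1 K-1
#'
#' @return The molar gas constant, 1.9872e-3 kcal mol-1 K-1.
#' @export
gas_constant <- function() 1.9872e-3

#' Temperature and concentration unit conversions
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname units
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' @rdname units
#' @export
mM_to_M <- function(x) x * 1e-3

#' @rdname units
#' @export
uM_to_M <- function(x) x * 1e-6

stop_domain <- function(field, value) {
  stop(sprintf("invalid value for '%s': %s", field,
               paste(format(value), collapse = ", ")), call. = FALSE)
}
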