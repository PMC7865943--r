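#' Convert air-pressure sensor voltage to pressure
#'
#' The airbag pressure module outputs a voltage `b` in the range
#' 0.5--4.5 V that maps linearly onto 0--40 kPa: `a = (b - 0.5) * 10`.
#' Values outside the sensor's stated voltage range are converted anyway
#' but trigger a warning, since they indicate saturation or a wiring fault.
#'
#' @param voltage numeric vector of sensor voltages in volts.
#' @return numeric vector of pressures in kPa.
#' @examples
#' voltage_to_pressure(c(0.5, 2.5, 4.5))  # 0, 20, 40 kPa
#' @export
voltage_to_pressure <- function(voltage) {
  if (!is.numeric(voltage)) stop("voltage must be numeric", call. = FALSE)
  if (any(!is.finite(voltage))) stop("voltage must be finite", call. = FALSE)
  out_of_range <- voltage < 0.5 | voltage > 4.5
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " voltage value(s) outside the sensor range [0.5, 4.5] V",
            call. = FALSE)
  }
  (voltage - 0.5) * 10
}
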