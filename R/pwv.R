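#' Configuration for the Zc-to-PWV conversion
#'
#' The water-hammer relation `Zc = rho * PWV / A` links the characteristic
#' impedance of the proximal aorta to the pulse wave velocity through the
#' blood density and the aortic cross-sectional area. The area model is a
#' simple anthropometric stand-in — a diameter of 28 mm for a 45-year-old
#' man, growing 0.05 mm per year of age and 2 mm smaller in women — and is
#' fully swappable through this configuration object.
#'
#' @param rho blood density (kg/m^3).
#' @param area_model function `(age, sex)` returning the aortic
#'   cross-sectional area in m^2; `sex` is `"male"` or `"female"`.
#' @return A list with `rho`, `area_model`, and the unit conversion
#'   constant from mmHg·s/ml to Pa·s/m^3.
#' @export
pwv_config <- function(rho = 1050,
                       area_model = default_aortic_area) {
  if (!is.finite(rho) || rho <= 0) validation_error("rho must be positive")
  list(rho = rho, area_model = area_model,
       mmhg_s_ml_to_si = 133.322 * 1e6)
}

#' @rdname pwv_config
#' @param age age in years.
#' @param sex `"male"` or `"female"`.
#' @export
default_aortic_area <- function(age, sex) {
  d_mm <- 28 + 0.05 * (age - 45) - 2 * (sex == "female")
  pi * (d_mm / 2000)^2
}

#' Pulse wave velocity from the characteristic impedance
#'
#' Converts a fitted characteristic impedance to an aortic pulse wave
#' velocity via the water-hammer relation `PWV = Zc_SI * A(age, sex) / rho`,
#' with `Zc_SI = Zc * 133.322e6` Pa·s/m^3 per mmHg·s/ml.
#'
#' @param zc characteristic impedance (mmHg·s/ml), positive.
#' @param age age in years (enters the area model).
#' @param sex `"male"` or `"female"`.
#' @param cfg a [pwv_config()].
#' @return PWV in m/s.
#' @export
pwv_from_zc <- function(zc, age, sex, cfg = pwv_config()) {
  if (!is.finite(zc) || zc < 0) validation_error("Zc must be non-negative")
  a <- cfg$area_model(age, sex)
  if (!all(is.finite(a)) || any(a <= 0))
    validation_error("area model returned a non-positive area")
  zc * cfg$mmhg_s_ml_to_si * a / cfg$rho
}
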