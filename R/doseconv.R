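#' Monitor calibration factor K(E)
#'
#' Number of particles per monitor unit from a plateau dose measurement:
#' K = D_meas * A / (S_Ex * MU). Unit bookkeeping: D in Gy (J/kg), A in
#' cm^2, S in MeV cm^2/g gives Gy g / MeV per MU; with 1 MeV =
#' 1.602176634e-13 J and 1 Gy g = 1e-3 J, the factor to particles/MU is
#' 1e-3 / 1.602176634e-13 = 6.2415e9. This product arrangement is the only
#' dimensionally consistent reading of the calibration relation.
#'
#' @param D_meas Measured dose in the plateau, Gy (> 0).
#' @param S_Ex Mass stopping power at the measurement depth, MeV cm^2/g
#'   (> 0).
#' @param MU Monitor units delivered (> 0).
#' @param A Homogeneously irradiated area, cm^2 (> 0).
#' @return Particles per monitor unit.
#' @examples
#' monitor_calibration(1, 1, 1, 1) # 6.2415e9
#' @export
monitor_calibration <- function(D_meas, S_Ex, MU, A) {
  for (v in list(D_meas = D_meas, S_Ex = S_Ex, MU = MU, A = A)) {
    if (!is.numeric(v) || any(v <= 0)) {
      stop("all calibration inputs must be strictly positive", call. = FALSE)
    }
  }
  mev_per_joule <- 1 / 1.602176634e-13
  (D_meas * 1e-3) * A / (S_Ex * MU) * mev_per_joule
}

#' Air-density (temperature-pressure) correction
#'
#' Standard open-chamber correction k_TP = (273.2 + T)/(273.2 + T0) *
#' (P0 / P), unity at reference conditions.
#'
#' @param temperature Air temperature in degrees C (> -273.2).
#' @param pressure Air pressure in hPa (> 0).
#' @param T0,P0 Reference conditions (defaults 20 C, 1013.25 hPa).
#' @return Dimensionless correction factor.
#' @examples
#' k_tp(20, 1013.25) # 1
#' k_tp(25, 1013.25) # 1.01705
#' @export
k_tp <- function(temperature, pressure, T0 = 20, P0 = 1013.25) {
  stopifnot(temperature > -273.2, pressure > 0)
  (273.2 + temperature) / (273.2 + T0) * (P0 / pressure)
}

#' Carbon/Co-60 beam-quality factor K_Q
#'
#' K_Q = \[(w/e)_C12 * s_w,air(carbon)\] / \[(w/e)_Co60 *
#' (L/rho)_w,air(Co-60)\]: the ratio of the effective w value for carbon
#' ions (including fragments) times the carbon water/air stopping-power
#' ratio to the Co-60 w value times the Spencer-Attix restricted ratio.
#' All four physics inputs are user-supplied literature values; none is
#' bundled as authoritative.
#'
#' @param we_c12 Effective w/e for carbon including fragments, J/C (> 0).
#' @param we_co60 w/e for Co-60, J/C (> 0).
#' @param spr_carbon Water/air mass stopping-power ratio for carbon (> 0).
#' @param spr_co60 Restricted (Spencer-Attix) water/air ratio for Co-60
#'   (> 0).
#' @return Dimensionless K_Q.
#' @examples
#' beam_quality_kq(34.5, 33.97, 1.13, 1.133) # 1.0129
#' @export
beam_quality_kq <- function(we_c12, we_co60, spr_carbon, spr_co60) {
  stopifnot(we_c12 > 0, we_co60 > 0, spr_carbon > 0, spr_co60 > 0)
  (we_c12 * spr_carbon) / (we_co60 * spr_co60)
}

#' Absorbed dose to water at the effective point of measurement
#'
#' D_w(P_eff) = M_corr * N_w,Co-60 * K_Q, optionally times an explicit
#' k_TP factor for charge not already corrected to laboratory conditions
#' (whether the raw charge includes the air-density correction is a
#' protocol choice, so the factor is exposed rather than hidden).
#'
#' @param M_corr Measured charge, C (> 0).
#' @param N_w_co60 Absorbed-dose-to-water calibration factor for Co-60,
#'   Gy/C (> 0).
#' @param K_Q Beam-quality factor, see [beam_quality_kq()] (> 0).
#' @param k_tp Air-density correction (default 1, i.e. M_corr already
#'   corrected).
#' @return Absorbed dose to water in Gy.
#' @examples
#' absorbed_dose_peff(20e-9, 5.4e7, 1.0125) # 1.0935
#' @export
absorbed_dose_peff <- function(M_corr, N_w_co60, K_Q, k_tp = 1) {
  stopifnot(M_corr > 0, N_w_co60 > 0, K_Q > 0, k_tp > 0)
  M_corr * k_tp * N_w_co60 * K_Q
}
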