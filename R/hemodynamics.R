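#' Distensibility between diastolic and systolic states
#'
#' Diameter-based distensibility coefficient: the normalized change in
#' arterial diameter from end-diastole to end-systole divided by the change
#' in pressure,
#' \deqn{D = \frac{(d_{sys} - d_{dias})/d_{dias}}{P_{sys} - P_{dias}}}
#' in Pa^-1.  Note that area-based conventions
#' (\eqn{D_A = \Delta A/(A \Delta P)}) are about a factor 2 larger for
#' small pulses; \code{basis = "area"} computes
#' \eqn{(d_{sys}^2 - d_{dias}^2)/(d_{dias}^2 \Delta P)}, the form under
#' which the Bramwell-Hill and Moens-Korteweg velocities coincide.
#'
#' @param d_dias,d_sys outer diameters (um) at end-diastolic and
#'   end-systolic pressure.
#' @param P_dias_mmHg,P_sys_mmHg pressures (mmHg); defaults 5 and 25, the
#'   diastolic and systolic evaluation pressures.
#' @param basis \code{"diameter"} (default, as reported) or \code{"area"}.
#' @return distensibility D in Pa^-1.
#' @export
distensibility <- function(d_dias, d_sys, P_dias_mmHg = 5, P_sys_mmHg = 25,
                           basis = c("diameter", "area")) {
  basis <- match.arg(basis)
  stopifnot(d_dias > 0, d_sys >= d_dias)
  if (P_sys_mmHg <= P_dias_mmHg)
    stop("systolic pressure must exceed diastolic pressure")
  dP <- mmHg_to_Pa(P_sys_mmHg - P_dias_mmHg)
  if (basis == "diameter") (d_sys - d_dias) / d_dias / dP
  else (d_sys^2 - d_dias^2) / d_dias^2 / dP
}

#' Bramwell-Hill pulse wave velocity
#'
#' \deqn{PWV = \sqrt{1/(\rho D)}}
#' with \eqn{\rho} the mass density of the contained fluid (blood,
#' approximately 1050 kg/m^3) and D the distensibility coefficient.
#'
#' @param D distensibility (Pa^-1), > 0.
#' @param rho_kg_m3 fluid mass density (kg/m^3).
#' @return pulse wave velocity in m/s.
#' @export
pwv <- function(D, rho_kg_m3 = 1050) {
  if (any(D <= 0)) stop("distensibility must be positive")
  if (any(rho_kg_m3 <= 0)) stop("fluid density must be positive")
  sqrt(1 / (rho_kg_m3 * D))
}

#' Model-predicted distensibility and PWV for a fitted vessel
#'
#' Solves the inflation equilibrium at the diastolic and systolic pressures
#' (at the in vivo axial stretch) for the model-predicted outer diameters,
#' then applies \code{\link{distensibility}} and \code{\link{pwv}}.
#'
#' @param params,geom fitted parameters and unloaded geometry.
#' @param P_dias_mmHg,P_sys_mmHg evaluation pressures (mmHg).
#' @param rho_kg_m3 blood density.
#' @param lambda_z axial stretch; defaults to \code{geom$lambda_z_iv}.
#' @param basis distensibility convention, see \code{\link{distensibility}}.
#' @return list with \code{d_dias_um}, \code{d_sys_um}, \code{D_Pa_inv},
#'   \code{PWV_m_per_s}.
#' @export
model_pwv <- function(params, geom, P_dias_mmHg = 5, P_sys_mmHg = 25,
                      rho_kg_m3 = 1050, lambda_z = geom$lambda_z_iv,
                      basis = "diameter") {
  if (is.null(lambda_z))
    stop("axial stretch not given and geometry has no lambda_z_iv")
  lt <- solve_circ_stretch(mmHg_to_Pa(c(P_dias_mmHg, P_sys_mmHg)),
                           lambda_z, params, geom)
  r <- radii_from_stretches(lt, lambda_z, geom)
  d <- 2 * r$r_o_um
  D <- distensibility(d[1], d[2], P_dias_mmHg, P_sys_mmHg, basis = basis)
  list(d_dias_um = d[1], d_sys_um = d[2], D_Pa_inv = D,
       PWV_m_per_s = pwv(D, rho_kg_m3))
}

#' Moens-Korteweg pulse wave velocity of a thin elastic tube
#'
#' Closed-form reference \eqn{\sqrt{E h / (2 \rho r)}} for a thin-walled
#' linearly elastic tube, used as the limit check on the Bramwell-Hill
#' computation.
#'
#' @param E_Pa incremental Young's modulus (Pa).
#' @param h_m wall thickness (m).
#' @param r_m lumen radius (m).
#' @param rho_kg_m3 fluid density.
#' @return wave speed in m/s.
#' @export
moens_korteweg <- function(E_Pa, h_m, r_m, rho_kg_m3 = 1050) {
  sqrt(E_Pa * h_m / (2 * rho_kg_m3 * r_m))
}
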