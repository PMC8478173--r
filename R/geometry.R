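#' Unloaded (traction-free) vessel geometry
#'
#' The excised, traction-free configuration defines the reference state for
#' all kinematics: stretches are 1 there by definition.  The unloaded wall
#' volume \eqn{\bar V = \pi L (OD^2 - ID^2)/4} with \eqn{ID = OD - 2H} is
#' conserved under loading (incompressibility) and is what ties loaded outer
#' radius measurements to the unmeasurable loaded inner radius.
#'
#' @param L_um unloaded length between ligatures (micrometres).
#' @param OD_um unloaded outer diameter (micrometres).
#' @param H_um unloaded wall thickness (micrometres); must satisfy
#'   \code{0 < H < OD/2}.
#' @param lambda_z_iv optional vessel-specific in vivo axial stretch
#'   (dimensionless), carried along for downstream analyses.
#' @return An object of class \code{"unloaded_geometry"}: a list with the
#'   inputs plus derived \code{ID_um}, \code{V_um3} (wall volume) and
#'   \code{rho_mid_um} (unloaded mid-wall radius \eqn{(OD + ID)/4}).
#' @examples
#' g <- unloaded_geometry(L_um = 4000, OD_um = 900, H_um = 60)
#' g$rho_mid_um
#' @export
unloaded_geometry <- function(L_um, OD_um, H_um, lambda_z_iv = NULL) {
  stopifnot(is.numeric(L_um), is.numeric(OD_um), is.numeric(H_um),
            length(L_um) == 1, length(OD_um) == 1, length(H_um) == 1)
  if (L_um <= 0) stop("unloaded length must be positive")
  if (OD_um <= 0) stop("unloaded outer diameter must be positive")
  if (H_um <= 0 || H_um >= OD_um / 2)
    stop("wall thickness must satisfy 0 < H < OD/2")
  ID_um <- OD_um - 2 * H_um
  structure(list(
    L_um = L_um, OD_um = OD_um, H_um = H_um, ID_um = ID_um,
    V_um3 = pi * L_um * (OD_um^2 - ID_um^2) / 4,
    rho_mid_um = (OD_um + ID_um) / 4,
    lambda_z_iv = lambda_z_iv
  ), class = "unloaded_geometry")
}

#' @export
print.unloaded_geometry <- function(x, ...) {
  cat("Unloaded vessel geometry\n")
  cat(sprintf("  L = %.1f um, OD = %.1f um, H = %.1f um (ID = %.1f um)\n",
              x$L_um, x$OD_um, x$H_um, x$ID_um))
  cat(sprintf("  wall volume = %.4g um^3, mid-wall radius = %.2f um\n",
              x$V_um3, x$rho_mid_um))
  if (!is.null(x$lambda_z_iv))
    cat(sprintf("  in vivo axial stretch = %.3f\n", x$lambda_z_iv))
  invisible(x)
}

#' Loaded inner radius from incompressibility
#'
#' Wall volume is conserved, so \eqn{\pi l (r_o^2 - r_i^2) = \bar V} gives
#' \eqn{r_i = \sqrt{r_o^2 - \bar V/(\pi l)}}.  Any consistent length unit
#' may be used for all three arguments.
#'
#' @param r_o loaded outer radius.
#' @param l loaded axial length between ligatures.
#' @param V unloaded wall volume (cubed length unit).
#' @return loaded inner radius, same unit as \code{r_o}.
#' @export
inner_radius <- function(r_o, l, V) {
  stopifnot(all(r_o > 0), all(l > 0), all(V >= 0))
  if (any(V >= pi * r_o^2 * l))
    stop("infeasible geometry: wall volume exceeds enclosed cylinder volume")
  sqrt(r_o^2 - V / (pi * l))
}

#' Mean circumferential and axial stretch
#'
#' \eqn{\lambda_\theta = (r_i + r_o)/(2\rho_{mid})} (loaded mid-wall radius
#' over unloaded mid-wall radius) and \eqn{\lambda_z = l/L}.
#'
#' @param r_i,r_o loaded inner and outer radii (micrometres).
#' @param l loaded length (micrometres).
#' @param geom an \code{\link{unloaded_geometry}}.
#' @return named numeric vector \code{c(lambda_theta, lambda_z)}.
#' @export
stretches <- function(r_i, r_o, l, geom) {
  stopifnot(inherits(geom, "unloaded_geometry"))
  if (any(r_i >= r_o)) stop("require r_i < r_o")
  if (any(l <= 0)) stop("loaded length must be positive")
  c(lambda_theta = unname((r_i + r_o) / (2 * geom$rho_mid_um)),
    lambda_z = unname(l / geom$L_um))
}

#' Mean (thin-wall) Cauchy stresses under inflation-extension
#'
#' The 2-D mean-stress formulation for a pressurized, axially loaded
#' cylindrical vessel:
#' \deqn{\sigma_\theta = \frac{P r_i}{r_o - r_i}, \qquad
#'       \sigma_z = \frac{f_T + P \pi r_i^2}{\pi (r_o^2 - r_i^2)},}
#' where \eqn{f_T} is the axial force read by the transducer (the
#' pressure-on-cap term \eqn{P \pi r_i^2} is added back).  All inputs SI.
#'
#' @param P transmural pressure (Pa).
#' @param f_T transducer axial force (N).
#' @param r_i,r_o loaded inner/outer radii (m).
#' @return named numeric vector \code{c(sigma_theta, sigma_z)} in Pa.
#' @export
mean_stresses <- function(P, f_T, r_i, r_o) {
  if (any(r_o <= r_i) || any(r_i <= 0))
    stop("degenerate wall: require r_o > r_i > 0")
  c(sigma_theta = unname(P * r_i / (r_o - r_i)),
    sigma_z = unname((f_T + P * pi * r_i^2) / (pi * (r_o^2 - r_i^2))))
}

#' Derive kinematics and stresses for a table of biaxial records
#'
#' Takes raw biaxial records in lab units and appends the derived loaded
#' inner radius (incompressibility), loaded wall thickness, mean stretches
#' and mean Cauchy stresses.  Loaded wall thickness is always computed, never
#' measured.
#'
#' @param data data.frame with columns \code{pressure_mmHg},
#'   \code{outer_diameter_um}, \code{axial_length_um}, \code{axial_force_mN}
#'   (extra columns such as \code{protocol_id} are preserved).
#' @param geom an \code{\link{unloaded_geometry}}.
#' @return the input data.frame with columns \code{inner_radius_um},
#'   \code{wall_thickness_um}, \code{lambda_theta}, \code{lambda_z},
#'   \code{sigma_theta_kPa}, \code{sigma_z_kPa} appended.
#' @export
derive_kinematics <- function(data, geom) {
  stopifnot(inherits(geom, "unloaded_geometry"))
  need <- c("pressure_mmHg", "outer_diameter_um", "axial_length_um",
            "axial_force_mN")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  r_o <- data$outer_diameter_um / 2
  l <- data$axial_length_um
  r_i <- inner_radius(r_o, l, geom$V_um3)
  P <- mmHg_to_Pa(data$pressure_mmHg)
  f <- mN_to_N(data$axial_force_mN)
  r_i_m <- um_to_m(r_i); r_o_m <- um_to_m(r_o)
  data$inner_radius_um <- r_i
  data$wall_thickness_um <- r_o - r_i
  data$lambda_theta <- (r_i + r_o) / (2 * geom$rho_mid_um)
  data$lambda_z <- l / geom$L_um
  data$sigma_theta_kPa <- P * r_i_m / (r_o_m - r_i_m) / 1e3
  data$sigma_z_kPa <- (f + P * pi * r_i_m^2) / (pi * (r_o_m^2 - r_i_m^2)) / 1e3
  data
}
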