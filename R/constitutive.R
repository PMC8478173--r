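#' Four-fiber-family constitutive parameters
#'
#' Stored-energy function for the passive arterial wall: an isotropic
#' (elastin-dominated) neo-Hookean term plus four exponential
#' collagen-dominated fiber families along the axial (\eqn{\alpha_0 = 0}),
#' circumferential (\eqn{\alpha_0 = 90^\circ}) and two symmetric diagonal
#' (\eqn{\pm\alpha_0}) directions:
#' \deqn{W = \frac{c}{2}(I_c - 3) + \sum_{i=1}^4
#'   \frac{c_1^i}{4 c_2^i}\left\{\exp\!\left[c_2^i (IV_c^i - 1)^2\right] - 1\right\}.}
#' The diagonal pair shares \eqn{(c_1, c_2)}, so the model has 8 free
#' scalars: \eqn{c}, per-family \eqn{(c_1, c_2)} for axial, circumferential
#' and the diagonal pair, and the diagonal angle \eqn{\alpha_0}.
#'
#' @param c_kPa isotropic modulus \eqn{c} (kPa), \eqn{\ge 0}.
#' @param c1_axial_kPa,c2_axial axial family modulus (kPa) and exponent.
#' @param c1_circ_kPa,c2_circ circumferential family modulus and exponent.
#' @param c1_diag_kPa,c2_diag shared diagonal-pair modulus and exponent.
#' @param alpha0_deg diagonal fiber angle from the axial direction
#'   (degrees), in (0, 90).
#' @return object of class \code{"four_fiber_params"} with per-family
#'   vectors \code{c1_kPa}, \code{c2}, \code{alpha0_deg} of length 4
#'   (axial, circumferential, +diagonal, -diagonal).
#' @export
four_fiber_params <- function(c_kPa, c1_axial_kPa, c2_axial,
                              c1_circ_kPa, c2_circ,
                              c1_diag_kPa, c2_diag, alpha0_deg) {
  vals <- c(c_kPa, c1_axial_kPa, c2_axial, c1_circ_kPa, c2_circ,
            c1_diag_kPa, c2_diag, alpha0_deg)
  stopifnot(is.numeric(vals), length(vals) == 8, all(is.finite(vals)))
  if (c_kPa < 0 || any(c(c1_axial_kPa, c1_circ_kPa, c1_diag_kPa) < 0) ||
      any(c(c2_axial, c2_circ, c2_diag) < 0))
    stop("moduli and exponents must be nonnegative")
  if (alpha0_deg <= 0 || alpha0_deg >= 90)
    stop("diagonal angle must lie strictly between 0 and 90 degrees")
  structure(list(
    c_kPa = c_kPa,
    c1_kPa = c(c1_axial_kPa, c1_circ_kPa, c1_diag_kPa, c1_diag_kPa),
    c2 = c(c2_axial, c2_circ, c2_diag, c2_diag),
    alpha0_deg = c(0, 90, alpha0_deg, -alpha0_deg)
  ), class = "four_fiber_params")
}

#' @export
print.four_fiber_params <- function(x, ...) {
  cat("Four-fiber-family parameters\n")
  cat(sprintf("  c = %.4g kPa\n", x$c_kPa))
  fam <- c("axial", "circumferential", "+diagonal", "-diagonal")
  for (i in 1:4)
    cat(sprintf("  %-16s c1 = %.4g kPa, c2 = %.4g, alpha0 = %.2f deg\n",
                fam[i], x$c1_kPa[i], x$c2[i], x$alpha0_deg[i]))
  invisible(x)
}

# free-parameter vector <-> object, used by the fitter
params_to_vector <- function(p) {
  c(c = p$c_kPa, c1_ax = p$c1_kPa[1], c2_ax = p$c2[1],
    c1_ci = p$c1_kPa[2], c2_ci = p$c2[2],
    c1_dg = p$c1_kPa[3], c2_dg = p$c2[3], alpha0 = p$alpha0_deg[3])
}

vector_to_params <- function(v) {
  four_fiber_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8])
}

#' Deformation invariants for a biaxial state
#'
#' Under incompressibility (\eqn{\lambda_r = 1/(\lambda_\theta\lambda_z)}),
#' the first invariant of the right Cauchy-Green tensor is
#' \eqn{I_c = \lambda_\theta^2 + \lambda_z^2 + 1/(\lambda_\theta^2\lambda_z^2)}
#' and the square of the stretch of a fiber family at reference angle
#' \eqn{\alpha_0} from the axial direction is
#' \eqn{IV_c = \lambda_\theta^2 \sin^2\alpha_0 + \lambda_z^2 \cos^2\alpha_0}.
#'
#' @param lambda_theta,lambda_z stretches (> 0); vectors recycle.
#' @param alpha0_deg fiber angle(s) in degrees.
#' @return list with \code{I_c} (length of the states) and \code{IV_c}
#'   (matrix, states x angles).
#' @export
deformation_invariants <- function(lambda_theta, lambda_z, alpha0_deg) {
  stopifnot(all(lambda_theta > 0), all(lambda_z > 0))
  n <- max(length(lambda_theta), length(lambda_z))
  lambda_theta <- rep_len(lambda_theta, n)
  lambda_z <- rep_len(lambda_z, n)
  a <- alpha0_deg * pi / 180
  I_c <- lambda_theta^2 + lambda_z^2 + 1 / (lambda_theta^2 * lambda_z^2)
  IV_c <- outer(lambda_theta^2, sin(a)^2) + outer(lambda_z^2, cos(a)^2)
  list(I_c = I_c, IV_c = IV_c)
}

# fiber-term energy density, handling the removable c2 -> 0 singularity
fiber_energy_term <- function(c1, c2, IV) {
  x <- (IV - 1)^2
  if (c2 == 0) return(c1 / 4 * x)
  c1 / (4 * c2) * expm1(c2 * x)   # expm1: accurate near the c2 -> 0 limit
}

#' Stored energy of a biaxial state
#'
#' @param lambda_theta,lambda_z stretches (vectorized).
#' @param params a \code{\link{four_fiber_params}}.
#' @return stored energy W in kPa (= kJ/m^3), same length as the states.
#' @export
strain_energy <- function(lambda_theta, lambda_z, params) {
  stopifnot(inherits(params, "four_fiber_params"))
  inv <- deformation_invariants(lambda_theta, lambda_z, params$alpha0_deg)
  W <- params$c_kPa / 2 * (inv$I_c - 3)
  for (i in 1:4)
    W <- W + fiber_energy_term(params$c1_kPa[i], params$c2[i], inv$IV_c[, i])
  W
}

# dW/dIV for one family (handles c2 = 0 exactly: exp(0) = 1)
fiber_dW_dIV <- function(c1, c2, IV) {
  c1 / 2 * (IV - 1) * exp(c2 * (IV - 1)^2)
}

#' Model Cauchy stresses from the stored-energy function
#'
#' With \eqn{\hat W(\lambda_\theta, \lambda_z)} the incompressible reduced
#' energy and zero mean radial stress, the mean Cauchy stresses are
#' \eqn{\sigma_\theta = \lambda_\theta\, \partial\hat W/\partial\lambda_\theta}
#' and \eqn{\sigma_z = \lambda_z\, \partial\hat W/\partial\lambda_z},
#' evaluated analytically.
#'
#' @inheritParams strain_energy
#' @return data.frame with columns \code{sigma_theta_kPa},
#'   \code{sigma_z_kPa}.
#' @export
model_stresses <- function(lambda_theta, lambda_z, params) {
  stopifnot(inherits(params, "four_fiber_params"))
  n <- max(length(lambda_theta), length(lambda_z))
  lt <- rep_len(lambda_theta, n); lz <- rep_len(lambda_z, n)
  inv <- deformation_invariants(lt, lz, params$alpha0_deg)
  a <- params$alpha0_deg * pi / 180
  # isotropic part: sigma = c (lambda^2 - 1/(lt^2 lz^2))
  st <- params$c_kPa * (lt^2 - 1 / (lt^2 * lz^2))
  sz <- params$c_kPa * (lz^2 - 1 / (lt^2 * lz^2))
  for (i in 1:4) {
    IV <- inv$IV_c[, i]
    g <- 2 * fiber_dW_dIV(params$c1_kPa[i], params$c2[i], IV)  # 2 dW/dIV
    st <- st + g * lt^2 * sin(a[i])^2
    sz <- sz + g * lz^2 * cos(a[i])^2
  }
  data.frame(sigma_theta_kPa = st, sigma_z_kPa = sz)
}

# first and second partial derivatives of the reduced energy w.r.t. the
# stretches; returned in kPa units
energy_derivatives <- function(lt, lz, params) {
  n <- max(length(lt), length(lz))
  lt <- rep_len(lt, n); lz <- rep_len(lz, n)
  a <- params$alpha0_deg * pi / 180
  inv <- deformation_invariants(lt, lz, params$alpha0_deg)
  cc <- params$c_kPa
  Wt <- cc * (lt - lt^-3 * lz^-2)
  Wz <- cc * (lz - lz^-3 * lt^-2)
  Wtt <- cc * (1 + 3 * lt^-4 * lz^-2)
  Wzz <- cc * (1 + 3 * lz^-4 * lt^-2)
  for (i in 1:4) {
    IV <- inv$IV_c[, i]
    s2 <- sin(a[i])^2; c2a <- cos(a[i])^2
    c1 <- params$c1_kPa[i]; c2 <- params$c2[i]
    e <- exp(c2 * (IV - 1)^2)
    d1 <- c1 / 2 * (IV - 1) * e                    # dW/dIV
    d2 <- c1 / 2 * e * (1 + 2 * c2 * (IV - 1)^2)   # d2W/dIV2
    Wt <- Wt + d1 * 2 * lt * s2
    Wz <- Wz + d1 * 2 * lz * c2a
    Wtt <- Wtt + 2 * s2 * d1 + (2 * lt * s2)^2 * d2
    Wzz <- Wzz + 2 * c2a * d1 + (2 * lz * c2a)^2 * d2
  }
  list(Wt = Wt, Wz = Wz, Wtt = Wtt, Wzz = Wzz)
}

#' Linearized (small-on-large) biaxial material stiffness
#'
#' Linearization about a finitely deformed state, in terms of Green strains
#' \eqn{E_{ii} = (\lambda_i^2 - 1)/2}:
#' \deqn{C_{iiii} = 2\sigma_i + \lambda_i^4\,
#'   \partial^2 \hat W / \partial E_{ii}^2,}
#' which reduces algebraically to
#' \eqn{C_{\theta\theta\theta\theta} = \lambda_\theta\,
#' \partial\sigma_\theta/\partial\lambda_\theta} at fixed \eqn{\lambda_z}
#' (and symmetrically for the axial component).
#'
#' @inheritParams strain_energy
#' @return data.frame with columns \code{C_tttt_kPa}, \code{C_zzzz_kPa}.
#' @export
linearized_stiffness <- function(lambda_theta, lambda_z, params) {
  stopifnot(inherits(params, "four_fiber_params"))
  d <- energy_derivatives(lambda_theta, lambda_z, params)
  # C = 2 sigma + lambda^4 (Wxx/lambda^2 - Wx/lambda^3)
  #   = lambda Wx + lambda^2 Wxx
  data.frame(
    C_tttt_kPa = lambda_theta * d$Wt + lambda_theta^2 * d$Wtt,
    C_zzzz_kPa = lambda_z * d$Wz + lambda_z^2 * d$Wzz
  )
}

# loaded radii (um) implied by the stretches and incompressibility
radii_from_stretches <- function(lambda_theta, lambda_z, geom) {
  stopifnot(inherits(geom, "unloaded_geometry"))
  s <- 2 * geom$rho_mid_um * lambda_theta            # r_i + r_o
  d <- geom$V_um3 / (pi * lambda_z * geom$L_um * s)  # r_o - r_i
  r_i <- (s - d) / 2
  r_o <- (s + d) / 2
  if (any(r_i <= 0)) stop("infeasible geometry: nonpositive inner radius")
  list(r_i_um = r_i, r_o_um = r_o)
}

#' Equilibrium pressure and transducer force predicted by the model
#'
#' Inverts the thin-wall mean-stress relations: for a state
#' \eqn{(\lambda_\theta, \lambda_z)} the loaded radii follow from
#' incompressibility, then
#' \eqn{P = \sigma_\theta (r_o - r_i)/r_i} and
#' \eqn{f_T = \sigma_z \pi (r_o^2 - r_i^2) - P \pi r_i^2}.
#'
#' @inheritParams strain_energy
#' @param geom an \code{\link{unloaded_geometry}}.
#' @return data.frame with \code{P_Pa}, \code{f_T_N}, \code{r_i_um},
#'   \code{r_o_um}.
#' @export
equilibrium_pressure_force <- function(lambda_theta, lambda_z, params, geom) {
  r <- radii_from_stretches(lambda_theta, lambda_z, geom)
  s <- model_stresses(lambda_theta, lambda_z, params)
  ri <- um_to_m(r$r_i_um); ro <- um_to_m(r$r_o_um)
  P <- s$sigma_theta_kPa * 1e3 * (ro - ri) / ri
  f <- s$sigma_z_kPa * 1e3 * pi * (ro^2 - ri^2) - P * pi * ri^2
  data.frame(P_Pa = P, f_T_N = f, r_i_um = r$r_i_um, r_o_um = r$r_o_um)
}

#' Solve the circumferential stretch that equilibrates a target pressure
#'
#' Bracketed root finding on \eqn{P(\lambda_\theta) - P^\ast} at fixed
#' axial stretch.
#'
#' @param P_target_Pa target transmural pressure (Pa); vectorized.
#' @param lambda_z fixed axial stretch.
#' @param params,geom model parameters and unloaded geometry.
#' @param interval search bracket for \eqn{\lambda_\theta}.
#' @return numeric vector of circumferential stretches.
#' @export
solve_circ_stretch <- function(P_target_Pa, lambda_z, params, geom,
                               interval = c(0.3, 4)) {
  f <- function(lt, Pt)
    equilibrium_pressure_force(lt, lambda_z, params, geom)$P_Pa - Pt
  # scan for a sign change: very stiff parameter sets can overflow the
  # exponential fiber terms near the bracket ends, so the widest finite
  # sub-bracket is located first
  grid <- seq(interval[1], interval[2], length.out = 61)
  vapply(P_target_Pa, function(Pt) {
    fv <- suppressWarnings(f(grid, Pt))
    ok <- is.finite(fv)
    sgn <- which(ok[-length(ok)] & ok[-1] &
                   fv[-length(fv)] * fv[-1] <= 0)
    if (!length(sgn))
      stop(sprintf(
        "no equilibrium solution for P = %.3g Pa in bracket [%g, %g]",
        Pt, interval[1], interval[2]))
    i <- sgn[1]
    stats::uniroot(f, c(grid[i], grid[i + 1]), Pt = Pt, tol = 1e-12)$root
  }, numeric(1))
}

#' Stored energy (and stiffness) at physiologic evaluation pressures
#'
#' For each pressure, solves the inflation equilibrium for
#' \eqn{\lambda_\theta} at the vessel-specific in vivo axial stretch and
#' evaluates the stored energy and the linearized biaxial stiffness there.
#' Default pressures are the diastolic, mean and systolic values used for
#' reporting (5, 15, 25 mmHg).
#'
#' @param params,geom model parameters and unloaded geometry.
#' @param pressures_mmHg evaluation pressures.
#' @param lambda_z axial stretch; defaults to \code{geom$lambda_z_iv}.
#' @return data.frame with one row per pressure: \code{pressure_mmHg},
#'   \code{lambda_theta}, \code{W_kPa}, \code{C_tttt_kPa}, \code{C_zzzz_kPa},
#'   \code{outer_diameter_um}.
#' @export
stored_energy_at_pressures <- function(params, geom,
                                       pressures_mmHg = c(5, 15, 25),
                                       lambda_z = geom$lambda_z_iv) {
  if (is.null(lambda_z))
    stop("axial stretch not given and geometry has no lambda_z_iv")
  lt <- solve_circ_stretch(mmHg_to_Pa(pressures_mmHg), lambda_z, params, geom)
  st <- linearized_stiffness(lt, lambda_z, params)
  r <- radii_from_stretches(lt, lambda_z, geom)
  data.frame(pressure_mmHg = pressures_mmHg,
             lambda_theta = lt,
             W_kPa = strain_energy(lt, lambda_z, params),
             C_tttt_kPa = st$C_tttt_kPa,
             C_zzzz_kPa = st$C_zzzz_kPa,
             outer_diameter_um = 2 * r$r_o_um)
}
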