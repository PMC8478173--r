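#' Nonlinear regression of four-fiber-family parameters to biaxial data
#'
#' The material constants are identified from the full set of passive
#' protocols at once by bound-constrained nonlinear least squares on
#' pressure and axial force.  For every record the stretches are taken from
#' the measurements (outer radius plus incompressibility — never refit) and
#' the model predicts \eqn{(P, f_T)} through the equilibrium relations;
#' residuals are normalized by the per-vessel means of the measured
#' pressure and force so both channels carry comparable weight and the fit
#' is invariant to unit changes.
#'
#' @name estimation
NULL

# default box constraints for the 8 free parameters
# (c, c1_ax, c2_ax, c1_ci, c2_ci, c1_dg, c2_dg, alpha0_deg)
default_fit_bounds <- function() {
  list(lower = c(0, 0, 0, 0, 0, 0, 0, 5),
       upper = c(1e4, 1e4, 50, 1e4, 50, 1e4, 50, 85))
}

# model-predicted (P, f) for the measured states of a record table
predict_pressure_force <- function(par_vec, data, geom) {
  p <- vector_to_params(par_vec)
  r_o <- data$outer_diameter_um / 2
  l <- data$axial_length_um
  r_i <- inner_radius(r_o, l, geom$V_um3)
  lt <- (r_i + r_o) / (2 * geom$rho_mid_um)
  lz <- l / geom$L_um
  s <- model_stresses(lt, lz, p)
  ri <- um_to_m(r_i); ro <- um_to_m(r_o)
  P <- s$sigma_theta_kPa * 1e3 * (ro - ri) / ri
  f <- s$sigma_z_kPa * 1e3 * pi * (ro^2 - ri^2) - P * pi * ri^2
  list(P_Pa = P, f_T_N = f)
}

# normalized residual vector; non-finite entries (overflow of the
# exponential fiber terms far from the optimum) are clamped so the
# Levenberg-Marquardt step remains defined
fit_residuals <- function(par_vec, data, geom, P_bar_Pa, f_bar_N) {
  pred <- predict_pressure_force(par_vec, data, geom)
  r <- c((pred$P_Pa - mmHg_to_Pa(data$pressure_mmHg)) / P_bar_Pa,
         (pred$f_T_N - mN_to_N(data$axial_force_mN)) / f_bar_N)
  r[!is.finite(r)] <- 1e6
  r
}

normalization_constants <- function(data) {
  P_bar <- mean(mmHg_to_Pa(data$pressure_mmHg))
  f_bar <- mean(mN_to_N(data$axial_force_mN))
  if (P_bar <= 0) P_bar <- max(mean(abs(mmHg_to_Pa(data$pressure_mmHg))), 1)
  if (f_bar <= 0) f_bar <- max(mean(abs(mN_to_N(data$axial_force_mN))), 1e-6)
  list(P_bar_Pa = P_bar, f_bar_N = f_bar)
}

#' Fitting objective: normalized sum of squared pressure/force residuals
#'
#' \deqn{J = \sum_k \left[\frac{P_k^{mod} - P_k^{exp}}{\bar P}\right]^2 +
#'            \left[\frac{f_k^{mod} - f_k^{exp}}{\bar f}\right]^2}
#' with \eqn{\bar P, \bar f} the per-vessel means of the measured pressure
#' and force over all records.
#'
#' @param params a \code{\link{four_fiber_params}}.
#' @param data biaxial record table (columns \code{pressure_mmHg},
#'   \code{outer_diameter_um}, \code{axial_length_um},
#'   \code{axial_force_mN}); all protocols stacked.
#' @param geom an \code{\link{unloaded_geometry}}.
#' @return scalar objective value, \eqn{\ge 0}.
#' @export
fit_objective <- function(params, data, geom) {
  stopifnot(inherits(params, "four_fiber_params"))
  nc <- normalization_constants(data)
  sum(fit_residuals(params_to_vector(params), data, geom,
                    nc$P_bar_Pa, nc$f_bar_N)^2)
}

# Latin-hypercube starting points; moduli and exponents are sampled on a
# log scale (the physically plausible mass of the box is near its lower
# corner), the angle uniformly
lhs_starts <- function(n_starts, bounds) {
  u <- lhs::randomLHS(n_starts, 8)
  lo_log <- c(-1, -2, -2, -2, -2, -2, -2, NA)
  hi_log <- c(3, 3, 1, 3, 1, 3, 1, NA)
  starts <- matrix(NA_real_, n_starts, 8)
  for (j in 1:7) starts[, j] <- 10^(lo_log[j] + u[, j] * (hi_log[j] - lo_log[j]))
  starts[, 8] <- 15 + u[, 8] * 60
  for (j in 1:8) {
    starts[, j] <- pmin(pmax(starts[, j], bounds$lower[j]), bounds$upper[j])
  }
  starts
}

#' Fit the four-fiber-family model to multi-protocol biaxial data
#'
#' Multi-start bound-constrained Levenberg-Marquardt
#' (\code{minpack.lm::nls.lm}) from Latin-hypercube initializations; the
#' start with the lowest final objective wins (ties broken by the smaller
#' parameter-vector norm).  The diagonal-pair symmetry
#' (\eqn{c_1^3 = c_1^4}, \eqn{c_2^3 = c_2^4}) is built into the
#' parameterization, so it holds exactly in the result.
#'
#' @param data stacked biaxial records (all protocols); optionally with a
#'   \code{protocol_id} column used for the per-protocol RMSE report.
#' @param geom an \code{\link{unloaded_geometry}}.
#' @param n_starts number of Latin-hypercube initializations.
#' @param seed integer seed making the starts reproducible.
#' @param bounds list with \code{lower}/\code{upper} length-8 vectors in the
#'   order (c, c1 axial, c2 axial, c1 circ, c2 circ, c1 diag, c2 diag,
#'   alpha0 deg).
#' @return object of class \code{"four_fiber_fit"}: list with
#'   \code{params} (\code{\link{four_fiber_params}}), \code{objective},
#'   \code{rmse} (per-protocol RMSE of pressure in mmHg and force in mN),
#'   \code{converged}, \code{n_starts}, \code{seed},
#'   \code{start_objectives}.
#' @export
fit_four_fiber <- function(data, geom, n_starts = 20, seed = 1,
                           bounds = default_fit_bounds()) {
  stopifnot(inherits(geom, "unloaded_geometry"))
  if (nrow(data) < 8 * 8)
    stop("need at least 8x more records than the 8 free parameters")
  nc <- normalization_constants(data)
  starts <- with_seed(seed, lhs_starts(n_starts, bounds))
  best <- NULL
  objs <- rep(NA_real_, n_starts)
  any_conv <- FALSE
  for (k in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[k, ], lower = bounds$lower, upper = bounds$upper,
        fn = fit_residuals, data = data, geom = geom,
        P_bar_Pa = nc$P_bar_Pa, f_bar_N = nc$f_bar_N,
        control = minpack.lm::nls.lm.control(maxiter = 400,
                                             ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- fit$deviance
    objs[k] <- obj
    any_conv <- TRUE
    if (is.null(best) || obj < best$obj - 1e-15 ||
        (abs(obj - best$obj) <= 1e-15 &&
         sum(fit$par^2) < sum(best$par^2))) {
      best <- list(par = fit$par, obj = obj, info = fit$info)
    }
  }
  if (!any_conv)
    stop("estimation failure: no start converged; check data and bounds")
  params <- vector_to_params(best$par)
  pred <- predict_pressure_force(best$par, data, geom)
  pid <- if (!is.null(data$protocol_id)) data$protocol_id else "all"
  rmse <- do.call(rbind, lapply(split(seq_len(nrow(data)), pid), function(i) {
    data.frame(
      protocol_id = pid[i[1]],
      rmse_P_mmHg = sqrt(mean((Pa_to_mmHg(pred$P_Pa[i]) -
                               data$pressure_mmHg[i])^2)),
      rmse_f_mN = sqrt(mean((pred$f_T_N[i] * 1e3 -
                             data$axial_force_mN[i])^2)))
  }))
  rownames(rmse) <- NULL
  structure(list(params = params, objective = best$obj, rmse = rmse,
                 converged = TRUE, n_starts = n_starts, seed = seed,
                 start_objectives = objs),
            class = "four_fiber_fit")
}

#' @export
print.four_fiber_fit <- function(x, ...) {
  cat(sprintf("Four-fiber-family fit: objective = %.4g (%d starts, seed %d)\n",
              x$objective, x$n_starts, x$seed))
  print(x$params)
  cat("Per-protocol RMSE:\n")
  print(x$rmse, row.names = FALSE)
  invisible(x)
}
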