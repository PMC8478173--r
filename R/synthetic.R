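#' Synthetic vessel specification
#'
#' Ground-truth description of a murine pulmonary-artery-like vessel used
#' by every generator: unloaded geometry, four-fiber-family constants, in
#' vivo axial stretch and measurement noise levels.  The default constants
#' are order-of-magnitude plausible for murine pulmonary arteries (elastin
#' modulus on the 10 kPa scale, soft exponentially stiffening collagen
#' families); they are a synthetic construction, not fitted literature
#' values.
#'
#' @param geom an \code{\link{unloaded_geometry}}; default a 4 mm segment,
#'   900 um unloaded outer diameter, 60 um wall, in vivo axial
#'   stretch 1.4.
#' @param params a \code{\link{four_fiber_params}} ground truth.
#' @param noise_diameter,noise_force relative SD of the multiplicative
#'   Gaussian measurement noise on outer diameter and axial force.
#' @return object of class \code{"synthetic_vessel_spec"}.
#' @export
synthetic_vessel_spec <- function(
    geom = unloaded_geometry(L_um = 4000, OD_um = 900, H_um = 60,
                             lambda_z_iv = 1.4),
    params = four_fiber_params(c_kPa = 18,
                               c1_axial_kPa = 2.5, c2_axial = 0.8,
                               c1_circ_kPa = 4.0, c2_circ = 0.6,
                               c1_diag_kPa = 1.5, c2_diag = 1.2,
                               alpha0_deg = 42),
    noise_diameter = 0.02, noise_force = 0.02) {
  stopifnot(inherits(geom, "unloaded_geometry"),
            inherits(params, "four_fiber_params"),
            noise_diameter >= 0, noise_force >= 0)
  structure(list(geom = geom, params = params,
                 noise_diameter = noise_diameter,
                 noise_force = noise_force),
            class = "synthetic_vessel_spec")
}

#' Simulate the seven passive biaxial protocols
#'
#' Three pressure sweeps (0 to 30 mmHg in 1 mmHg steps) at axial stretches
#' of 0.95, 1.00 and 1.05 times the in vivo value, plus four axial-stretch
#' sweeps (0.90 to 1.10 times in vivo, 21 points) at fixed pressures of 5,
#' 10, 15 and 20 mmHg.  Each state is solved from the inflation
#' equilibrium of the ground-truth model by bracketed root finding;
#' multiplicative Gaussian noise is then applied to the recorded outer
#' diameter and axial force.  Deterministic given the seed.
#'
#' @param spec a \code{\link{synthetic_vessel_spec}}.
#' @param seed integer seed.
#' @return data.frame in the biaxial record schema (\code{time_s},
#'   \code{pressure_mmHg}, \code{outer_diameter_um},
#'   \code{axial_length_um}, \code{axial_force_mN}, \code{protocol_id})
#'   with the ground truth attached as attribute \code{"truth"}.
#' @export
simulate_biaxial_protocols <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_vessel_spec"))
  geom <- spec$geom; params <- spec$params
  lz_iv <- geom$lambda_z_iv
  states <- list()
  for (fz in c(0.95, 1.00, 1.05)) {
    P <- seq(0, 30, by = 1)
    states[[length(states) + 1]] <- data.frame(
      protocol_id = sprintf("P-sweep@%.2flz", fz),
      pressure_mmHg = P, lambda_z = fz * lz_iv)
  }
  for (Pfix in c(5, 10, 15, 20)) {
    lz <- seq(0.90, 1.10, length.out = 21) * lz_iv
    states[[length(states) + 1]] <- data.frame(
      protocol_id = sprintf("lz-sweep@%dmmHg", Pfix),
      pressure_mmHg = Pfix, lambda_z = lz)
  }
  states <- do.call(rbind, states)
  out <- do.call(rbind, lapply(seq_len(nrow(states)), function(i) {
    lz <- states$lambda_z[i]
    lt <- solve_circ_stretch(mmHg_to_Pa(states$pressure_mmHg[i]),
                             lz, params, geom)
    eq <- equilibrium_pressure_force(lt, lz, params, geom)
    data.frame(pressure_mmHg = states$pressure_mmHg[i],
               outer_diameter_um = 2 * eq$r_o_um,
               axial_length_um = lz * geom$L_um,
               axial_force_mN = eq$f_T_N * 1e3,
               protocol_id = states$protocol_id[i])
  }))
  out <- with_seed(seed, {
    n <- nrow(out)
    out$outer_diameter_um <- out$outer_diameter_um *
      (1 + spec$noise_diameter * stats::rnorm(n))
    out$axial_force_mN <- out$axial_force_mN *
      (1 + spec$noise_force * stats::rnorm(n))
    out
  })
  out <- cbind(time_s = seq_len(nrow(out)) - 1, out)
  attr(out, "truth") <- list(params = params, geom = geom, seed = seed,
                             noise_diameter = spec$noise_diameter,
                             noise_force = spec$noise_force)
  out
}

#' Simulate a first-order vasoactive response trace
#'
#' \eqn{d(t) = d_0 (1 - A (1 - e^{-t/\tau}))} plus additive Gaussian
#' noise: a monoexponential approach to a contracted plateau, emulating
#' the diameter time course under KCl or phenylephrine at fixed pressure.
#'
#' @param d0_um baseline outer diameter (um).
#' @param amplitude plateau fractional reduction A in [0, 1).
#' @param tau_min time constant (minutes), > 0.
#' @param duration_min trace length; contraction assays span >= 15 min.
#' @param dt_min sampling interval.
#' @param noise_sd additive noise SD relative to d0.
#' @param agent agent label.
#' @param seed integer seed.
#' @param ... passed to \code{\link{vaso_trace}} (vessel_id, group).
#' @return a \code{\link{vaso_trace}} with attribute \code{"truth"}.
#' @export
simulate_vaso_trace <- function(d0_um, amplitude, tau_min,
                                duration_min = 15, dt_min = 0.25,
                                noise_sd = 0, agent = "PE", seed = NULL,
                                ...) {
  stopifnot(amplitude >= 0, amplitude < 1, tau_min > 0)
  t <- seq(0, duration_min, by = dt_min)
  d <- d0_um * (1 - amplitude * (1 - exp(-t / tau_min)))
  if (noise_sd > 0)
    d <- d + with_seed(seed, d0_um * noise_sd * stats::rnorm(length(t)))
  tr <- vaso_trace(t, d, agent = agent, ...)
  attr(tr, "truth") <- list(d0_um = d0_um, amplitude = amplitude,
                            tau_min = tau_min, noise_sd = noise_sd,
                            seed = seed)
  tr
}

# accumulate ellipsoidal Gaussian blobs (sigma in um, axis-aligned with
# the long axis axial) into a 3-D array
add_blobs <- function(arr, centers_um, sigma_um, dxy, dz, peak = 1) {
  d <- dim(arr)
  for (q in seq_len(nrow(centers_um))) {
    ctr <- centers_um[q, ]
    i0 <- round(ctr[1] / dxy) + 1
    j0 <- round(ctr[2] / dxy) + 1
    k0 <- round(ctr[3] / dz) + 1
    wi <- ceiling(3 * sigma_um[1] / dxy)
    wj <- ceiling(3 * sigma_um[2] / dxy)
    wk <- ceiling(3 * sigma_um[3] / dz)
    ii <- max(1, i0 - wi):min(d[1], i0 + wi)
    jj <- max(1, j0 - wj):min(d[2], j0 + wj)
    kk <- max(1, k0 - wk):min(d[3], k0 + wk)
    if (!length(ii) || !length(jj) || !length(kk)) next
    gx <- exp(-((ii - 1) * dxy - ctr[1])^2 / (2 * sigma_um[1]^2))
    gy <- exp(-((jj - 1) * dxy - ctr[2])^2 / (2 * sigma_um[2]^2))
    gz <- exp(-((kk - 1) * dz - ctr[3])^2 / (2 * sigma_um[3]^2))
    arr[ii, jj, kk] <- arr[ii, jj, kk] +
      peak * outer(gx, outer(gy, gz))
  }
  arr
}

#' Render a synthetic three-channel vessel stack
#'
#' Builds a cylindrical-shell phantom matching the multiphoton acquisition
#' geometry: the vessel axis runs along the first (axial) array axis, the
#' cross-section lies in the lateral-depth plane.  The elastin channel
#' contains two thin laminae shells (internal and external elastic
#' laminae), the collagen channel oriented helical fiber segments in the
#' adventitia with pitch angles drawn from an axial von Mises
#' distribution, and the nuclei channel ellipsoidal Gaussian blobs
#' Poisson-placed per layer.  Optional Poisson shot noise.  A ground-truth
#' record is attached as attribute \code{"truth"}.
#'
#' @param outer_radius_um loaded outer radius of the shell.
#' @param wall_thickness_um loaded wall thickness.
#' @param length_um axial extent of the rendered segment.
#' @param fiber_theta_deg,fiber_kappa adventitial fiber orientation
#'   distribution (mean angle from axial, concentration).
#' @param n_fibers number of collagen fiber segments.
#' @param fiber_length_um length of each fiber segment.
#' @param nuclei_density_media,nuclei_density_adventitia expected nuclear
#'   densities per 0.001 mm^3 of layer volume.
#' @param nuclei_density_intima expected intimal density per 0.01 mm^2 of
#'   luminal surface.
#' @param dxy_um,dz_um voxel sizes (defaults 0.48 and 1, the acquisition
#'   values).
#' @param margin_um clearance between vessel and field edge; the field of
#'   view must contain the vessel.
#' @param shot_noise_scale photons per intensity unit for Poisson shot
#'   noise; 0 disables noise.
#' @param seed integer seed.
#' @return a \code{\link{vessel_stack}} with attribute \code{"truth"}.
#' @export
render_vessel_stack <- function(outer_radius_um = 40,
                                wall_thickness_um = 14,
                                length_um = 100,
                                fiber_theta_deg = 0, fiber_kappa = 10,
                                n_fibers = 600, fiber_length_um = 60,
                                nuclei_density_media = 0,
                                nuclei_density_adventitia = 0,
                                nuclei_density_intima = 0,
                                dxy_um = 0.48, dz_um = 1,
                                margin_um = 8,
                                shot_noise_scale = 0, seed = 1) {
  R_o <- outer_radius_um; H <- wall_thickness_um
  stopifnot(H > 0, H < R_o)
  if (margin_um < 0) stop("field of view smaller than the vessel")
  r_lumen <- R_o - H
  r_iel <- r_lumen + 0.15 * H
  r_eel <- R_o - 0.35 * H
  half <- R_o + margin_um
  nx <- max(2, round(length_um / dxy_um))
  ny <- 2 * round(half / dxy_um) + 1
  nz <- 2 * round(half / dz_um) + 1
  ctr <- c((ny - 1) / 2 * dxy_um, (nz - 1) / 2 * dz_um)
  ys <- (seq_len(ny) - 1) * dxy_um - ctr[1]
  zs <- (seq_len(nz) - 1) * dz_um - ctr[2]
  rho <- sqrt(outer(ys^2, zs^2, `+`))
  lam_sigma <- 1.0
  ela2d <- exp(-(rho - r_iel)^2 / (2 * lam_sigma^2)) +
    exp(-(rho - r_eel)^2 / (2 * lam_sigma^2))
  elastin <- aperm(array(ela2d, c(ny, nz, nx)), c(3, 1, 2))
  collagen <- array(0, c(nx, ny, nz))
  nuclei <- array(0, c(nx, ny, nz))
  truth <- with_seed(seed, {
    # --- adventitial collagen fibers: helices at von Mises pitch angles
    betas <- if (n_fibers > 0)
      sample_axial_von_mises(n_fibers, fiber_theta_deg, fiber_kappa)
    else numeric(0)
    r_adv <- sqrt(stats::runif(n_fibers, r_eel^2, R_o^2))
    phi0 <- stats::runif(n_fibers, 0, 2 * pi)
    x0 <- stats::runif(n_fibers, -fiber_length_um, length_um)
    step <- 0.4
    for (q in seq_len(n_fibers)) {
      b <- betas[q] * pi / 180
      s <- seq(0, fiber_length_um, by = step)
      x <- x0[q] + s * cos(b)
      phi <- phi0[q] + s * sin(b) / r_adv[q]
      keep <- x >= 0 & x <= (nx - 1) * dxy_um
      if (!any(keep)) next
      i <- round(x[keep] / dxy_um) + 1
      j <- round((ctr[1] + r_adv[q] * cos(phi[keep])) / dxy_um) + 1
      k <- round((ctr[2] + r_adv[q] * sin(phi[keep])) / dz_um) + 1
      ok <- j >= 1 & j <= ny & k >= 1 & k <= nz
      lin <- cbind(i[ok], j[ok], k[ok])
      collagen[lin] <- collagen[lin] + 1
    }
    # --- nuclei per layer
    axial_len <- nx * dxy_um
    place_annulus <- function(n, r1, r2) {
      if (n == 0) return(matrix(numeric(0), 0, 3))
      r <- sqrt(stats::runif(n, r1^2, r2^2))
      phi <- stats::runif(n, 0, 2 * pi)
      cbind(stats::runif(n, 0, (nx - 1) * dxy_um),
            ctr[1] + r * cos(phi), ctr[2] + r * sin(phi))
    }
    v_media <- pi * (r_eel^2 - r_iel^2) * axial_len
    v_adv <- pi * (R_o^2 - r_eel^2) * axial_len
    a_int <- 2 * pi * r_lumen * axial_len
    n_med <- stats::rpois(1, nuclei_density_media * v_media / 1e6)
    n_adv <- stats::rpois(1, nuclei_density_adventitia * v_adv / 1e6)
    n_int <- stats::rpois(1, nuclei_density_intima * a_int / 1e4)
    sig <- c(2, 1.5, 1.5)
    nuclei <- add_blobs(nuclei, place_annulus(n_med, r_iel + 2, r_eel - 2),
                         sig, dxy_um, dz_um)
    nuclei <- add_blobs(nuclei, place_annulus(n_adv, r_eel + 1, R_o - 1),
                         sig, dxy_um, dz_um)
    nuclei <- add_blobs(nuclei,
                         place_annulus(n_int, r_lumen + 0.5, r_iel - 0.5),
                         sig, dxy_um, dz_um)
    if (shot_noise_scale > 0) {
      noisify <- function(a) {
        stats::rpois(length(a), pmax(a, 0) * shot_noise_scale) /
          shot_noise_scale
      }
      collagen <- array(noisify(collagen), dim(collagen))
      elastin <- array(noisify(elastin), dim(elastin))
      nuclei <- array(noisify(nuclei), dim(nuclei))
    }
    list(fiber_theta_deg = fiber_theta_deg, fiber_kappa = fiber_kappa,
         fiber_angles_deg = betas,
         r_lumen_um = r_lumen, r_iel_um = r_iel, r_eel_um = r_eel,
         r_outer_um = R_o,
         n_nuclei = c(intima = n_int, media = n_med, adventitia = n_adv),
         density_media = n_med / v_media * 1e6,
         density_adventitia = n_adv / v_adv * 1e6,
         density_intima = n_int / a_int * 1e4,
         seed = seed)
  })
  # mild cross-sectional blur so fibers have finite thickness
  for (ix in seq_len(nx)) {
    collagen[ix, , ] <- gblur_mat(collagen[ix, , ], 0.8)
    nuclei[ix, , ] <- gblur_mat(nuclei[ix, , ], 0.5)
  }
  st <- vessel_stack(collagen, elastin, nuclei, dxy_um, dz_um)
  attr(st, "truth") <- truth
  st
}

#' Render a synthetic stained-section panel
#'
#' Produces matched VVG, trichrome and Movat images of one synthetic
#' cross-section: tissue pixels in an annular section are partitioned into
#' elastin, cytoplasm, ground substance, fibrin and collagen regions with
#' exact target fractions (spatially clumped via a smoothed random field),
#' then colored with per-stain palettes consistent with the default stain
#' rules, with an uneven illumination field, optional blur, and mild pixel
#' noise.
#'
#' @param fractions named vector with \code{elastin}, \code{cytoplasm},
#'   \code{ground}, \code{fibrin} target area fractions (sum <= 1;
#'   collagen is the remainder).
#' @param size_px image side length.
#' @param blur_sigma_px Gaussian blur applied to each stain image.
#' @param noise_sd additive RGB noise SD.
#' @param seed integer seed.
#' @return list with RGB arrays \code{vvg}, \code{mtc}, \code{movat} and
#'   \code{truth} (the exact pixel fractions).
#' @export
render_stain_panel <- function(fractions = c(elastin = 0.37,
                                             cytoplasm = 0.12,
                                             ground = 0.07, fibrin = 0.02),
                               size_px = 160, blur_sigma_px = 0,
                               noise_sd = 0.005, seed = 1) {
  stopifnot(all(fractions >= 0), sum(fractions) <= 1)
  n <- size_px
  with_seed(seed, {
    xs <- seq(-1, 1, length.out = n)
    rho <- sqrt(outer(xs^2, xs^2, `+`))
    tissue <- rho >= 0.35 & rho <= 0.92
    nt <- sum(tissue)
    # compact Voronoi patches assigned greedily to classes, so every
    # constituent forms blob-like regions rather than thin ribbons; the
    # realized pixel fractions are recorded as the ground truth
    n_patch <- 150
    tij <- which(tissue, arr.ind = TRUE)
    seeds <- tij[sample.int(nt, n_patch), , drop = FALSE]
    d2 <- outer(tij[, 1], seeds[, 1], `-`)^2 +
      outer(tij[, 2], seeds[, 2], `-`)^2
    patch <- max.col(-d2)
    psize <- tabulate(patch, n_patch)
    labels <- rep("collagen", nt)
    remaining <- sample.int(n_patch)
    for (cls in names(fractions)) {
      target <- fractions[cls] * nt
      got <- 0
      take <- integer(0)
      for (pp in remaining) {
        if (got + psize[pp] / 2 > target) next
        take <- c(take, pp)
        got <- got + psize[pp]
        if (got >= target) break
      }
      labels[patch %in% take] <- cls
      remaining <- setdiff(remaining, take)
    }
    class_map <- matrix(NA_character_, n, n)
    class_map[tissue] <- labels
    palettes <- list(
      vvg = c(elastin = "#592673", cytoplasm = "#F2C7D1",
              ground = "#F2C7D1", fibrin = "#F2C7D1",
              collagen = "#F2C7D1"),
      mtc = c(elastin = "#CCBFD9", cytoplasm = "#D93350",
              ground = "#BFCCE6", fibrin = "#D9C7CC",
              collagen = "#4D66CC"),
      movat = c(elastin = "#201A21", cytoplasm = "#D94D59",
                ground = "#33B399", fibrin = "#E69926",
                collagen = "#F2D9DD"))
    render_one <- function(pal) {
      img <- array(1, c(n, n, 3))
      cols <- grDevices::col2rgb(pal[labels]) / 255
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[tissue] <- cols[ch, ]
        img[, , ch] <- plane
      }
      illum <- outer(seq(0.88, 1, length.out = n),
                     seq(0.95, 1, length.out = n))
      illum <- illum / max(illum)
      for (ch in 1:3) {
        plane <- img[, , ch] * illum +
          noise_sd * stats::rnorm(n * n)
        if (blur_sigma_px > 0) plane <- gblur_mat(plane, blur_sigma_px)
        img[, , ch] <- pmin(pmax(plane, 0), 1)
      }
      img
    }
    cls_names <- c(names(fractions), "collagen")
    truth_frac <- vapply(cls_names, function(cl) mean(labels == cl), 0)
    list(vvg = render_one(palettes$vvg), mtc = render_one(palettes$mtc),
         movat = render_one(palettes$movat),
         truth = truth_frac, class_map = class_map, tissue = tissue)
  })
}
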