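test_that("circle fit recovers an exact annulus and is translation
           equivariant", {
  img <- render_annulus_slice(101, 101, 1, 1, 50, 48, 32, 2)
  f <- fit_midwall_circle(img, 1, 1)
  expect_lt(abs(f$center_um[1] - 50), 0.1)
  expect_lt(abs(f$center_um[2] - 48), 0.1)
  expect_lt(abs(f$radius_um - 32), 0.1)
  # translating the annulus translates the fitted center identically
  img2 <- render_annulus_slice(101, 101, 1, 1, 55, 42, 32, 2)
  f2 <- fit_midwall_circle(img2, 1, 1)
  expect_equal(f2$center_um - f$center_um, c(5, -6), tolerance = 0.1)
  expect_equal(f2$radius_um, f$radius_um, tolerance = 0.1)
})

test_that("circle fit tolerates noise at SNR 5 within a pixel", {
  set.seed(31)
  for (i in 1:5) {
    img <- render_annulus_slice(101, 101, 1, 1, 50, 50, 30, 2,
                                noise_sd = 0.2)
    f <- fit_midwall_circle(img, 1, 1)
    expect_lt(max(abs(f$center_um - c(50, 50))), 1)
    expect_lt(abs(f$radius_um - 30), 1)
  }
  expect_error(fit_midwall_circle(matrix(1, 50, 50), 1, 1))
})

test_that("unwrapping maps an annulus to a band of constant radius", {
  st <- render_vessel_stack(outer_radius_um = 40, wall_thickness_um = 14,
                            length_um = 30, n_fibers = 0, dxy_um = 1,
                            dz_um = 1, seed = 1)
  pol <- unwrap_to_polar(st, n_theta = 120)
  # per-angle intensity-weighted radius of the inner lamina shell
  tr <- attr(st, "truth")
  prof <- pol$elastin[, , 5]
  r_of_theta <- apply(prof, 1, function(p) sum(pol$r_um * p) / sum(p))
  expect_lt(sd(r_of_theta), 0.5)
  expect_equal(mean(r_of_theta), (tr$r_iel_um + tr$r_eel_um) / 2,
               tolerance = 0.05)
})

test_that("polar -> Cartesian -> polar round trip preserves intensities", {
  st <- render_vessel_stack(outer_radius_um = 40, wall_thickness_um = 14,
                            length_um = 5, n_fibers = 0, dxy_um = 0.48,
                            dz_um = 0.5, seed = 2)
  pol <- unwrap_to_polar(st)
  slice <- st$elastin[5, , ]
  # rewrap: sample the polar image back onto the Cartesian grid
  ctr <- pol$circle$center_um
  ys <- (seq_len(nrow(slice)) - 1) * st$dxy_um - ctr[1]
  zs <- (seq_len(ncol(slice)) - 1) * st$dz_um - ctr[2]
  rho <- sqrt(outer(ys^2, zs^2, `+`))
  th <- atan2(outer(rep(1, length(ys)), zs),
              outer(ys, rep(1, length(zs))))
  th[th < 0] <- th[th < 0] + 2 * pi
  dtheta <- pol$theta_rad[2] - pol$theta_rad[1]
  dr <- pol$r_um[2] - pol$r_um[1]
  back <- pamech:::interp_bilinear(pol$elastin[, , 5], dtheta, dr,
                                   as.numeric(th),
                                   as.numeric(rho - pol$r_um[1]))
  back <- matrix(back, nrow(slice), ncol(slice))
  wall <- rho >= min(pol$r_um) + 2 & rho <= max(pol$r_um) - 2
  rms <- sqrt(mean((back[wall] - slice[wall])^2))
  expect_lt(rms / diff(range(slice)), 0.02)
})

test_that("structure tensor recovers stripe orientations within a degree
           and is rotation consistent", {
  for (beta in c(0, 25, 63, -40)) {
    img <- render_stripes(128, 128, beta)
    of <- orientation_field(img)
    keep <- of$mask & of$coherence > 0.8
    # interior pixels only (borders suffer from replicated-edge gradients)
    interior <- matrix(FALSE, 128, 128)
    interior[15:114, 15:114] <- TRUE
    ang <- of$angle_deg[keep & interior]
    f <- fit_von_mises_axial(ang)
    expect_lt(abs(f$theta_bar_deg - beta), 1)
  }
  # rotation consistency: shifting the stripe angle by delta shifts the
  # recovered angle by delta
  base <- 10; delta <- 35
  rec <- sapply(c(base, base + delta), function(b) {
    of <- orientation_field(render_stripes(128, 128, b))
    interior <- matrix(FALSE, 128, 128)
    interior[15:114, 15:114] <- TRUE
    fit_von_mises_axial(of$angle_deg[of$mask & interior])$theta_bar_deg
  })
  expect_lt(abs((rec[2] - rec[1]) - delta), 1)
  # reflection negates angles
  of_p <- orientation_field(render_stripes(128, 128, 30))
  of_m <- orientation_field(render_stripes(128, 128, -30))
  interior <- matrix(FALSE, 128, 128); interior[15:114, 15:114] <- TRUE
  a_p <- fit_von_mises_axial(of_p$angle_deg[of_p$mask & interior])
  a_m <- fit_von_mises_axial(of_m$angle_deg[of_m$mask & interior])
  expect_lt(abs(a_p$theta_bar_deg + a_m$theta_bar_deg), 1)
  expect_warning(orientation_field(matrix(1, 50, 50)), "uniform")
})

test_that("layer segmentation finds the elastic laminae and partitions
           the wall", {
  st <- render_vessel_stack(outer_radius_um = 40, wall_thickness_um = 14,
                            length_um = 30, n_fibers = 200, dxy_um = 1,
                            dz_um = 1, seed = 3)
  tr <- attr(st, "truth")
  pol <- unwrap_to_polar(st, n_theta = 120)
  seg <- segment_layers(pol)
  dr <- pol$r_um[2] - pol$r_um[1]
  expect_lt(abs(seg$r_iel_um - tr$r_iel_um), 1.5 * dr)
  expect_lt(abs(seg$r_eel_um - tr$r_eel_um), 1.5 * dr)
  # masks are disjoint and cover the wall annulus contiguously
  expect_equal(sum(seg$intima & seg$media), 0)
  expect_equal(sum(seg$media & seg$adventitia), 0)
  covered <- seg$intima | seg$media | seg$adventitia
  idx <- which(covered)
  expect_equal(idx, seq(min(idx), max(idx)))
  # with shot noise the lamina peaks stay within one radial sample
  st_n <- render_vessel_stack(outer_radius_um = 40, wall_thickness_um = 14,
                              length_um = 30, n_fibers = 200, dxy_um = 1,
                              dz_um = 1, shot_noise_scale = 25, seed = 4)
  seg_n <- segment_layers(unwrap_to_polar(st_n, n_theta = 120))
  expect_lt(abs(seg_n$r_iel_um - attr(st_n, "truth")$r_iel_um), 1.5 * dr)
  expect_error(segment_layers(structure(list(
    elastin = array(0, c(8, 8, 2)), collagen = array(0, c(8, 8, 2)),
    nuclei = array(0, c(8, 8, 2)), r_um = 1:8, theta_rad = 1:8,
    dxy_um = 1, dz_um = 1), class = "polar_stack")), "elastin peaks")
})

test_that("end-to-end orientation pipeline recovers helical fiber pitch", {
  # all fibers at one pitch angle: unwrapped stripes at that angle
  st <- render_vessel_stack(outer_radius_um = 40, wall_thickness_um = 14,
                            length_um = 90, fiber_theta_deg = 20,
                            fiber_kappa = 5e4, n_fibers = 250,
                            dxy_um = 1, dz_um = 1, seed = 6)
  fo <- analyze_fiber_orientation(st)
  expect_lt(abs(fo$theta_bar_deg - 20), 3)
  expect_gt(fo$kappa, 30)
})

test_that("cell density recovers a constructed nucleus count and is
           invariant to intensity scaling", {
  st <- render_vessel_stack(outer_radius_um = 40, wall_thickness_um = 14,
                            length_um = 60, n_fibers = 250,
                            nuclei_density_media = 150, dxy_um = 1,
                            dz_um = 1, seed = 8)
  tr <- attr(st, "truth")
  pol <- unwrap_to_polar(st, n_theta = 120)
  cd <- cell_density(st, "media", polar = pol)
  expect_lt(abs(cd$count - tr$n_nuclei["media"]) /
              max(tr$n_nuclei["media"], 1), 0.15)
  # doubling the intensities must not change the count (adaptive Otsu)
  st2 <- st
  st2$nuclei <- 2 * st$nuclei
  cd2 <- cell_density(st2, "media", polar = pol)
  expect_equal(cd2$count, cd$count)
  # empty layer mask errors
  st0 <- render_vessel_stack(outer_radius_um = 40, wall_thickness_um = 14,
                             length_um = 20, n_fibers = 100, dxy_um = 1,
                             dz_um = 1, seed = 9)
  expect_equal(cell_density(st0, "media")$count, 0)
})
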