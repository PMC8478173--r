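# shared fixtures, built once per test run

default_geom <- function() {
  unloaded_geometry(L_um = 4000, OD_um = 900, H_um = 60, lambda_z_iv = 1.4)
}

default_params <- function() {
  four_fiber_params(c_kPa = 18, c1_axial_kPa = 2.5, c2_axial = 0.8,
                    c1_circ_kPa = 4.0, c2_circ = 0.6,
                    c1_diag_kPa = 1.5, c2_diag = 1.2, alpha0_deg = 42)
}

# noise-free seven-protocol dataset from the default ground truth
noise_free_data <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      spec <- synthetic_vessel_spec(noise_diameter = 0, noise_force = 0)
      val <<- simulate_biaxial_protocols(spec, seed = 1)
    }
    val
  }
})

# render an ideal annulus slice (matrix ny x nz) in physical coordinates
render_annulus_slice <- function(ny, nz, dy, dz, cy, cz, r_mid, width,
                                 noise_sd = 0) {
  ys <- (seq_len(ny) - 1) * dy
  zs <- (seq_len(nz) - 1) * dz
  rho <- sqrt(outer((ys - cy)^2, (zs - cz)^2, `+`))
  img <- exp(-(rho - r_mid)^2 / (2 * width^2))
  if (noise_sd > 0) img <- img + matrix(rnorm(ny * nz, sd = noise_sd), ny, nz)
  img
}

# oriented-stripe phantom: sinusoidal stripes along direction beta
# (degrees from axis 1) in an n1 x n2 image
render_stripes <- function(n1, n2, beta_deg, period = 14) {
  b <- beta_deg * pi / 180
  x <- outer(seq_len(n1), rep(1, n2))
  y <- outer(rep(1, n1), seq_len(n2))
  # stripes constant along (cos b, sin b): phase varies along the normal
  0.5 + 0.5 * sin(2 * pi * (-x * sin(b) + y * cos(b)) / period)
}
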