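test_that("deformation invariants match their definitions", {
  inv <- deformation_invariants(1, 1, c(0, 90, 45, -45))
  expect_equal(inv$I_c, 3)
  expect_equal(as.numeric(inv$IV_c), rep(1, 4))
  expect_equal(deformation_invariants(1.2, 1.0, 90)$IV_c[1, 1], 1.44)
  expect_equal(deformation_invariants(1.2, 1.1, 45)$IV_c[1, 1],
               (1.44 + 1.21) / 2)
  expect_equal(deformation_invariants(1.3, 1.2, 30)$I_c,
               1.3^2 + 1.2^2 + 1 / (1.3^2 * 1.2^2))
})

test_that("stored energy vanishes at the reference state and reduces to
           neo-Hookean when the fiber moduli vanish", {
  p <- default_params()
  expect_equal(strain_energy(1, 1, p), 0)
  nh <- four_fiber_params(10, 0, 0, 0, 0, 0, 0, 45)
  expect_equal(strain_energy(1.2, 1, nh),
               5 * (1.2^2 + 1 + 1 / 1.2^2 - 3), tolerance = 1e-12)
  expect_equal(strain_energy(1.2, 1, nh), 0.67222, tolerance = 1e-5)
  expect_true(all(strain_energy(runif(50, 0.8, 1.5),
                                runif(50, 0.8, 1.5), p) >= 0))
})

test_that("the c2 -> 0 fiber term limit is the quadratic energy", {
  IV <- 1.3  # axial family: IV = lambda_z^2
  W_zero <- strain_energy(1, sqrt(IV),
                          four_fiber_params(0, 5, 0, 0, 0, 0, 0, 45))
  W_near <- strain_energy(1, sqrt(IV),
                          four_fiber_params(0, 5, 1e-10, 0, 0, 0, 0, 45))
  expect_equal(W_zero, 5 / 4 * (IV - 1)^2, tolerance = 1e-8)
  expect_equal(W_near, W_zero, tolerance = 1e-8)
})

test_that("analytic stresses match finite differences of W", {
  p <- default_params()
  expect_equal(as.numeric(model_stresses(1, 1, p)), c(0, 0))
  nh <- four_fiber_params(7, 0, 0, 0, 0, 0, 0, 30)
  expect_equal(model_stresses(1.2, 1, nh)$sigma_theta_kPa,
               7 * (1.44 - 1 / 1.44), tolerance = 1e-12)
  set.seed(21)
  h <- 1e-6
  for (i in 1:20) {
    lt <- runif(1, 0.85, 1.5); lz <- runif(1, 0.85, 1.5)
    s <- model_stresses(lt, lz, p)
    fd_t <- lt * (strain_energy(lt + h, lz, p) -
                  strain_energy(lt - h, lz, p)) / (2 * h)
    fd_z <- lz * (strain_energy(lt, lz + h, p) -
                  strain_energy(lt, lz - h, p)) / (2 * h)
    expect_equal(s$sigma_theta_kPa, fd_t,
                 tolerance = 1e-6 * max(1, abs(fd_t)))
    expect_equal(s$sigma_z_kPa, fd_z,
                 tolerance = 1e-6 * max(1, abs(fd_z)))
  }
})

test_that("analytic stiffness matches finite differences of stresses", {
  nh <- four_fiber_params(9, 0, 0, 0, 0, 0, 0, 45)
  C0 <- linearized_stiffness(1, 1, nh)
  expect_equal(C0$C_tttt_kPa, 4 * 9, tolerance = 1e-10)
  expect_equal(C0$C_zzzz_kPa, 4 * 9, tolerance = 1e-10)
  p <- default_params()
  set.seed(22)
  h <- 1e-6
  for (i in 1:20) {
    lt <- runif(1, 0.85, 1.5); lz <- runif(1, 0.85, 1.5)
    C <- linearized_stiffness(lt, lz, p)
    fd_t <- lt * (model_stresses(lt + h, lz, p)$sigma_theta_kPa -
                  model_stresses(lt - h, lz, p)$sigma_theta_kPa) / (2 * h)
    fd_z <- lz * (model_stresses(lt, lz + h, p)$sigma_z_kPa -
                  model_stresses(lt, lz - h, p)$sigma_z_kPa) / (2 * h)
    expect_equal(C$C_tttt_kPa, fd_t, tolerance = 1e-4 * abs(fd_t))
    expect_equal(C$C_zzzz_kPa, fd_z, tolerance = 1e-4 * abs(fd_z))
  }
})

test_that("circumferential stiffness is non-decreasing in stretch for the
           exponential circumferential family", {
  p <- four_fiber_params(5, 0, 0, 8, 1.5, 0, 0, 45)
  lt <- seq(1.0, 1.5, by = 0.02)
  C <- linearized_stiffness(lt, 1.2, p)$C_tttt_kPa
  expect_true(all(diff(C) > 0))
})

test_that("the diagonal pair is frame-symmetric", {
  # swapping +alpha0 / -alpha0 leaves W, sigma and C unchanged
  p <- default_params()
  q <- p
  q$alpha0_deg <- c(0, 90, -42, 42)
  states <- cbind(runif(10, 0.9, 1.4), runif(10, 0.9, 1.4))
  for (i in 1:10) {
    expect_equal(strain_energy(states[i, 1], states[i, 2], p),
                 strain_energy(states[i, 1], states[i, 2], q))
    expect_equal(model_stresses(states[i, 1], states[i, 2], p),
                 model_stresses(states[i, 1], states[i, 2], q))
    expect_equal(linearized_stiffness(states[i, 1], states[i, 2], p),
                 linearized_stiffness(states[i, 1], states[i, 2], q))
  }
})

test_that("equilibrium pressure/force invert the mean-stress relations", {
  p <- default_params(); g <- default_geom()
  eq0 <- equilibrium_pressure_force(1, 1, p, g)
  expect_equal(eq0$P_Pa, 0, tolerance = 1e-12)
  expect_equal(eq0$f_T_N, 0, tolerance = 1e-12)
  # round trip through mean_stresses
  eq <- equilibrium_pressure_force(1.25, 1.4, p, g)
  s <- mean_stresses(eq$P_Pa, eq$f_T_N, um_to_m(eq$r_i_um),
                     um_to_m(eq$r_o_um))
  sm <- model_stresses(1.25, 1.4, p)
  expect_equal(unname(s[1]) / 1e3, sm$sigma_theta_kPa, tolerance = 1e-10)
  expect_equal(unname(s[2]) / 1e3, sm$sigma_z_kPa, tolerance = 1e-10)
  # pressure strictly increasing in circumferential stretch
  P <- equilibrium_pressure_force(seq(1.0, 1.5, by = 0.02), 1.4, p, g)$P_Pa
  expect_true(all(diff(P) > 0))
})

test_that("stored energy at evaluation pressures round-trips the
           generator's state and grows with pressure", {
  p <- default_params(); g <- default_geom()
  en <- stored_energy_at_pressures(p, g, pressures_mmHg = c(0, 5, 15, 25))
  expect_true(all(en$W_kPa >= 0))
  expect_true(all(diff(en$W_kPa) > 0))
  # the solved state reproduces the requested pressure exactly
  for (i in seq_len(nrow(en))) {
    eq <- equilibrium_pressure_force(en$lambda_theta[i], 1.4, p, g)
    expect_equal(Pa_to_mmHg(eq$P_Pa), en$pressure_mmHg[i],
                 tolerance = 1e-6)
  }
  # energy equals direct evaluation at the same state
  expect_equal(en$W_kPa, strain_energy(en$lambda_theta, 1.4, p),
               tolerance = 1e-6)
  expect_error(stored_energy_at_pressures(p, unloaded_geometry(1, 2, 0.5)),
               "lambda_z_iv")
})
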