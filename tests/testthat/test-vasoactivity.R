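test_that("trace normalization starts at one and is idempotent", {
  tr <- vaso_trace(seq(0, 15, 0.5), rep(800, 31), agent = "KCl")
  n1 <- normalize_trace(tr)
  expect_true(all(n1$normalized == 1))
  tr2 <- vaso_trace(c(0, 5, 15), c(1000, 800, 690), agent = "PE")
  n2 <- normalize_trace(tr2)
  expect_equal(n2$normalized[3], 0.69)
  # idempotent: normalizing the normalized diameters changes nothing
  tr3 <- vaso_trace(c(0, 5, 15), n2$normalized, agent = "PE")
  expect_equal(normalize_trace(tr3)$normalized, n2$normalized)
  expect_error(vaso_trace(c(1, 5), c(100, 90)), "t = 0")
})

test_that("percent change at 15 min reproduces constructed endpoints", {
  tr <- vaso_trace(c(0, 5, 15), c(1000, 800, 690), agent = "KCl")
  expect_equal(percent_change_at(tr, 15), 31)
  flat <- vaso_trace(c(0, 15), c(900, 900), agent = "KCl")
  expect_equal(percent_change_at(flat, 15), 0)
  # closed form of the first-order generator model
  tr2 <- simulate_vaso_trace(900, amplitude = 0.35, tau_min = 2)
  expect_equal(percent_change_at(tr2, 15), 100 * 0.35 * (1 - exp(-7.5)),
               tolerance = 1e-9)
  expect_equal(percent_change_at(tr2, 15), 34.98, tolerance = 1e-3)
  expect_error(percent_change_at(tr2, 20), "outside")
})

test_that("percent change interpolates linearly between samples and is
           scale invariant", {
  tr <- vaso_trace(c(0, 10, 20), c(1000, 900, 700), agent = "PE")
  # t = 15 lies midway between the samples at 900 and 700
  expect_equal(percent_change_at(tr, 15), 100 * (1 - 800 / 1000))
  tr_scaled <- vaso_trace(c(0, 10, 20), 2.5 * c(1000, 900, 700),
                          agent = "PE")
  expect_equal(percent_change_at(tr_scaled, 15), percent_change_at(tr, 15))
  # monotone decreasing trace: percent change non-decreasing in t
  tr3 <- simulate_vaso_trace(900, 0.3, 3)
  pc <- sapply(seq(0, 15, 0.5), function(t) percent_change_at(tr3, t))
  expect_true(all(diff(pc) >= 0))
})

test_that("group summary averages traces and reports SEM", {
  mk <- function(d0, id, grp)
    simulate_vaso_trace(d0, 0.3, 2, vessel_id = id, group = grp)
  tr <- list(mk(900, "a", "g1"), mk(900, "b", "g1"),
             mk(800, "c", "g2"), mk(1000, "d", "g2"))
  gs <- group_response_summary(tr)
  g1 <- gs$time_course[gs$time_course$group == "g1", ]
  expect_true(all(g1$sem_normalized == 0))      # identical traces
  g2 <- gs$time_course[gs$time_course$group == "g2", ]
  # normalized traces are identical regardless of baseline diameter
  expect_equal(g2$mean_normalized, g1$mean_normalized)
  expect_equal(nrow(gs$endpoints), 4)
  expect_error(group_response_summary(list(mk(900, "a", "g1"),
                                           mk(900, "b", "g2"))),
               "at least 2")
})

test_that("group endpoint means cover the generator truth", {
  # simulated cohorts with per-vessel amplitude variation: the group mean
  # endpoint should lie within 2 SEM of the realized-truth mean in most
  # replicates (nominal ~95% coverage)
  set.seed(9)
  R <- 40; covered <- 0
  for (r in 1:R) {
    A <- rnorm(6, 0.35, 0.03)
    tr <- lapply(1:6, function(i)
      simulate_vaso_trace(900, A[i], 2, noise_sd = 0.005,
                          seed = r * 100 + i,
                          vessel_id = paste0("v", i), group = "g"))
    B <- rnorm(6, 0.28, 0.03)
    tr2 <- lapply(1:6, function(i)
      simulate_vaso_trace(900, B[i], 2, noise_sd = 0.005,
                          seed = r * 100 + 50 + i,
                          vessel_id = paste0("w", i), group = "h"))
    ep <- group_response_summary(c(tr, tr2))$endpoints
    m <- mean(ep$percent_change[ep$group == "g"])
    s <- sd(ep$percent_change[ep$group == "g"]) / sqrt(6)
    truth <- 100 * mean(A) * (1 - exp(-15 / 2))
    if (abs(m - truth) <= 2 * s) covered <- covered + 1
  }
  expect_gte(covered / R, 0.9)
})
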