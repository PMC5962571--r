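test_that("transcription rate follows the half-open high windows", {
  sic1 <- g1s_model()$genes$SIC1
  expect_equal(transcription_rate(sic1, 120), 22.15)   # inside 118.09-124.05
  expect_equal(transcription_rate(sic1, 60), 1.72)
  expect_equal(transcription_rate(sic1, 118.09), 22.15)  # start included
  expect_equal(transcription_rate(sic1, 124.05), 1.72)   # end excluded
  expect_equal(transcription_rate(sic1, 120 + 129), 22.15)  # periodic
  cln2 <- g1s_model()$genes$CLN2
  expect_equal(transcription_rate(cln2, c(25, 80, 121)), c(4.4, 0.02, 4.4))
})

test_that("relative promoter activity matches the shipped constants", {
  m <- g1s_model()
  expect_equal(promoter_activity(m$genes$SIC1), 100 * 1.72 / 22.15)
  expect_equal(round(promoter_activity(m$genes$SIC1), 1), 7.8)
  expect_equal(round(promoter_activity(m$genes$CLB5)), 15)
  g <- constant_gene(k = 3)
  expect_equal(promoter_activity(g), 100)
  g0 <- gene_params("Z", 0, 0, 0.5, c(1, 2))
  expect_error(promoter_activity(g0), "k_high")
})

test_that("mean trajectory reaches k/p under a constant rate and decays at k = 0", {
  g <- constant_gene(k = 5, p = 0.5)
  m <- mean_trajectory(g, c(0, 50), m0 = 0)
  expect_equal(m[2], 5 / 0.5, tolerance = 1e-9)
  sic1 <- g1s_model()$genes$SIC1
  expect_equal(sic1$k_low / sic1$p, 1.72 / 0.56)  # basal level ~3.07
  dead <- gene_params("DEAD", 0, 0, 0.3, c(1, 2))
  tg <- seq(0, 10, by = 0.5)
  expect_equal(mean_trajectory(dead, tg, m0 = 5), 5 * exp(-0.3 * tg),
               tolerance = 1e-9)
})

test_that("closed-form mean matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  sic1 <- g1s_model()$genes$SIC1
  tg <- seq(118.09, 124.05, by = 0.01)
  m0 <- sic1$k_low / sic1$p
  ours <- mean_trajectory(sic1, tg, m0 = m0)
  ode <- deSolve::ode(y = c(m = m0), times = tg, parms = NULL,
                      func = function(t, y, parms)
                        list(transcription_rate(sic1, t) - sic1$p * y),
                      method = "rk4")
  expect_equal(ours, unname(ode[, "m"]), tolerance = 1e-5)
  expect_equal(ours[length(ours)], 38.25, tolerance = 0.01)  # end of window
  # a multi-window gene across a cycle boundary
  cln2 <- g1s_model()$genes$CLN2
  tg2 <- seq(100, 170, by = 0.05)
  ours2 <- mean_trajectory(cln2, tg2, m0 = 2)
  # adaptive integrator: fixed-step RK lands stage evaluations across the
  # rate discontinuities at the window edges
  ode2 <- deSolve::ode(y = c(m = 2), times = tg2, parms = NULL,
                       func = function(t, y, parms)
                         list(transcription_rate(cln2, t) - cln2$p * y),
                       method = "lsoda", rtol = 1e-10, atol = 1e-10)
  expect_equal(ours2, unname(ode2[, "m"]), tolerance = 1e-6)
})

test_that("iterating cycles converges geometrically to the periodic mean", {
  for (g in g1s_model()$genes) {
    T <- g$cycle_length
    m_star <- periodic_mean(g, 0)
    # propagate arbitrary starts over successive cycles
    for (m0 in c(0, 25)) {
      errs <- numeric(4)
      m <- m0
      for (cyc in 1:4) {
        m <- mean_trajectory(g, c(0, T), m0 = m)[2]
        errs[cyc] <- abs(m - m_star)
      }
      expect_lt(errs[4], 1e-6 + errs[1] * exp(-g$p * T * 2))
      # contraction factor per cycle is exp(-p T) (checkable only while the
      # error is still representable)
      if (errs[2] > 1e-14)
        expect_equal(errs[2] / errs[1], exp(-g$p * T), tolerance = 1e-3)
    }
  }
})

test_that("phase distributions are proper pmfs with the mixture identities", {
  m <- g1s_model()
  pm <- m$phase_map
  for (g in m$genes) {
    for (ph in pm$phase_names) {
      pmf <- phase_count_distribution(g, pm, ph, n_max = 150)
      expect_equal(sum(pmf), 1, tolerance = 1e-12)
      expect_true(all(pmf >= 0))
      counts <- as.numeric(names(pmf))
      mu_pmf <- sum(counts * pmf)
      # law of total expectation: pmf mean = time-average of m(t)
      iv <- phase_interval(ph, pm)
      tt <- seq(iv[["start"]], iv[["end"]], length.out = 4001)
      mu_time <- mean(periodic_mean(g, pmin(tt, iv[["end"]] - 1e-9)))
      expect_equal(mu_pmf, mu_time, tolerance = 2e-3)
      # Poisson mixtures are over-dispersed
      v_pmf <- sum(counts^2 * pmf) - mu_pmf^2
      expect_gte(v_pmf, mu_pmf - 1e-6)
    }
  }
})

test_that("a time-homogeneous gene gives the plain Poisson law in every phase", {
  g <- constant_gene(k = 4, p = 0.8)
  pm <- default_phase_map()
  for (ph in c("eG1", "G2", "T/C")) {
    pmf <- phase_count_distribution(g, pm, ph, n_max = 60)
    expect_equal(unname(pmf[1:40]), dpois(0:39, 4 / 0.8), tolerance = 1e-10)
  }
  expect_error(phase_count_distribution(g, pm, "eG1", n_max = -1), "n_max")
})
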