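test_that("zero repression leaves the schedule untouched", {
  g <- toy_gene()
  for (onset in c(0, 33.3, 55, 100, 128.9)) {
    sch <- apply_stress_schedule(g, onset, t_d = 0, horizon = 200)
    tt <- seq(0.01, 199.9, by = 0.37)
    expect_equal(sched_rate_at(sch, tt), transcription_rate(g, onset + tt))
    expect_equal(sch$freeze, 0)
  }
})

test_that("an interrupted window resumes after repression with its remaining time", {
  g <- toy_gene()                      # high window [50, 70)
  sch <- apply_stress_schedule(g, onset = 60, t_d = 12, horizon = 60)
  # 10 min of the window remained at onset; low until t_d, then 10 min high
  expect_equal(sched_rate_at(sch, c(1, 11.9)), c(0.5, 0.5))
  expect_equal(sched_rate_at(sch, c(12.01, 21.9)), c(8, 8))
  expect_equal(sched_rate_at(sch, 22.1), 0.5)
  expect_equal(sch$freeze, 12)
  # repression hitting only low-rate time defers by the trapped window part
  sch2 <- apply_stress_schedule(g, onset = 40, t_d = 12, horizon = 60)
  # clock advances 10 min of low, freezes at the window start for 2 min
  expect_equal(sch2$freeze, 2)
  expect_equal(sched_rate_at(sch2, c(11, 12.5, 31.5, 32.5)),
               c(0.5, 8, 8, 0.5))     # window plays [12, 32)
})

test_that("scheduled high-expression exposure is conserved for any onset and t_d", {
  g <- toy_gene()
  set.seed(14)
  dt <- 0.01
  for (rep in 1:12) {
    onset <- runif(1, 0, 129)
    t_d <- runif(1, 0, 30)
    H <- 180
    sch <- apply_stress_schedule(g, onset, t_d, horizon = H)
    tt <- seq(dt / 2, H - dt / 2, by = dt)
    high_stressed <- sum(sched_rate_at(sch, tt) == g$k_high) * dt
    # oracle: the clock progresses H - freeze minutes of the unstressed
    # schedule, whose high exposure is integrated directly
    tt2 <- seq(dt / 2, H - sch$freeze - dt / 2, by = dt)
    high_unstressed <- sum(transcription_rate(g, onset + tt2) == g$k_high) * dt
    expect_equal(high_stressed, high_unstressed, tolerance = 0.05)
  }
})

test_that("distribution distance is zero at identity, 2 for disjoint groups, and matches a naive loop", {
  mk <- function(histlist) structure(histlist, bin_max = 30,
                                     class = "stress_distributions")
  h <- function(...) {
    v <- rep(0L, 32); x <- list(...)
    for (i in seq_along(x)) v[x[[i]][1] + 1L] <- x[[i]][2]
    v
  }
  a <- mk(list("0" = list(G = list(eG1 = h(c(0, 10), c(3, 5))))))
  expect_equal(distribution_distance(a, a), 0)
  b <- mk(list("0" = list(G = list(eG1 = h(c(0, 8))))))
  d <- mk(list("0" = list(G = list(eG1 = h(c(5, 4))))))
  expect_equal(distribution_distance(b, d), 2)   # disjoint single bins
  # random histograms against a brute-force double loop
  set.seed(3)
  rnd <- function() mk(list(
    "0" = list(G1 = list(eG1 = rpois(32, 3), S = rpois(32, 1)),
               G2 = list(eG1 = rpois(32, 2))),
    "15" = list(G1 = list(lG1 = rpois(32, 4)),
                G2 = list(eG1 = rpois(32, 1) + 1L))))
  s <- rnd(); o <- rnd()
  oracle <- 0
  for (tm in names(o)) for (g in names(o[[tm]])) for (ph in names(o[[tm]][[g]])) {
    fo <- o[[tm]][[g]][[ph]] / sum(o[[tm]][[g]][[ph]])
    hs <- s[[tm]][[g]][[ph]]
    fs <- if (is.null(hs)) 0 * fo else hs / sum(hs)
    for (bin in seq_along(fo)) oracle <- oracle + (fs[bin] - fo[bin])^2
  }
  expect_equal(distribution_distance(s, o), oracle, tolerance = 1e-12)
  # mismatched keys must fail loudly
  expect_error(distribution_distance(
    mk(list("0" = list(G1 = list(eG1 = h(c(0, 1)))))),
    mk(list("15" = list(G1 = list(eG1 = h(c(0, 1))))))), "times")
  expect_error(distribution_distance(
    mk(list("0" = list(G1 = list(eG1 = h(c(0, 1)))))),
    mk(list("0" = list(G2 = list(eG1 = h(c(0, 1))))))), "gene")
})

test_that("unstressed limit: t_d = 0 reproduces the asynchronous distributions", {
  m <- g1s_model()
  cfg <- stress_config(c(CLN2 = 0, CLB5 = 0), n_onsets = 600)
  tabs <- simulate_stress_population(m, cfg, n_cells = 600, seed = 8)
  ref <- generate_cell_table(m, n_cells = 6000, seed = 9)
  for (g in names(m$genes)) {
    for (tm in c("0", "45")) {
      p <- chisq_two_sample_pvalue(tabs[[tm]]$count[tabs[[tm]]$gene == g],
                                   ref$count[ref$gene == g])
      expect_gt(p, 0.001)
    }
  }
})

test_that("repression depresses the cyclins at 15 min and spares SIC1", {
  m <- g1s_model()
  cfg <- stress_config(c(CLN2 = 28, CLB5 = 12), n_onsets = 500)
  tabs <- simulate_stress_population(m, cfg, n_cells = 500, seed = 18)
  mu <- function(tm, g) mean(tabs[[tm]]$count[tabs[[tm]]$gene == g])
  expect_lt(mu("15", "CLN2"), 0.6 * mu("0", "CLN2"))
  # CLB5 (short t_d, fast turnover) shows its depletion phase-resolved:
  # S-labeled cells carry far fewer transcripts during/after repression
  muS <- function(tm) mean(tabs[[tm]]$count[tabs[[tm]]$gene == "CLB5" &
                                              tabs[[tm]]$phase == "S"])
  expect_lt(muS("30"), 0.5 * muS("0"))
  expect_gt(mu("90", "CLN2"), 0.7 * mu("0", "CLN2"))   # recovery
  expect_lt(abs(mu("15", "SIC1") - mu("0", "SIC1")), 0.2 * mu("0", "SIC1"))
  expect_identical(tabs, simulate_stress_population(m, cfg, n_cells = 500,
                                                    seed = 18))
})

test_that("a single-point grid is returned as-is and the search is seed-stable", {
  m <- g1s_model()
  cfg <- stress_config(c(CLN2 = 10, CLB5 = 10), n_onsets = 80)
  obs <- stress_histograms(simulate_stress_population(m, cfg, n_cells = 80,
                                                      seed = 21))
  gs <- grid_search_td(obs, m, grid = list(CLN2 = 10, CLB5 = 10),
                       n_sims = 40, seed = 22)
  expect_equal(unname(gs$best), c(10, 10))
  expect_equal(nrow(gs$surface), 1L)
  gs2 <- grid_search_td(obs, m, grid = list(CLN2 = c(8, 10), CLB5 = 12),
                        n_sims = 40, seed = 22)
  gs3 <- grid_search_td(obs, m, grid = list(CLN2 = c(8, 10), CLB5 = 12),
                        n_sims = 40, seed = 22)
  expect_identical(gs2$surface, gs3$surface)
})
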