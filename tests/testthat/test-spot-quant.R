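test_that("median normalization calls molecules as intensity ratios", {
  sp <- data.frame(spot_id = 1:4, cell_id = c(1, 1, 2, 2), gene = "G",
                   intensity = c(7, 7, 7, 21), nuclear = FALSE)
  mol <- molecules_per_spot(sp, "G")
  expect_identical(mol$molecules, c(1L, 1L, 1L, 3L))     # median = 7
  sp$intensity <- rep(5, 4)
  expect_true(all(molecules_per_spot(sp, "G")$molecules == 1L))
  expect_error(molecules_per_spot(sp, "H"), "no spots")
})

test_that("molecule calls are scale-invariant and idempotent under renormalization", {
  set.seed(5)
  sp <- data.frame(spot_id = 1:400, cell_id = rep(1:80, 5), gene = "G",
                   intensity = rlnorm(400, 0, 0.3) *
                     sample(c(1, 1, 1, 1, 3, 5), 400, replace = TRUE),
                   nuclear = sample(c(TRUE, FALSE), 400, replace = TRUE))
  base <- molecules_per_spot(sp, "G")$molecules
  for (c0 in c(0.01, 3.7, 1e4)) {
    sp2 <- sp; sp2$intensity <- sp$intensity * c0
    expect_identical(molecules_per_spot(sp2, "G")$molecules, base)
  }
  sp3 <- sp; sp3$intensity <- sp$intensity / median(sp$intensity)
  expect_identical(molecules_per_spot(sp3, "G")$molecules, base)
})

test_that("modest lognormal noise keeps most single molecules called as singles", {
  set.seed(6)
  n <- 5000
  truth <- sample(c(1L, 3L), n, replace = TRUE, prob = c(0.9, 0.1))
  sp <- data.frame(spot_id = seq_len(n), cell_id = rep(1:500, 10), gene = "G",
                   intensity = truth * rlnorm(n, 0, 0.2), nuclear = FALSE)
  mol <- molecules_per_spot(sp, "G")
  expect_gte(mean(mol$molecules[truth == 1L] == 1L), 0.88)
})

test_that("transcription sites require nuclear spots with at least 3 molecules", {
  sp <- data.frame(
    spot_id = 1:6,
    cell_id = c(1, 1, 2, 3, 3, 4),
    gene = "G",
    intensity = c(1, 3, 10, 4, 5, 2.9),
    nuclear = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  # median intensity 3.5 would break the unit anchor; use explicit singles
  sp <- rbind(sp, data.frame(spot_id = 7:16, cell_id = 5, gene = "G",
                             intensity = 1, nuclear = FALSE))
  ts <- call_transcription_sites(sp, "G")
  get <- function(cl) ts$ts[ts$cell_id == cl]
  expect_identical(get(1), 1L)   # nuclear 3-molecule spot -> TS
  expect_identical(get(2), 0L)   # bright but cytoplasmic
  expect_identical(get(3), 2L)   # two nuclear spots of 4 and 5 molecules
  expect_identical(get(4), 1L)   # 2.9 rounds to 3
})

test_that("quantified cell tables aggregate molecules per cell", {
  set.seed(9)
  phases <- data.frame(cell_id = 1:6,
                       phase = c("eG1", "eG1", "lG1", "S", "Ana", "T/C"))
  sp <- data.frame(spot_id = 1:9,
                   cell_id = c(1, 1, 1, 2, 3, 3, 5, 5, 5),
                   gene = "G",
                   intensity = c(1, 1, 3, 1, 1, 1, 1, 4, 1),
                   nuclear = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                               FALSE, TRUE, FALSE))
  tab <- quantify_cells(sp, phases)
  expect_s3_class(tab, "cell_table")
  cnt <- setNames(tab$count, tab$cell_id)
  expect_identical(cnt[["1"]], 5L)   # 1 + 1 + 3
  expect_identical(cnt[["2"]], 1L)
  expect_identical(cnt[["4"]], 0L)   # listed cell without spots
  expect_identical(cnt[["5"]], 6L)
  expect_identical(tab$ts[tab$cell_id == 1], 1L)
  expect_identical(tab$ts[tab$cell_id == 5], 1L)
})

test_that("phase summaries match hand arithmetic and a naive recomputation", {
  tab <- as_cell_table(data.frame(cell_id = 1:3, phase = "S", gene = "G",
                                  count = c(0L, 1L, 2L)))
  s <- phase_summary(tab)
  expect_equal(s$mean, 1)
  expect_equal(s$cv, 1)
  expect_equal(s$frac_expressing, 2 / 3)
  expect_equal(s$sem, 1 / sqrt(3))
  # 50-cell fixture against a direct spreadsheet-style recomputation
  set.seed(11)
  fx <- as_cell_table(data.frame(
    cell_id = 1:50,
    phase = sample(c("eG1", "lG1", "G2"), 50, replace = TRUE),
    gene = sample(c("A", "B"), 50, replace = TRUE),
    count = rpois(50, 4)))
  s2 <- phase_summary(fx)
  expect_equal(sum(s2$n), 50)
  for (r in seq_len(nrow(s2))) {
    v <- fx$count[fx$phase == s2$phase[r] & fx$gene == s2$gene[r]]
    expect_equal(s2$mean[r], sum(v) / length(v))
    expect_equal(s2$sd[r], sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
    expect_equal(s2$median[r], median(v))
    expect_equal(s2$frac_expressing[r], mean(v >= 1))
  }
  # Poisson counts approach the lambda^{-1/2} noise law
  set.seed(12)
  big <- as_cell_table(data.frame(cell_id = 1:20000, phase = "G2",
                                  gene = "A", count = rpois(20000, 9)))
  expect_equal(phase_summary(big)$cv, 1 / 3, tolerance = 0.03)
  expect_error(phase_summary(as_cell_table(
    data.frame(cell_id = 1, phase = "eG1", gene = "A", count = 1L))[0, ]),
    NA)  # empty table is fine (no rows, no groups)
})
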