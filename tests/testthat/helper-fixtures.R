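# shared fixtures: small kinetic models and comparison helpers

derive_seed_test <- cycleFISH:::derive_seed

# a gene with equal high/low rates: counts are Poisson(k/p) in every phase
constant_gene <- function(k = 5, p = 0.5, name = "CONST") {
  gene_params(name, k_high = k, k_low = k, p = p, windows = c(10, 20))
}

# single-gene toy model with one sharp window
toy_gene <- function() gene_params("TOY", 8, 0.5, 0.4, c(50, 70))

toy_model <- function(map = default_phase_map()) {
  model_spec(list(toy_gene()), map)
}

# rate of a piecewise schedule list(breaks, rates) at times t (right-open)
sched_rate_at <- function(sched, t) {
  i <- findInterval(t, sched$breaks)
  i[i < 1L] <- 1L
  sched$rates[i]
}

# greedily pool adjacent bins so every group's reference mass is >= target
pool_bins <- function(ref, target = 5) {
  g <- integer(length(ref)); gid <- 1L; acc <- 0
  for (b in seq_along(ref)) {
    g[b] <- gid
    acc <- acc + ref[b]
    if (acc >= target) { gid <- gid + 1L; acc <- 0 }
  }
  gid <- max(g)
  if (gid > 1L && sum(ref[g == gid]) < target)      # fold a light/empty tail
    g[g == gid] <- gid - 1L
  g
}

# chi-square goodness-of-fit of observed integer counts against a pmf over
# 0..n_max (+tail), with adjacent bins pooled to expected >= 5
chisq_gof_pvalue <- function(counts, pmf) {
  n_max <- length(pmf) - 1L
  obs <- tabulate(pmin(counts, n_max) + 1L, nbins = n_max + 1L)
  expd <- pmf * length(counts)
  g <- pool_bins(expd, 5)
  O <- tapply(obs, g, sum)
  E <- tapply(expd, g, sum)
  if (length(E) < 2) return(1)
  stat <- sum((O - E)^2 / E)
  pchisq(stat, df = length(E) - 1L, lower.tail = FALSE)
}

# two-sample chi-square on pooled count histograms
chisq_two_sample_pvalue <- function(x, y, bin_max = 30) {
  bx <- tabulate(pmin(x, bin_max) + 1L, nbins = bin_max + 1L)
  by <- tabulate(pmin(y, bin_max) + 1L, nbins = bin_max + 1L)
  g <- pool_bins(bx + by, 10)
  O <- rbind(tapply(bx, g, sum), tapply(by, g, sum))
  if (ncol(O) < 2) return(1)
  suppressWarnings(chisq.test(O)$p.value)
}
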