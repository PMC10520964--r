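# Independent oracles used to cross-check package routines.

# Kruskal-Wallis H from the raw rank-sum formula with midranks and the
# standard tie correction (independent of stats::kruskal.test).
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Upper-tail hypergeometric probability by exact enumeration over all
# possible overlaps (binomial coefficients only; valid for small N).
hyper_enum <- function(N, K, n, k) {
  ks <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}

# Two-female fixture in the long CSV layout.
fixture_cohort_df <- function() {
  data.frame(
    female_id = c("f1", "f1", "f2"),
    generation = c("F1", "F1", "F2"),
    rearing_temperature_C = c(5, 5, 15),
    lifespan_days = c(100, 100, 60),
    n_molts = c(3, 3, 2),
    clutch_index = c(1, 2, NA),
    oviposition_day = c(34, 48, NA),
    eggs_laid = c(3, 4, NA),
    eggs_hatched = c(2, 3, NA),
    hatching_times = c("20;22", "21;23;25", ""),
    stringsAsFactors = FALSE
  )
}

# Small single-exposure expression design: 4 temperatures x 3 replicates.
small_expression_config <- function(...) {
  expression_config(exposures = "ST", ...)
}
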