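# shared simulation helpers; everything is generated in code at test time

# fully invariant multi-group dataset from the DHS-like preset
make_invariant_sim <- function(item_set = "physical_ipv", G = 6, n_g = 600,
                               seed = 1, alpha = NULL) {
  spec <- dhs_like_preset(item_set, G = G, n_g = n_g, alpha = alpha)
  generate_responses(spec, seed = seed)
}

# independent grid-search oracle for the tetrachoric correlation:
# coarse pass at 1e-3 then local refinement to 1e-5 (pure enumeration,
# no shared code with the package's optimizer path)
grid_tetrachoric <- function(cells) {
  if (any(cells == 0)) cells <- cells + 0.5
  n <- sum(cells)
  p1 <- (cells[1] + cells[2]) / n
  p2 <- (cells[1] + cells[3]) / n
  t1 <- qnorm(1 - p1); t2 <- qnorm(1 - p2)
  ll <- function(r) {
    p11 <- mvtnorm::pmvnorm(upper = c(-t1, -t2),
                            corr = matrix(c(1, r, r, 1), 2))[1]
    pr <- pmax(c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11), 1e-12)
    sum(cells * log(pr))
  }
  coarse <- seq(-0.999, 0.999, by = 1e-3)
  v <- vapply(coarse, ll, numeric(1))
  best <- coarse[which.max(v)]
  fine <- seq(max(-0.9999, best - 2e-3), min(0.9999, best + 2e-3), by = 1e-5)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# pooled flag precision/recall over 20 seeded runs with injected
# non-invariance (6 of 80 cells, n_g = 2000); computed once and cached, as
# both the alignment suite and the acceptance suite assert on it
flag_accuracy_pooled <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tp <- fp <- fn_ <- 0
    for (run in 1:20) {
      spec <- dhs_like_preset("controlling", G = 8, n_g = 2000)
      spec <- inject_noninvariance(spec, items = 1:2, groups = 3,
                                   threshold_delta = 1.0)
      spec <- inject_noninvariance(spec, items = 4:5, groups = 6,
                                   threshold_delta = -0.8)
      spec <- inject_noninvariance(spec, items = 3, groups = c(2, 7),
                                   loading_delta = 1.2)
      sim <- generate_responses(spec, seed = 1000 + run)
      conf <- fit_multigroup(sim$table, "configural")
      sol <- flag_invariance(align_groups(conf, seed = run),
                             alpha_level = 0.01)
      flags <- cbind(sol$flag_threshold, sol$flag_loading)
      truthm <- cbind(spec$noninv_threshold, spec$noninv_loading)
      tp <- tp + sum(flags & truthm)
      fp <- fp + sum(flags & !truthm)
      fn_ <- fn_ + sum(!flags & truthm)
    }
    cache <<- list(precision = tp / (tp + fp), recall = tp / (tp + fn_))
    cache
  }
})

# independent enumeration oracle for the Wilcoxon signed-rank test
enum_wilcoxon <- function(a, b, alternative = "two.sided") {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = NA_real_, p = 1))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  m <- 2^n
  Vnull <- numeric(m)
  for (k in 0:(m - 1)) {
    signs <- as.integer(intToBits(k))[1:n]
    Vnull[k + 1] <- sum(r[signs == 1])
  }
  mu <- sum(r) / 2
  p <- switch(alternative,
              greater = mean(Vnull >= V),
              less = mean(Vnull <= V),
              two.sided = min(1, 2 * (if (V > mu) mean(Vnull >= V)
                                      else mean(Vnull <= V))))
  list(statistic = V, p = p)
}
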