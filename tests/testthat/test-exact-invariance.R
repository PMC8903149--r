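sim6 <- make_invariant_sim(G = 6, n_g = 600, seed = 3)
ladder6 <- invariance_ladder(sim6$table)

test_that("log-likelihoods nest across the invariance ladder", {
  expect_gte(ladder6$configural$loglik + 1e-6, ladder6$metric$loglik)
  expect_gte(ladder6$metric$loglik + 1e-6, ladder6$scalar$loglik)
  # parameter counts strictly decrease
  expect_gt(ladder6$configural$n_par, ladder6$metric$n_par)
  expect_gt(ladder6$metric$n_par, ladder6$scalar$n_par)
})

test_that("constraint patterns hold exactly in the fitted parameters", {
  m <- ladder6$metric
  lam <- sapply(m$params, `[[`, "lambda")
  expect_equal(max(apply(lam, 1, function(x) diff(range(x)))), 0)
  expect_true(all(sapply(m$params, `[[`, "alpha") == 0))
  expect_equal(m$params[[1]]$psi, 1)

  s <- ladder6$scalar
  tau <- sapply(s$params, `[[`, "tau")
  expect_equal(max(apply(tau, 1, function(x) diff(range(x)))), 0)
  expect_equal(s$params[[1]]$alpha, 0)
})

test_that("df arithmetic equals the closed-form constraint count for any J, G", {
  for (J in c(3, 5, 7)) {
    for (G in c(2, 6, 36)) {
      n_conf <- 2 * J * G
      n_met <- J + J * G + (G - 1)
      n_scal <- 2 * J + 2 * (G - 1)
      expect_equal(n_conf - n_met, (G - 1) * J - (G - 1))
      expect_equal(n_met - n_scal, (G - 1) * J - (G - 1))
    }
  }
  # and the fitted objects agree with the closed forms (J = 7, G = 6)
  expect_equal(ladder6$configural$n_par, 84)
  expect_equal(ladder6$metric$n_par, 7 + 42 + 5)
  expect_equal(ladder6$scalar$n_par, 14 + 10)
})

test_that("likelihood-ratio tests compute chisq, df, and p correctly", {
  t1 <- ladder6$test_metric
  expect_equal(t1$chisq,
               2 * (ladder6$configural$loglik - ladder6$metric$loglik),
               tolerance = 1e-8)
  expect_gte(t1$chisq, 0)
  expect_equal(t1$df, 30)

  # identical fits: chisq 0, p 1
  same <- list(loglik = -100, n_par = 20, level = "configural")
  t0 <- lr_test(same, list(loglik = -100, n_par = 10, level = "metric"))
  expect_equal(t0$chisq, 0)
  expect_equal(t0$p_value, 1)

  # published parameter counts give df = 175
  t_pub <- lr_test(list(loglik = -462468.524, n_par = 539, level = "configural"),
                   list(loglik = -463664.754, n_par = 364, level = "metric"))
  expect_equal(t_pub$df, 175)

  # misordered or non-nested input is a usage error
  expect_error(lr_test(list(loglik = -1, n_par = 10, level = "scalar"),
                       list(loglik = -1, n_par = 5, level = "metric")),
               "less constrained")
  expect_error(lr_test(list(loglik = -1, n_par = 5),
                       list(loglik = -1, n_par = 5)), "not nested")
})

test_that("fully invariant data attains scalar; injected loading shifts break metric", {
  expect_equal(ladder6$highest_level, "scalar")
  expect_gt(ladder6$test_metric$p_value, 0.05)

  spec <- dhs_like_preset("controlling", G = 4, n_g = 2000)
  spec <- inject_noninvariance(spec, items = 1:2, groups = 3:4,
                               loading_delta = 1.0)
  sim_ni <- generate_responses(spec, seed = 17)
  lad_ni <- invariance_ladder(sim_ni$table)
  expect_lt(lad_ni$test_metric$p_value, 0.001)
  expect_equal(lad_ni$highest_level, "configural")
})

test_that("scalar fit recovers the shared generating parameters", {
  spec <- dhs_like_preset("controlling", G = 6, n_g = 2000)
  sim <- generate_responses(spec, seed = 23)
  scal <- fit_multigroup(sim$table, "scalar")
  expect_true(scal$converged)
  # shared items: loose 3-SE-scale tolerance at n_g = 2000
  expect_lt(max(abs(scal$params[[1]]$lambda - spec$lambda[, 1])), 0.15)
  expect_lt(max(abs(scal$params[[1]]$tau - spec$tau[, 1])), 0.15)
  # group factor means track the generating spread
  a_est <- sapply(scal$params, `[[`, "alpha")
  expect_gt(cor(a_est, spec$alpha), 0.95)
})

test_that("a single-group configural fit reduces to the one-group model", {
  one <- sim6$table[sim6$table$group == "G01", , drop = FALSE]
  class(one) <- class(sim6$table)
  fit1 <- fit_multigroup(one, "configural", stabilize = FALSE)
  expect_equal(fit1$G, 1)
  expect_equal(fit1$n_par, 14)
  # against an independent direct optimization of the same marginal likelihood
  items <- item_names(one)
  pat <- ipvalign:::collapse_patterns(as.matrix(one[items]), one$weight)
  nll <- function(p) {
    eta <- sqrt(2) * statmod::gauss.quad(21, "hermite")$nodes
    w <- statmod::gauss.quad(21, "hermite")$weights / sqrt(pi)
    z <- outer(p[1:7], eta) - p[8:14]
    P <- pmin(pmax(pnorm(z), 1e-14), 1 - 1e-14)
    like <- exp(pat$Y1 %*% log(P) + pat$Y0 %*% log(1 - P))
    -sum(pat$w * log(pmax(as.vector(like %*% w), 1e-300)))
  }
  par_pkg <- c(fit1$params[[1]]$lambda, fit1$params[[1]]$tau)
  # the independently coded marginal likelihood agrees at the fitted values
  expect_equal(-nll(par_pkg), fit1$loglik, tolerance = 1e-6)
  # and derivative-free search started there finds no material improvement
  direct <- optim(par_pkg, nll, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-12))
  expect_lt(-direct$value - fit1$loglik, 0.01)
})

test_that("quadrature refinement barely changes the log-likelihood", {
  cfg21 <- pipeline_config(n_quad = 21)
  cfg41 <- pipeline_config(n_quad = 41)
  f21 <- fit_multigroup(sim6$table, "configural", cfg21, stabilize = FALSE)
  f41 <- fit_multigroup(sim6$table, "configural", cfg41, stabilize = FALSE)
  expect_lt(abs(f21$loglik - f41$loglik) / nrow(sim6$table), 1e-3)
})

test_that("the logit link recovers parameters after the scale conversion", {
  spec <- generation_spec(G = 1, n_g = 5000, lambda = rep(1, 5),
                          tau = rep(0.5, 5))
  sim <- generate_responses(spec, seed = 29)
  f_probit <- fit_multigroup(sim$table, "configural", stabilize = FALSE)
  f_logit <- fit_multigroup(sim$table, "configural",
                            pipeline_config(link = "logit"), stabilize = FALSE)
  ratio <- f_logit$params[[1]]$lambda / f_probit$params[[1]]$lambda
  expect_true(all(ratio > 1.4 & ratio < 2.0))
})
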