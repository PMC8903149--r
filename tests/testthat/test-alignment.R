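# small invariant configural fit shared across blocks
sim_al <- make_invariant_sim(G = 6, n_g = 800, seed = 42,
                             alpha = c(0, -0.8, -0.3, 0.1, 0.4, 0.8))
conf_al <- fit_multigroup(sim_al$table, "configural")
sol_al <- flag_invariance(align_groups(conf_al, seed = 7), alpha_level = 0.01)

test_that("the component loss matches its closed form and symmetry", {
  expect_equal(component_loss(0, 1e-4), 0.1)
  expect_equal(component_loss(1, 0.01), 1.002491, tolerance = 1e-6)
  x <- seq(-3, 3, by = 0.37)
  expect_equal(component_loss(x, 0.01), component_loss(-x, 0.01))
  # strictly increasing in |x|
  expect_true(all(diff(component_loss(seq(0, 5, 0.1), 0.01)) > 0))
  expect_error(component_loss(1, 0), "epsilon")
})

test_that("total loss at identical configural parameters hits the closed-form floor", {
  J <- 3; G <- 4
  params <- lapply(seq_len(G), function(g)
    list(lambda = c(a = 1.2, b = 0.9, c = 1.5),
         tau = c(a = 0.5, b = 1, c = 1.5), alpha = 0, psi = 1))
  fake <- structure(list(level = "configural", J = J, G = G,
                         groups = paste0("g", 1:G), items = c("a", "b", "c"),
                         n_g = stats::setNames(rep(100, G), paste0("g", 1:G)),
                         params = params, converged = TRUE),
                    class = "ipv_mgfit")
  eps <- 0.01
  got <- total_loss(fake, rep(0, G), rep(1, G), eps)
  want <- J * choose(G, 2) * 100 * 2 * eps^0.25  # all differences zero
  expect_equal(got, want, tolerance = 1e-10)

  # perturbing one group's mean away from the optimum increases the loss
  worse <- total_loss(fake, c(0, 0.5, 0, 0), rep(1, G), eps)
  expect_gt(worse, got)
  expect_error(total_loss(fake, rep(0, G), c(1, -1, 1, 1)), "psi")
})

test_that("a two-group, one-item toy reproduces hand-computed loss", {
  params <- list(list(lambda = c(i = 1.0), tau = c(i = 0.4), alpha = 0, psi = 1),
                 list(lambda = c(i = 1.4), tau = c(i = 0.9), alpha = 0, psi = 1))
  fake <- structure(list(level = "configural", J = 1, G = 2,
                         groups = c("g1", "g2"), items = "i",
                         n_g = c(g1 = 50, g2 = 200), params = params,
                         converged = TRUE),
                    class = "ipv_mgfit")
  alpha <- c(0, 0.3); psi <- c(1, 1.2); eps <- 0.01
  # by hand: w = sqrt(50*200) = 100; aligned values per the transform
  l1 <- 1.0; l2 <- 1.4 / sqrt(1.2)
  n1 <- -0.4; n2 <- -0.9 - 1.4 * 0.3 / sqrt(1.2)
  want <- 100 * (((l1 - l2)^2 + eps)^0.25 + ((n1 - n2)^2 + eps)^0.25)
  expect_equal(total_loss(fake, alpha, psi, eps), want, tolerance = 1e-12)
})

test_that("alignment loss gradient matches numerical differentiation", {
  cm <- ipvalign:::configural_matrices(conf_al)
  obj <- ipvalign:::alignment_objective(cm$lam0, cm$nu0, conf_al$n_g, 1L, 0.01)
  set.seed(99)
  th <- rnorm(10, 0, 0.3)
  expect_equal(obj$gr(th), numDeriv::grad(obj$fn, th), tolerance = 1e-6)
  objq <- ipvalign:::alignment_objective(cm$lam0, cm$nu0, conf_al$n_g, 1L,
                                         0.01, loss = "quadratic")
  expect_equal(objq$gr(th), numDeriv::grad(objq$fn, th), tolerance = 1e-6)
})

test_that("alignment recovers generating factor means and beats the identity transform", {
  truth <- c(0, -0.8, -0.3, 0.1, 0.4, 0.8)
  expect_gt(cor(sol_al$alpha, truth), 0.98)
  expect_equal(unname(sol_al$alpha[1]), 0)   # FIXED reference
  expect_equal(unname(sol_al$psi[1]), 1)
  loss_sol <- total_loss(conf_al, sol_al$alpha, sol_al$psi)
  loss_id <- total_loss(conf_al, rep(0, 6), rep(1, 6))
  expect_lte(loss_sol, loss_id)
})

test_that("two identical groups align to the identity transform", {
  one <- sim_al$table[sim_al$table$group == "G01", , drop = FALSE]
  two <- one
  two$group <- "G02"
  both <- rbind(one, two)
  attr(both, "item_set") <- attr(sim_al$table, "item_set")
  class(both) <- class(sim_al$table)
  conf2 <- fit_multigroup(both, "configural")
  al2 <- align_groups(conf2, seed = 1)
  expect_lt(abs(al2$alpha[2]), 0.02)
  expect_lt(abs(al2$psi[2] - 1), 0.05)
})

test_that("relabelling groups permutes the solution", {
  tab <- sim_al$table
  relab <- c(G01 = "G01", G02 = "G06", G03 = "G05", G04 = "G04",
             G05 = "G03", G06 = "G02")
  tab2 <- tab
  tab2$group <- unname(relab[tab$group])
  attr(tab2, "item_set") <- attr(tab, "item_set")
  class(tab2) <- class(tab)
  conf_b <- fit_multigroup(tab2, "configural")
  al_a <- align_groups(conf_al, reference = "G01", n_starts = 1)
  al_b <- align_groups(conf_b, reference = "G01", n_starts = 1)
  # compare by original group identity
  expect_equal(unname(al_b$alpha[relab[names(al_a$alpha)]]),
               unname(al_a$alpha), tolerance = 1e-3)
})

test_that("the alignment transform preserves response probabilities", {
  eta_star <- seq(-3, 3, length.out = 25)
  for (g in seq_len(conf_al$G)) {
    p_conf <- pnorm(outer(sol_al$lambda0[, g], eta_star) + sol_al$nu0[, g])
    eta_g <- sol_al$alpha[g] + sqrt(sol_al$psi[g]) * eta_star
    p_alig <- pnorm(outer(sol_al$lambda[, g], eta_g) + sol_al$nu[, g])
    expect_lt(max(abs(p_conf - p_alig)), 1e-8)
  }
})

test_that("non-invariance percentages reproduce the published arithmetic exactly", {
  expect_equal(unname(pct_noninvariant(21, 3, 5, 36)), c(11.7, 1.7, 6.7))
  expect_equal(unname(pct_noninvariant(55, 8, 7, 36)[["thresholds"]]), 21.8)
  expect_equal(unname(pct_noninvariant(0, 0, 7, 36)), c(0, 0, 0))
  expect_error(pct_noninvariant(181, 0, 5, 36), "J\\*G")
})

test_that("flagging under full invariance stays near the test size", {
  pct <- sol_al$pct
  expect_lt(pct[["all"]], 25)
  # expected flag rate is about alpha_level; allow generous sampling slack
  expect_lt(pct[["all"]], 10)
  # G = 2 with overlapping intervals: no flags possible
  one <- sim_al$table[sim_al$table$group %in% c("G01", "G04"), , drop = FALSE]
  attr(one, "item_set") <- attr(sim_al$table, "item_set")
  class(one) <- class(sim_al$table)
  confp <- fit_multigroup(one, "configural")
  solp <- flag_invariance(align_groups(confp, seed = 2))
  expect_equal(sum(solp$flag_threshold) + sum(solp$flag_loading), 0)
})

test_that("flagging detects injected non-invariance with good precision and recall", {
  # 6 perturbed cells of 80 (7.5%), threshold and loading shifts, n_g = 2000,
  # pooled over 20 seeded runs
  acc <- flag_accuracy_pooled()
  expect_gte(acc$precision, 0.8)
  expect_gte(acc$recall, 0.8)
})

test_that("R-squared invariance indices behave at their limits", {
  # perfectly invariant parameters with group-varying alpha, psi: R^2 = 1
  J <- 3; G <- 5
  lb <- c(1.2, 0.9, 1.5); nb <- c(-0.5, -1, -1.5)
  alpha <- c(0, -0.5, 0.2, 0.6, -0.2)
  psi <- c(1, 1.3, 0.8, 1.1, 0.9)
  lam0 <- outer(lb, sqrt(psi))
  nu0 <- outer(nb, rep(1, G)) + outer(lb, alpha)
  sol <- structure(list(lambda0 = lam0, nu0 = nu0, alpha = alpha, psi = psi,
                        wavg_loading = lb, wavg_nu = nb),
                   class = "ipv_alignment")
  rownames(sol$lambda0) <- rownames(sol$nu0) <- c("a", "b", "c")
  r2 <- invariance_r2(sol)
  expect_equal(r2$r2_threshold, rep(1, J), tolerance = 1e-10)
  expect_equal(r2$r2_loading, rep(1, J), tolerance = 1e-10)

  # parameters varying independently of alpha, psi: R^2 near 0, floored at 0
  set.seed(12)
  sol$lambda0 <- sol$lambda0 * 0 + lb + matrix(rnorm(J * G, 0, 0.4), J, G)
  sol$nu0 <- sol$nu0 * 0 + nb + matrix(rnorm(J * G, 0, 0.4), J, G)
  r2b <- invariance_r2(sol)
  expect_true(all(r2b$r2_loading >= 0 & r2b$r2_loading <= 1))
  expect_true(all(r2b$r2_loading < 0.6))

  # fitted solution: all indices in [0, 1] (or NA for zero-variance rows)
  ok <- !is.na(unlist(sol_al$r2[-1]))
  vals <- unlist(sol_al$r2[-1])[ok]
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("the Monte-Carlo quality check is reproducible and flags degeneracy", {
  mc1 <- monte_carlo_quality(sol_al, replications = 1, seed = 5, n_starts = 2)
  mc2 <- monte_carlo_quality(sol_al, replications = 1, seed = 5, n_starts = 2)
  expect_equal(mc1$correlations, mc2$correlations)
  expect_gt(mc1$mean_correlation, 0.9)

  sol_deg <- sol_al
  sol_deg$alpha[] <- 0
  mc_deg <- monte_carlo_quality(sol_deg, replications = 1, seed = 5)
  expect_true(is.na(mc_deg$mean_correlation))
  expect_match(mc_deg$note, "degenerate")
})
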