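# Marginal maximum likelihood engine for the two-parameter binary factor
# model. Respondent rows are collapsed to unique response patterns (missing
# positions included in the pattern key) so likelihood cost is independent of
# sample size; the latent trait is integrated out by Gauss-Hermite quadrature.

# collapse a group's response matrix to unique patterns with summed weights
collapse_patterns <- function(y, w) {
  key <- apply(y, 1L, function(r) paste(ifelse(is.na(r), "m", r), collapse = ""))
  idx <- split(seq_along(key), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  Y <- y[first, , drop = FALSE]
  list(Y1 = ifelse(is.na(Y), 0, Y == 1) * 1,
       Y0 = ifelse(is.na(Y), 0, Y == 0) * 1,
       w = vapply(idx, function(i) sum(w[i]), numeric(1)))
}

gh_rule <- function(n_quad) {
  gq <- statmod::gauss.quad(n_quad, kind = "hermite")
  list(x = gq$nodes, logw = log(gq$weights) - 0.5 * log(pi))
}

# link-specific log-probabilities and hazard ratios at linear predictor z
link_terms <- function(z, link) {
  if (link == "probit") {
    list(logp1 = stats::pnorm(z, log.p = TRUE),
         logp0 = stats::pnorm(z, lower.tail = FALSE, log.p = TRUE),
         r1 = exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE)),
         r0 = exp(stats::dnorm(z, log = TRUE) -
                    stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)))
  } else {
    p <- stats::plogis(z)
    list(logp1 = stats::plogis(z, log.p = TRUE),
         logp0 = stats::plogis(z, lower.tail = FALSE, log.p = TRUE),
         r1 = 1 - p, r0 = p)
  }
}

# negative log-likelihood and gradient for one group.
# Parameters: lambda (J), tau (J), alpha, t = log(psi).
# Returns list(nll, g_lambda, g_tau, g_alpha, g_t).
group_nll <- function(lambda, tau, alpha, t, pat, quad, link, grad = TRUE) {
  psi <- exp(t)
  eta <- alpha + sqrt(2 * psi) * quad$x          # Q nodes
  z <- outer(lambda, eta) - tau                  # J x Q
  lt <- link_terms(z, link)
  M <- pat$Y1 %*% lt$logp1 + pat$Y0 %*% lt$logp0 # npat x Q
  Mw <- sweep(M, 2L, quad$logw, "+")
  mstar <- apply(Mw, 1L, max)
  L_log <- mstar + log(rowSums(exp(Mw - mstar)))
  nll <- -sum(pat$w * L_log)
  if (!grad) return(list(nll = nll))
  U <- exp(Mw - L_log)                           # posterior node weights
  V <- pat$w * U
  A1 <- crossprod(pat$Y1, V)                     # J x Q
  A0 <- crossprod(pat$Y0, V)
  B <- A1 * lt$r1 - A0 * lt$r0                   # d/dz accumulators
  g_lambda <- -as.vector(B %*% eta)
  g_tau <- rowSums(B)
  g_alpha <- -sum(lambda * rowSums(B))
  g_t <- -sum(lambda * as.vector(B %*% (eta - alpha))) / 2
  list(nll = nll, g_lambda = g_lambda, g_tau = g_tau,
       g_alpha = g_alpha, g_t = g_t)
}

# fit one group with alpha = 0, psi = 1 (the configural building block).
# Item parameters are box-bounded (the usual IRT safeguard): with very rare
# items the 2PL marginal likelihood has no interior maximum and slopes /
# thresholds drift to infinity; bounds keep such items finite, and their
# large SEs carry the uncertainty downstream.
fit_group_mml <- function(pat, J, quad, link, start = NULL,
                          lambda_max = 6, tau_max = 7, stabilize = FALSE) {
  if (is.null(start)) start <- c(rep(1, J), rep(0, J))
  scale <- if (link == "logit") 1.7 else 1
  start <- pmin(pmax(start, c(rep(0.02, J), rep(-tau_max * scale + 0.01, J))),
                c(rep(lambda_max * scale - 0.01, J), rep(tau_max * scale - 0.01, J)))
  # Optional Bayes-modal stabilization: weak log-normal prior on slopes and
  # normal prior on thresholds. With very rare items the (slope, threshold)
  # likelihood has a long flat ridge and the MLE wanders along it; the weak
  # prior pins estimates to the plausible region with negligible influence
  # when the data are informative.
  mu_l <- log(1.5) + log(scale); sd_l <- 0.5; sd_t <- 10 * scale
  pen <- function(p) {
    if (!stabilize) return(0)
    sum((log(p[1:J]) - mu_l)^2) / (2 * sd_l^2) +
      sum(p[J + 1:J]^2) / (2 * sd_t^2)
  }
  pen_gr <- function(p) {
    if (!stabilize) return(numeric(2 * J))
    c((log(p[1:J]) - mu_l) / (sd_l^2 * p[1:J]), p[J + 1:J] / sd_t^2)
  }
  fn <- function(p) group_nll(p[1:J], p[J + 1:J], 0, 0, pat, quad, link,
                              grad = FALSE)$nll + pen(p)
  gr <- function(p) {
    g <- group_nll(p[1:J], p[J + 1:J], 0, 0, pat, quad, link)
    c(g$g_lambda, g$g_tau) + pen_gr(p)
  }
  opt <- stats::nlminb(start, fn, gr,
                       lower = c(rep(1e-3, J), rep(-tau_max * scale, J)),
                       upper = c(rep(lambda_max * scale, J), rep(tau_max * scale, J)),
                       control = list(iter.max = 500, eval.max = 1000))
  par <- opt$par
  H <- stats::optimHess(par, fn, gr)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2 * J, 2 * J))
  list(lambda = par[1:J], tau = par[J + 1:J],
       loglik = -(opt$objective - pen(par)),
       vcov = vc, converged = opt$convergence == 0)
}
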