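# derivative matrix of model-implied correlations wrt loadings:
# sigma_k = lambda_i * lambda_j for pair k = (i, j)
loading_jacobian <- function(lambda, pairs) {
  q <- nrow(pairs); J <- length(lambda)
  D <- matrix(0, q, J)
  for (k in seq_len(q)) {
    D[k, pairs[k, 1]] <- lambda[pairs[k, 2]]
    D[k, pairs[k, 2]] <- lambda[pairs[k, 1]]
  }
  D
}

#' Fit indices from chi-square statistics
#'
#' RMSEA, CFI and TLI from a fitted and a baseline (independence) model
#' statistic: \eqn{RMSEA = \sqrt{\max(0, (\chi^2 - df)/(df (n-1)))}};
#' \eqn{CFI = 1 - \max(0, \chi^2 - df)/\max(\chi^2 - df, \chi_b^2 - df_b, 0)};
#' \eqn{TLI = ((\chi_b^2/df_b) - (\chi^2/df)) / ((\chi_b^2/df_b) - 1)},
#' truncated above at 1. With \code{df = 0} (saturated model) all three are
#' undefined and returned as \code{NA}.
#'
#' @param chisq,df Fitted-model statistic and degrees of freedom.
#' @param n Sample size.
#' @param baseline_chisq,baseline_df Independence-model statistic and df.
#' @return Named vector \code{c(rmsea, cfi, tli)}.
#' @export
fit_indices <- function(chisq, df, n, baseline_chisq, baseline_df) {
  if (df < 0 || n <= 1) stop("need df >= 0 and n > 1", call. = FALSE)
  if (df == 0) return(c(rmsea = NA_real_, cfi = NA_real_, tli = NA_real_))
  rmsea <- sqrt(max(0, (chisq - df) / (df * (n - 1))))
  cfi <- 1 - max(0, chisq - df) / max(chisq - df, baseline_chisq - baseline_df, 0)
  denom <- baseline_chisq / baseline_df - 1
  tli <- if (abs(denom) < .Machine$double.eps) {
    NA_real_
  } else {
    min(1, (baseline_chisq / baseline_df - chisq / df) / denom)
  }
  c(rmsea = rmsea, cfi = cfi, tli = tli)
}

#' One-factor model for binary items by least squares on tetrachorics
#'
#' Country-specific unidimensional factor analysis for dichotomous items:
#' estimates item thresholds from the margins, the tetrachoric correlation
#' matrix pairwise, and standardized loadings minimizing the (diagonally)
#' weighted least-squares discrepancy between the model-implied correlation
#' structure \eqn{\lambda\lambda'} (unit diagonal) and the estimated matrix.
#' The test statistic is mean-scaled using the asymptotic variances of the
#' tetrachoric estimates so that it is approximately chi-square distributed
#' under a correct model; the baseline for CFI/TLI is the independence model.
#' For one factor, exploratory and confirmatory analyses coincide (no
#' rotational freedom), so a single fit serves both stages.
#'
#' @param table An \code{ipv_responses} object.
#' @param group Optional single group label; default uses all rows.
#' @param weighting \code{"uls"} (default) for unweighted least squares or
#'   \code{"dwls"} to weight pairs by inverse asymptotic variance.
#' @return An object of class \code{ipv_fit}: loadings with SEs, thresholds,
#'   scaled chi-square and df, baseline statistic, RMSEA/CFI/TLI, residuals,
#'   and a convergence flag (Heywood cases, \eqn{|\hat\lambda| \ge 1}, are
#'   flagged non-converged).
#' @export
fit_one_factor <- function(table, group = NULL, weighting = c("uls", "dwls")) {
  weighting <- match.arg(weighting)
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  items <- item_names(table)
  J <- length(items)
  if (J < 3) stop("need at least 3 items for a one-factor model", call. = FALSE)
  n <- nrow(table)
  tau <- estimate_thresholds(table)
  tm <- tetrachoric_matrix(table)
  pairs <- t(utils::combn(J, 2L))
  q <- nrow(pairs)
  r <- tm$rho[pairs]
  gamma <- n * tm$se[pairs]^2          # asymptotic variance of sqrt(n) * rho_hat
  d <- if (weighting == "dwls") 1 / gamma else rep(1, q)

  obj <- function(l) sum(d * (r - l[pairs[, 1]] * l[pairs[, 2]])^2)
  grad <- function(l) {
    e <- d * (r - l[pairs[, 1]] * l[pairs[, 2]])
    g <- numeric(J)
    for (k in seq_len(q)) {
      g[pairs[k, 1]] <- g[pairs[k, 1]] - 2 * e[k] * l[pairs[k, 2]]
      g[pairs[k, 2]] <- g[pairs[k, 2]] - 2 * e[k] * l[pairs[k, 1]]
    }
    g
  }
  ev <- eigen(tm$rho, symmetric = TRUE)
  start <- ev$vectors[, 1] * sqrt(max(ev$values[1], 1e-6))
  if (mean(start) < 0) start <- -start
  start <- pmin(pmax(start, -0.95), 0.95)
  opt <- stats::optim(start, obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  lambda <- opt$par
  if (mean(lambda) < 0) lambda <- -lambda   # sign indeterminacy: positive pole
  converged <- opt$convergence == 0 && all(abs(lambda) < 1)
  names(lambda) <- items

  e <- r - lambda[pairs[, 1]] * lambda[pairs[, 2]]
  df <- q - J
  # mean-scaled statistic in the weighted metric
  sqd <- sqrt(d)
  Dl <- loading_jacobian(lambda, pairs)
  Dt <- sqd * Dl
  A <- crossprod(Dt)
  P <- Dt %*% solve(A, t(Dt))
  Gt <- diag(sqd * gamma * sqd, q)          # W^(1/2) Gamma W^(1/2), diagonal Gamma
  IP <- diag(q) - P
  scale_fit <- sum(diag(IP %*% Gt %*% IP))
  T_raw <- n * sum(d * e^2)
  chisq <- if (df > 0) df * T_raw / scale_fit else 0
  # baseline: zero correlations, no structural parameters
  T_b_raw <- n * sum(d * r^2)
  baseline_df <- q
  baseline_chisq <- baseline_df * T_b_raw / sum(diag(Gt))
  idx <- fit_indices(chisq, df, n, baseline_chisq, baseline_df)
  # sandwich covariance of loadings in the weighted metric
  B <- t(Dt) %*% Gt %*% Dt
  vcov_l <- solve(A) %*% B %*% solve(A) / n
  se <- sqrt(pmax(diag(vcov_l), 0))
  names(se) <- items

  structure(list(group = group, items = items, n = n,
                 lambda = lambda, se = se, tau = tau,
                 chisq = chisq, df = df, baseline_chisq = baseline_chisq,
                 baseline_df = baseline_df,
                 rmsea = idx[["rmsea"]], cfi = idx[["cfi"]], tli = idx[["tli"]],
                 rho = tm$rho, residuals = e, weighting = weighting,
                 converged = converged),
            class = "ipv_fit")
}

#' @export
print.ipv_fit <- function(x, ...) {
  cat(sprintf("One-factor fit%s: n = %d, %d items (%s)\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              x$n, length(x$items), x$weighting))
  cat("  loadings: ", paste(sprintf("%.3f", x$lambda), collapse = " "), "\n")
  cat(sprintf("  chisq = %.3f on %d df; RMSEA = %.3f, CFI = %.3f, TLI = %.3f\n",
              x$chisq, x$df, x$rmsea, x$cfi, x$tli))
  if (!x$converged) cat("  WARNING: not converged / Heywood case\n")
  invisible(x)
}

#' Adequacy gate for a country-specific factor model
#'
#' Pass requires every standardized loading at or above the minimum, and
#' RMSEA / CFI / TLI within their benchmarks (defaults 0.35, 0.08, 0.95,
#' 0.95). A non-converged fit fails automatically. Saturated models (df = 0)
#' are judged on loadings alone, the indices being undefined.
#'
#' @param fit An \code{ipv_fit}.
#' @param config An \code{ipv_config}; default benchmarks if omitted.
#' @return Object of class \code{ipv_adequacy}: \code{pass} plus per-criterion
#'   booleans and a \code{reason} string on failure.
#' @export
adequacy_gate <- function(fit, config = pipeline_config()) {
  if (!isTRUE(fit$converged)) {
    return(structure(list(pass = FALSE,
                          criteria = c(loading = NA, rmsea = NA, cfi = NA, tli = NA),
                          reason = "fit not converged"),
                     class = "ipv_adequacy"))
  }
  crit <- c(
    loading = min(fit$lambda) >= config$min_loading,
    rmsea = is.na(fit$rmsea) || fit$rmsea <= config$max_rmsea,
    cfi = is.na(fit$cfi) || fit$cfi >= config$min_cfi,
    tli = is.na(fit$tli) || fit$tli >= config$min_tli
  )
  structure(list(pass = all(crit), criteria = crit,
                 reason = if (all(crit)) "" else
                   paste("failed:", paste(names(crit)[!crit], collapse = ", "))),
            class = "ipv_adequacy")
}

#' @export
print.ipv_adequacy <- function(x, ...) {
  cat("Adequacy:", if (x$pass) "PASS" else paste("FAIL -", x$reason), "\n")
  invisible(x)
}
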