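#' Rank groups with confidence intervals
#'
#' Normal-approximation CIs at the configured level (default 99.9\%, wide to
#' account for the many pairwise comparisons), descending rank by estimate
#' with ties broken by group label.
#'
#' @param estimates Data frame with columns \code{group}, \code{est},
#'   \code{se}.
#' @param ci_level Confidence level in (0, 1); default 0.999.
#' @return Object of class \code{ipv_ranking}: data frame with \code{group},
#'   \code{est}, \code{se}, \code{lower}, \code{upper}, \code{rank} (1 =
#'   highest estimate), and \code{tied} flag, ordered by rank. Groups with
#'   missing SEs are dropped with a warning.
#' @export
rank_groups <- function(estimates, ci_level = 0.999) {
  stopifnot(all(c("group", "est", "se") %in% names(estimates)))
  bad <- is.na(estimates$se) | is.na(estimates$est)
  if (any(bad)) {
    warning("excluding group(s) without estimate/SE: ",
            paste(estimates$group[bad], collapse = ", "), call. = FALSE)
    estimates <- estimates[!bad, , drop = FALSE]
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- data.frame(group = estimates$group, est = estimates$est,
                    se = estimates$se,
                    lower = estimates$est - z * estimates$se,
                    upper = estimates$est + z * estimates$se,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$est, out$group), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tied <- duplicated(out$est) | duplicated(out$est, fromLast = TRUE)
  rownames(out) <- NULL
  structure(out, ci_level = ci_level, class = c("ipv_ranking", "data.frame"))
}

#' Cluster ranked groups by confidence-interval overlap
#'
#' Scans groups in rank order; a new cluster starts when a group's CI fails
#' to overlap the CI of every group already in the current cluster. Clusters
#' are therefore contiguous in rank; within a cluster, rankings are not
#' statistically interpretable.
#'
#' @param ranking An \code{ipv_ranking}.
#' @return The ranking with a \code{cluster} column added.
#' @export
cluster_by_ci_overlap <- function(ranking) {
  stopifnot(inherits(ranking, "ipv_ranking"))
  n <- nrow(ranking)
  cluster <- integer(n)
  if (n) {
    cluster[1] <- 1L
    members <- 1L
    for (i in seq_len(n)[-1]) {
      overlaps_all <- all(ranking$lower[i] <= ranking$upper[members] &
                            ranking$lower[members] <= ranking$upper[i])
      if (overlaps_all) {
        members <- c(members, i)
        cluster[i] <- cluster[members[1]]
      } else {
        members <- i
        cluster[i] <- max(cluster[seq_len(i - 1L)]) + 1L
      }
    }
  }
  ranking$cluster <- cluster
  ranking
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Paired test on per-group values (typically ranks under two estimation
#' strategies). Zero differences are excluded; absolute differences are
#' ranked with mid-ranks for ties. With 15 or fewer informative pairs the
#' null distribution is computed exactly by enumerating all sign assignments
#' (valid under ties as well); otherwise a normal approximation with tie and
#' continuity corrections is used. Two-sided by default.
#'
#' @param ranks_a,ranks_b Numeric vectors over the same groups (same order,
#'   or matching names).
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @param exact_limit Maximum number of informative pairs for the exact path.
#' @return Object of class \code{ipv_wilcoxon}: \code{statistic} (V, sum of
#'   positive-difference ranks), \code{p_value}, \code{n_informative},
#'   \code{method}. With no informative pairs the test is degenerate and
#'   \code{p_value = 1}.
#' @export
wilcoxon_signed_rank <- function(ranks_a, ranks_b,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_limit = 15L) {
  alternative <- match.arg(alternative)
  if (!is.null(names(ranks_a)) && !is.null(names(ranks_b))) {
    if (!setequal(names(ranks_a), names(ranks_b))) {
      stop("mismatched group sets", call. = FALSE)
    }
    ranks_b <- ranks_b[names(ranks_a)]
  } else if (length(ranks_a) != length(ranks_b)) {
    stop("mismatched lengths", call. = FALSE)
  }
  d <- ranks_a - ranks_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = NA_real_, p_value = 1,
                          n_informative = 0L, method = "degenerate"),
                     class = "ipv_wilcoxon"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_limit) {
    # enumerate all 2^n sign assignments
    m <- 2^n
    bits <- vapply(seq_len(n), function(i) (0:(m - 1) %/% 2^(i - 1)) %% 2,
                   numeric(m))
    Vnull <- as.vector(bits %*% r)
    # two-sided: double the one-sided p of the observed side (the standard
    # convention for the symmetric signed-rank null), capped at 1
    p <- switch(alternative,
                greater = mean(Vnull >= V),
                less = mean(Vnull <= V),
                two.sided = min(1, 2 * (if (V > mu) mean(Vnull >= V)
                                        else mean(Vnull <= V))))
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    cc <- 0.5
    z <- switch(alternative,
                greater = (V - mu - cc) / sigma,
                less = (V - mu + cc) / sigma,
                two.sided = (V - mu - sign(V - mu) * cc) / sigma)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = min(1, 2 * stats::pnorm(-abs(z))))
    method <- "normal approximation"
  }
  structure(list(statistic = V, p_value = p, n_informative = n,
                 method = method, alternative = alternative),
            class = "ipv_wilcoxon")
}

#' @export
print.ipv_wilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s, %s): V = %s, n = %d, p = %.4g\n",
              x$alternative %||% "two.sided", x$method,
              format(x$statistic), x$n_informative, x$p_value))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convergent-validity correlations
#'
#' Product-moment (or rank) correlations across groups between alignment
#' factor means and prevalence measures.
#'
#' @param factor_means Named numeric vector of per-group factor means.
#' @param prevalence Data frame with a \code{group} column and one or more
#'   numeric prevalence columns, or the \code{any} element of an
#'   \code{ipv_prevalence}.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return Correlation matrix between the factor means (first row/column,
#'   named \code{factor_mean}) and each prevalence column. Columns with zero
#'   variance yield \code{NA} with a warning.
#' @export
convergent_correlations <- function(factor_means, prevalence,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot("group" %in% names(prevalence))
  num_cols <- setdiff(names(prevalence)[vapply(prevalence, is.numeric, logical(1))],
                      c("se", "n", "rank"))
  common <- intersect(names(factor_means), prevalence$group)
  if (length(common) < 3) stop("need >= 3 groups in common", call. = FALSE)
  m <- cbind(factor_mean = factor_means[common],
             as.matrix(prevalence[match(common, prevalence$group), num_cols,
                                  drop = FALSE]))
  colnames(m)[-1] <- num_cols
  zv <- apply(m, 2L, stats::sd, na.rm = TRUE) < .Machine$double.eps
  if (any(zv)) {
    warning("zero-variance column(s): ", paste(colnames(m)[zv], collapse = ", "),
            call. = FALSE)
  }
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs", method = method))
}

#' Plot a group ranking with confidence intervals
#'
#' Estimate and CI by rank, the standard display for comparing group
#' orderings under wide simultaneous intervals.
#'
#' @param x An \code{ipv_ranking}.
#' @param main Plot title.
#' @param ... Passed to \code{plot}.
#' @export
plot.ipv_ranking <- function(x, main = "Group ranking", ...) {
  graphics::plot(x$rank, x$est, ylim = range(x$lower, x$upper), pch = 19,
                 xlab = "Rank", ylab = "Estimate", main = main, ...)
  graphics::arrows(x$rank, x$lower, x$rank, x$upper, angle = 90, code = 3,
                   length = 0.02, col = "grey40")
  if (!is.null(x$cluster)) {
    b <- which(diff(x$cluster) != 0) + 0.5
    graphics::abline(v = b, lty = 3, col = "grey60")
  }
  invisible(x)
}
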