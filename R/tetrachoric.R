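#' Probit thresholds from item margins
#'
#' For each item, the univariate probit threshold \eqn{\hat\tau_j =
#' \Phi^{-1}(1 - \hat p_j)} where \eqn{\hat p_j} is the weighted endorsement
#' prevalence over non-missing responses.
#'
#' @param table An \code{ipv_responses} object.
#' @param group Optional single group label; default uses all rows.
#' @return Named numeric vector of thresholds.
#' @export
estimate_thresholds <- function(table, group = NULL) {
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  items <- item_names(table)
  p <- vapply(items, function(j) wmean_se(table[[j]], table$weight)[["est"]],
              numeric(1))
  deg <- items[!is.na(p) & (p <= 0 | p >= 1)]
  if (length(deg)) {
    stop("degenerate item(s) with prevalence 0 or 1: ",
         paste(deg, collapse = ", "), call. = FALSE)
  }
  stats::qnorm(1 - p)
}

# standard bivariate normal CDF P(Z1 <= a, Z2 <= b | rho)
biv_cdf <- function(a, b, rho) {
  mvtnorm::pmvnorm(upper = c(a, b),
                   corr = matrix(c(1, rho, rho, 1), 2))[1]
}

# cell probabilities of the 2x2 table under thresholds (t1, t2) and rho;
# cells ordered (11, 10, 01, 00) with 1 meaning z > threshold
tetra_cell_probs <- function(t1, t2, rho) {
  p1 <- stats::pnorm(t1, lower.tail = FALSE)
  p2 <- stats::pnorm(t2, lower.tail = FALSE)
  p11 <- biv_cdf(-t1, -t2, rho)
  c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
}

# two-stage tetrachoric from (possibly weighted) 2x2 cell counts
# cells: c(n11, n10, n01, n00)
tetra_from_cells <- function(cells, correct = 0.5) {
  if (any(cells < 0) || sum(cells) <= 0) stop("invalid 2x2 cell counts", call. = FALSE)
  if (any(cells == 0)) cells <- cells + correct
  n <- sum(cells)
  p1 <- (cells[1] + cells[2]) / n
  p2 <- (cells[1] + cells[3]) / n
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    stop("degenerate margin in 2x2 table", call. = FALSE)
  }
  t1 <- stats::qnorm(1 - p1)
  t2 <- stats::qnorm(1 - p2)
  ll <- function(rho) {
    pr <- pmax(tetra_cell_probs(t1, t2, rho), 1e-12)
    sum(cells * log(pr))
  }
  opt <- stats::optimize(ll, c(-0.9999, 0.9999), maximum = TRUE, tol = 1e-9)
  rho <- opt$maximum
  # observed-information SE by central second difference
  h <- 1e-4
  d2 <- (ll(min(rho + h, 0.9999)) - 2 * ll(rho) + ll(max(rho - h, -0.9999))) / h^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  list(rho = rho, se = se, n = n, thresholds = c(t1, t2))
}

#' Tetrachoric correlation between two binary items
#'
#' Two-stage estimator: univariate probit thresholds are fixed at the margins
#' of the pairwise-complete 2x2 table, then the bivariate-normal likelihood of
#' the cell counts is maximized over the correlation. Sampling weights enter
#' as weighted cell counts; missing responses are handled by pairwise
#' deletion. Tables with an empty cell get a 0.5 continuity correction added
#' to every cell (prevents divergence to plus/minus 1).
#'
#' @param table An \code{ipv_responses} object.
#' @param item_i,item_j Item names.
#' @param group Optional single group label.
#' @return List with \code{rho}, \code{se}, \code{n} (pairwise-complete
#'   weighted count), and \code{thresholds}.
#' @export
tetrachoric <- function(table, item_i, item_j, group = NULL) {
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  yi <- table[[item_i]]; yj <- table[[item_j]]; w <- table$weight
  ok <- !is.na(yi) & !is.na(yj)
  yi <- yi[ok]; yj <- yj[ok]; w <- w[ok]
  if (!length(yi)) stop("no jointly observed responses for ", item_i, "/", item_j,
                        call. = FALSE)
  cells <- c(sum(w[yi == 1 & yj == 1]), sum(w[yi == 1 & yj == 0]),
             sum(w[yi == 0 & yj == 1]), sum(w[yi == 0 & yj == 0]))
  tetra_from_cells(cells)
}

#' Tetrachoric correlation matrix of an item set
#'
#' @param table An \code{ipv_responses} object.
#' @param group Optional single group label.
#' @return List with \code{rho} (J x J correlation matrix, unit diagonal) and
#'   \code{se} (J x J, NA diagonal).
#' @export
tetrachoric_matrix <- function(table, group = NULL) {
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  items <- item_names(table)
  J <- length(items)
  R <- diag(J); S <- matrix(NA_real_, J, J)
  dimnames(R) <- dimnames(S) <- list(items, items)
  for (i in seq_len(J - 1)) {
    for (j in (i + 1):J) {
      est <- tetrachoric(table, items[i], items[j])
      R[i, j] <- R[j, i] <- est$rho
      S[i, j] <- S[j, i] <- est$se
    }
  }
  list(rho = R, se = S)
}
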