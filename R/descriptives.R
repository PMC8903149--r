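#' Per-item missingness fractions
#'
#' @param table An \code{ipv_responses} object.
#' @param by_group If \code{TRUE}, also return per-group fractions.
#' @return Named vector of overall per-item missing fractions, or a list with
#'   \code{overall} and a group-by-item matrix when \code{by_group = TRUE}.
#' @export
item_missingness <- function(table, by_group = FALSE) {
  items <- item_names(table)
  y <- as.matrix(table[items])
  overall <- colMeans(is.na(y))
  if (!by_group) return(overall)
  groups <- sort(unique(table$group))
  m <- t(vapply(groups, function(g) colMeans(is.na(y[table$group == g, , drop = FALSE])),
                numeric(length(items))))
  rownames(m) <- groups
  list(overall = overall, by_group = m)
}

# weighted mean of 0/1 responses with linearized SE
wmean_se <- function(y, w) {
  ok <- !is.na(y)
  y <- y[ok]; w <- w[ok]
  if (!length(y)) return(c(est = NA_real_, se = NA_real_, n = 0))
  p <- sum(w * y) / sum(w)
  se <- sqrt(sum(w^2 * (y - p)^2)) / sum(w)
  c(est = p, se = se, n = length(y))
}

#' Survey-weighted item prevalence per group
#'
#' Computes \eqn{\hat p = \sum w y / \sum w} over non-missing responses with a
#' linearization standard error. With all-equal weights the estimate equals the
#' unweighted mean exactly.
#'
#' @param table An \code{ipv_responses} object.
#' @param item Item column name.
#' @return Data frame with one row per group: \code{group}, \code{est},
#'   \code{se}, \code{n} (non-missing count). Groups whose responses are all
#'   missing for the item are flagged with \code{NA} estimates and a warning.
#' @export
weighted_prevalence <- function(table, item) {
  if (!item %in% item_names(table)) stop("unknown item: ", item, call. = FALSE)
  groups <- sort(unique(table$group))
  res <- t(vapply(groups, function(g) {
    i <- table$group == g
    wmean_se(table[[item]][i], table$weight[i])
  }, numeric(3)))
  out <- data.frame(group = groups, est = res[, 1], se = res[, 2], n = res[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (anyNA(out$est)) {
    warning("group(s) with item '", item, "' entirely missing: ",
            paste(out$group[is.na(out$est)], collapse = ", "), call. = FALSE)
  }
  out
}

#' Weighted "any item" prevalence per group
#'
#' Prevalence of endorsing at least one of the listed items. A respondent
#' counts as positive if any observed listed item is 1; as negative only if
#' all listed items are observed and 0; and is excluded otherwise (partially
#' missing with no observed 1), mirroring standard DHS indicator construction.
#'
#' @param table An \code{ipv_responses} object.
#' @param items Character vector of item names; default all items.
#' @return Data frame as in [weighted_prevalence()].
#' @export
any_prevalence <- function(table, items = item_names(table)) {
  if (!length(items)) stop("empty item list", call. = FALSE)
  bad <- setdiff(items, item_names(table))
  if (length(bad)) stop("unknown item(s): ", paste(bad, collapse = ", "), call. = FALSE)
  y <- as.matrix(table[items])
  any1 <- rowSums(y == 1, na.rm = TRUE) > 0
  all0 <- rowSums(y == 0, na.rm = TRUE) == length(items)
  ind <- ifelse(any1, 1L, ifelse(all0, 0L, NA_integer_))
  groups <- sort(unique(table$group))
  res <- t(vapply(groups, function(g) {
    i <- table$group == g
    wmean_se(ind[i], table$weight[i])
  }, numeric(3)))
  data.frame(group = groups, est = res[, 1], se = res[, 2], n = res[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full descriptive screen of a response table
#'
#' The step-1 screening: per group-by-item weighted prevalence and SE, per
#' group any-item prevalence, per-item missingness, and the min/max prevalence
#' range across groups.
#'
#' @param table An \code{ipv_responses} object.
#' @return An object of class \code{ipv_prevalence}: list with \code{items}
#'   (long data frame group x item), \code{any} (per group), \code{missingness},
#'   and \code{range} (per item min/max across groups).
#' @export
prevalence_table <- function(table) {
  items <- item_names(table)
  per_item <- do.call(rbind, lapply(items, function(j) {
    d <- weighted_prevalence(table, j)
    d$item <- j
    d
  }))
  per_item <- per_item[c("group", "item", "est", "se", "n")]
  rng <- do.call(rbind, lapply(split(per_item, per_item$item), function(d) {
    data.frame(item = d$item[1], min = min(d$est, na.rm = TRUE),
               max = max(d$est, na.rm = TRUE), stringsAsFactors = FALSE)
  }))
  structure(list(items = per_item, any = any_prevalence(table),
                 missingness = item_missingness(table, by_group = TRUE),
                 range = rng[match(items, rng$item), ]),
            class = "ipv_prevalence")
}

#' @export
print.ipv_prevalence <- function(x, ...) {
  cat("Weighted prevalence summary\n")
  cat(sprintf("  any-item prevalence across groups: %.3f - %.3f\n",
              min(x$any$est, na.rm = TRUE), max(x$any$est, na.rm = TRUE)))
  cat(sprintf("  max per-item missingness: %.4f\n", max(x$missingness$overall)))
  print(x$range, row.names = FALSE)
  invisible(x)
}
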