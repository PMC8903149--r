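#' Construct an item response table
#'
#' The universal input container: one row per respondent with a group label, a
#' positive sampling weight, and binary (0/1/NA) responses to a named item set.
#'
#' @param group Character or factor vector of group (country) labels.
#' @param responses Data frame or matrix of 0/1/NA responses, one column per item.
#' @param weight Positive sampling weights; default all 1.
#' @param item_set Label of the item set (e.g. \code{"physical_ipv"}).
#' @return An object of class \code{ipv_responses}: a data frame with columns
#'   \code{group}, \code{weight}, then the item columns, with attribute
#'   \code{item_set}.
#' @export
response_table <- function(group, responses, weight = NULL, item_set = "custom") {
  responses <- as.data.frame(responses)
  n <- nrow(responses)
  if (length(group) != n) stop("group length must match response rows", call. = FALSE)
  if (is.null(weight)) weight <- rep(1, n)
  if (length(weight) != n) stop("weight length must match response rows", call. = FALSE)
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("validation error: all weights must be positive and finite", call. = FALSE)
  }
  for (j in names(responses)) {
    v <- responses[[j]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad)) {
      stop("validation error: item '", j, "' has responses outside {0, 1, NA} in row(s) ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
    responses[[j]] <- as.integer(v)
  }
  out <- data.frame(group = as.character(group), weight = as.numeric(weight),
                    responses, check.names = FALSE, stringsAsFactors = FALSE)
  structure(out, item_set = item_set, class = c("ipv_responses", "data.frame"))
}

#' @export
print.ipv_responses <- function(x, ...) {
  cat(sprintf("Item response table (%s): %d respondents, %d groups, %d items\n",
              attr(x, "item_set"), nrow(x), length(unique(x$group)),
              length(item_names(x))))
  NextMethod()
}

#' Item column names of a response table
#' @param table An \code{ipv_responses} object.
#' @return Character vector of item names.
#' @export
item_names <- function(table) {
  setdiff(names(table), c("group", "weight"))
}

#' Read an item response table from CSV
#'
#' Expects a header row with a \code{group} column, an optional \code{weight}
#' column (defaults to 1), and one column per item in the declared item set.
#' Missing responses are empty cells or the token \code{NA}; any other value
#' outside \{0, 1\} is a validation error.
#'
#' @param path Path to a CSV file.
#' @param item_set Either the label of a built-in set (see [item_sets()]) or a
#'   character vector of item column names.
#' @return An \code{ipv_responses} object.
#' @export
read_response_table <- function(path, item_set = "physical_ipv") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(item_set) == 1L && item_set %in% names(item_sets())) {
    items <- item_sets(item_set)
    label <- item_set
  } else {
    items <- as.character(item_set)
    label <- "custom"
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"group" %in% names(df)) {
    stop("schema error: no 'group' column in ", path, call. = FALSE)
  }
  missing_items <- setdiff(items, names(df))
  if (length(missing_items)) {
    stop("schema error: item column(s) missing from file: ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c("group", "weight", items))
  if (length(extra)) {
    stop("schema error: unknown column(s) for item set '", label, "': ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  response_table(group = df$group, responses = df[items],
                 weight = if ("weight" %in% names(df)) df$weight else NULL,
                 item_set = label)
}

#' Write an item response table to CSV
#'
#' Missing responses are written as empty cells; re-reading with
#' [read_response_table()] round-trips losslessly.
#'
#' @param table An \code{ipv_responses} object.
#' @param path Output path.
#' @export
write_response_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a stage result to disk
#'
#' Tabular results are written as CSV at full precision; structured results
#' (alignment solutions, study reports) as a JSON summary. A generic so every
#' pipeline stage output shares one interface.
#'
#' @param results A stage output (data frame, alignment solution, report, ...).
#' @param path Output path; extension \code{.csv} or \code{.json} is chosen by
#'   the method when \code{path} has none.
#' @export
write_report <- function(results, path) UseMethod("write_report")

#' @export
write_report.data.frame <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
write_report.default <- function(results, path) {
  jsonlite::write_json(unclass_deep(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' @export
write_report.ipv_alignment <- function(results, path) {
  s <- results
  s$summary <- list(
    n_flagged_thresholds = sum(s$flag_threshold, na.rm = TRUE),
    n_flagged_loadings = sum(s$flag_loading, na.rm = TRUE),
    pct = as.list(s$pct)
  )
  write_report.default(s, path)
}

# strip S3 classes / matrices so jsonlite serializes plainly
unclass_deep <- function(x) {
  if (is.matrix(x)) return(apply(x, 1L, function(r) as.list(r), simplify = FALSE))
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, unclass_deep))
  if (is.function(x)) return(NULL)
  x
}
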