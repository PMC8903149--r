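#' Item sets of the DHS domestic violence module
#'
#' Returns the named item sets the package knows about: the seven lifetime
#' physical-IPV acts and the five male controlling behaviours. Item names are
#' short mnemonics for the standard module wordings (e.g. \code{choke} for
#' "try to choke you or burn you on purpose").
#'
#' @param item_set Optional label; if supplied, returns that set's item names.
#' @return A named list of character vectors, or a single character vector if
#'   \code{item_set} is given.
#' @export
#' @examples
#' item_sets("physical_ipv")
item_sets <- function(item_set = NULL) {
  sets <- list(
    physical_ipv = c("push", "slap", "punch", "kick", "choke", "weapon", "twist"),
    controlling  = c("jealous", "accuse", "friends", "family", "whereabouts")
  )
  if (is.null(item_set)) return(sets)
  if (!item_set %in% names(sets)) {
    stop("unknown item set '", item_set, "'; known sets: ",
         paste(names(sets), collapse = ", "), call. = FALSE)
  }
  sets[[item_set]]
}

#' Pipeline configuration
#'
#' Holds the adequacy benchmarks and numerical settings used throughout the
#' pipeline. Defaults are the recommended benchmarks for binary factor models:
#' minimum standardized loading 0.35, RMSEA at most 0.08, CFI and TLI at least
#' 0.95, and at most 25\% non-invariant parameters for a trustworthy alignment.
#'
#' @param min_loading Minimum acceptable standardized loading, in (0, 1).
#' @param max_rmsea Maximum acceptable RMSEA.
#' @param min_cfi,min_tli Minimum acceptable CFI / TLI.
#' @param max_noninvariant_fraction Fraction of aligned parameters that may be
#'   flagged non-invariant before the alignment is declared untrustworthy.
#' @param link Link function for the marginal maximum likelihood path,
#'   \code{"probit"} (default, matches the generator) or \code{"logit"}.
#' @param n_quad Number of Gauss-Hermite quadrature nodes.
#' @param epsilon Alignment component-loss smoothing constant.
#' @param flag_alpha Significance level for non-invariance flagging.
#' @param ci_level Confidence level for group ranking intervals.
#' @param alpha Significance level for the invariance-ladder decisions.
#' @param seed Optional integer seed recorded in reports.
#' @return An object of class \code{ipv_config}.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_loading
pipeline_config <- function(min_loading = 0.35,
                            max_rmsea = 0.08,
                            min_cfi = 0.95,
                            min_tli = 0.95,
                            max_noninvariant_fraction = 0.25,
                            link = c("probit", "logit"),
                            n_quad = 21,
                            epsilon = 0.01,
                            flag_alpha = 0.01,
                            ci_level = 0.999,
                            alpha = 0.05,
                            seed = NULL) {
  link <- match.arg(link)
  chk_frac <- function(x, nm, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        x < lo || x > hi || (open_lo && x == lo) || (open_hi && x == hi)) {
      stop("configuration error: '", nm, "' must be in ",
           if (open_lo) "(" else "[", lo, ", ", hi,
           if (open_hi) ")" else "]", ", got ", format(x), call. = FALSE)
    }
    x
  }
  cfg <- list(
    min_loading = chk_frac(min_loading, "min_loading", 0, 1, TRUE, TRUE),
    max_rmsea = chk_frac(max_rmsea, "max_rmsea"),
    min_cfi = chk_frac(min_cfi, "min_cfi"),
    min_tli = chk_frac(min_tli, "min_tli"),
    max_noninvariant_fraction =
      chk_frac(max_noninvariant_fraction, "max_noninvariant_fraction"),
    link = link,
    n_quad = as.integer(n_quad),
    epsilon = epsilon,
    flag_alpha = chk_frac(flag_alpha, "flag_alpha", 0, 1, TRUE, TRUE),
    ci_level = chk_frac(ci_level, "ci_level", 0, 1, TRUE, TRUE),
    alpha = chk_frac(alpha, "alpha", 0, 1, TRUE, TRUE),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  if (cfg$n_quad < 3L) stop("configuration error: n_quad must be >= 3", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("configuration error: epsilon must be > 0", call. = FALSE)
  }
  structure(cfg, class = "ipv_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Any key absent from the file keeps its default; an empty or absent file
#' yields the default configuration.
#'
#' @param path Path to a YAML key/value document, or \code{NULL} for defaults.
#' @return An \code{ipv_config} object.
#' @export
load_config <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    known <- names(formals(pipeline_config))
    unknown <- setdiff(names(vals), known)
    if (length(unknown)) {
      stop("configuration error: unknown key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  do.call(pipeline_config, vals)
}

#' @export
print.ipv_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  adequacy: loading >= %.2f, RMSEA <= %.2f, CFI >= %.2f, TLI >= %.2f\n",
              x$min_loading, x$max_rmsea, x$min_cfi, x$min_tli))
  cat(sprintf("  alignment: epsilon = %g, flag alpha = %g, trust limit = %.0f%%\n",
              x$epsilon, x$flag_alpha, 100 * x$max_noninvariant_fraction))
  cat(sprintf("  estimation: %s link, %d quadrature nodes; ladder alpha = %g; CI level = %g\n",
              x$link, x$n_quad, x$alpha, x$ci_level))
  invisible(x)
}
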