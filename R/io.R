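# Delimited-text input of rate tables and JSON output of fit reports.

#' Read a rate table from delimited text
#'
#' Reads CSV/TSV with a header and columns for temperature (named
#' \code{T_K}, \code{T} or \code{temperature}, in kelvin) or coldness
#' (\code{beta}), plus a rate column (\code{k} or \code{rate}).  Lines
#' starting with \code{#} are comments.  Rows with non-positive or
#' missing rates are rejected with a warning naming the row numbers;
#' duplicated coldness values are averaged in \eqn{\ln k} (geometric
#' mean of \code{k}) with a warning.
#'
#' @param path Path to the file.
#' @param units A \code{\link{unit_system}} (or energy-unit string) used
#'   to convert temperatures to coldness.
#' @param sep Field separator; \code{NULL} guesses from the extension
#'   (\code{.tsv}/\code{.tab} = tab, otherwise comma).
#' @return A \code{\link{rate_dataset}} sorted by increasing beta.
#' @export
read_rate_table <- function(path, units = unit_system(), sep = NULL) {
  units <- .as_units(units)
  if (!file.exists(path)) {
    tv_stop(sprintf("input file not found: %s", path), "tv_input_error")
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  tab <- try(utils::read.table(path, header = TRUE, sep = sep,
                               comment.char = "#", strip.white = TRUE,
                               stringsAsFactors = FALSE),
             silent = TRUE)
  if (inherits(tab, "try-error") || nrow(tab) == 0) {
    tv_stop(sprintf("could not parse rate table: %s", path), "tv_input_error")
  }
  cols <- tolower(names(tab))
  t_col <- match(c("t_k", "t", "temperature"), cols)
  t_col <- t_col[!is.na(t_col)][1]
  b_col <- match("beta", cols)
  k_col <- match(c("k", "rate"), cols)
  k_col <- k_col[!is.na(k_col)][1]
  if (is.na(k_col) || (is.na(t_col) && is.na(b_col))) {
    tv_stop("rate table needs a rate column (k/rate) and a T_K/T/temperature or beta column",
            "tv_input_error")
  }
  k <- suppressWarnings(as.numeric(tab[[k_col]]))
  beta <- if (!is.na(b_col)) {
    suppressWarnings(as.numeric(tab[[b_col]]))
  } else {
    tt <- suppressWarnings(as.numeric(tab[[t_col]]))
    ifelse(is.finite(tt) & tt > 0, 1 / (units$boltzmann * tt), NA_real_)
  }
  bad <- !is.finite(k) | k <= 0 | !is.finite(beta) | beta <= 0
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with non-positive or unparseable values: %s",
                    sum(bad), paste(which(bad), collapse = ", ")),
            call. = FALSE)
    k <- k[!bad]; beta <- beta[!bad]
  }
  if (length(k) < 3) {
    tv_stop("fewer than 3 valid rows in rate table", "tv_input_error")
  }
  if (anyDuplicated(beta)) {
    warning("duplicate coldness values averaged in ln k", call. = FALSE)
    lnk <- tapply(log(k), beta, mean)
    beta <- as.numeric(names(lnk))
    k <- exp(unname(lnk))
  }
  rate_dataset(beta = beta, k = k, units = units)
}

#' Write a fit report as JSON
#'
#' Serializes a \code{fit_result} to JSON with deterministic field
#' ordering: law tag, parameter estimates and standard errors, residual
#' sum of squares and information criterion, the selected exponent or
#' breakpoint when present, the Arrhenius-plot classification for AM
#' fits, and (for super-Arrhenius fits) the thermal limits
#' \eqn{\epsilon^\dagger}, \eqn{T^\dagger}, \eqn{\beta^\dagger}.
#' Numbers are written at full precision, so a round-trip read
#' reproduces them exactly.
#'
#' @param result A \code{fit_result}.
#' @param path Output path, or \code{NULL} to return the report list
#'   invisibly without writing.
#' @param config Optional configuration list echoed verbatim.
#' @param timestamp Include an ISO timestamp field (default TRUE).
#' @return The report list, invisibly.
#' @export
write_report <- function(result, path = NULL, config = NULL,
                         timestamp = TRUE) {
  if (!inherits(result, "fit_result")) {
    tv_stop("result must be a fit_result", "tv_input_error")
  }
  report <- list(
    law = result$law,
    parameters = as.list(result$par),
    std_errors = as.list(result$se),
    rss_lnk = result$rss,
    aicc = result$aicc,
    n = result$n,
    units = result$units$energy_unit
  )
  if (!is.null(result$zeta)) report$zeta <- result$zeta
  if (!is.null(result$breakpoint)) {
    bp <- result$breakpoint
    report$breakpoint <- list(
      beta_c = bp$beta_c, T_c = bp$T_c,
      left = as.list(bp$left), right = as.list(bp$right)
    )
  }
  if ("d" %in% names(result$par)) {
    report$classification <- classify_behavior(result)
    d <- result$par[["d"]]; eps <- result$par[["eps_act"]]
    if (is.finite(d) && d > 0 && eps > 0) {
      tl <- thermal_limits(eps, d, result$units)
      report$thermal_limits <- list(
        eps_dagger = tl$eps_dagger, T_dagger = tl$T_dagger,
        beta_dagger = tl$beta_dagger
      )
    }
  }
  if (!is.null(config)) report$config <- config
  if (timestamp) report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(path)) {
    ok <- try(jsonlite::write_json(report, path, auto_unbox = TRUE,
                                   digits = NA, pretty = TRUE),
              silent = TRUE)
    if (inherits(ok, "try-error")) {
      tv_stop(sprintf("could not write report to %s", path), "tv_io_error")
    }
  }
  invisible(report)
}

#' Read or build a rate-law model from a parameter file
#'
#' Parameter files are JSON objects
#' \code{\{"law": ..., "params": \{...\}, "units": \{"energy_unit": ...\}\}}.
#'
#' @param path Path to the JSON file.
#' @return A \code{\link{rate_law}}.
#' @export
read_rate_law <- function(path) {
  if (!file.exists(path)) {
    tv_stop(sprintf("parameter file not found: %s", path), "tv_input_error")
  }
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$law) || is.null(spec$params)) {
    tv_stop("parameter file needs 'law' and 'params' fields", "tv_input_error")
  }
  units <- if (!is.null(spec$units$energy_unit)) {
    unit_system(spec$units$energy_unit)
  } else {
    unit_system()
  }
  p <- spec$params
  rate_law(spec$law,
           A = p$A %||% 1, eps_act = p$eps_act %||% 1,
           d = p$d, beta_dagger = p$beta_dagger, s = p$s, zeta = p$zeta,
           units = units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
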