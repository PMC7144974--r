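# CSV/JSON reading and writing for series, fits, rankings and
# verification reports, with the significance-star convention used in
# the comparison tables.

#' Read a time series from CSV
#'
#' Expects a header `t,y` and one numeric row per observation. Strictly
#' increasing times are *enforced*, not silently sorted; violations are
#' reported with their row number.
#'
#' @param path Path to a CSV file.
#' @return A [growth_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t", "y") %in% names(df))) {
    stop(sprintf("%s must have header columns 't' and 'y'", path))
  }
  for (col in c("t", "y")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (any(is.na(vn) & !is.na(v))) {
        stop(sprintf("non-numeric value in column '%s' at data row %d of %s",
                     col, which(is.na(vn) & !is.na(v))[1], path))
      }
      df[[col]] <- vn
    }
  }
  if (anyNA(df$t) || anyNA(df$y)) {
    stop(sprintf("missing value at data row %d of %s",
                 which(is.na(df$t) | is.na(df$y))[1], path))
  }
  growth_series(df$t, df$y)
}

#' Significance stars
#'
#' The star convention of the comparison tables: `*` below the .10
#' level, `**` below .05, `***` below .01.
#'
#' @param p Vector of p-values.
#' @return Character vector of star strings (empty when `p >= 0.10` or
#'   missing).
#' @examples
#' p_stars(c(0.2, 0.03, 0.005))  # "", "**", "***"
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.10] <- "*"
  out[!is.na(p) & p < 0.05] <- "**"
  out[!is.na(p) & p < 0.01] <- "***"
  out
}

ranking_to_df <- function(x) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 12)
  df
}

fit_to_list <- function(f) {
  list(model_id = f$model_id,
       estimates = as.list(f$estimates),
       free = f$free,
       se = as.list(stats::setNames(f$se, f$free)),
       tstat = as.list(stats::setNames(f$tstat, f$free)),
       pvalue = as.list(stats::setNames(f$pvalue, f$free)),
       stars = as.list(stats::setNames(p_stars(f$pvalue), f$free)),
       sse = f$sse, adj_r2 = f$adj_r2, df = f$df,
       converged = f$converged, n_starts = f$n_starts,
       seed = f$seed)
}

#' Write a report to CSV or JSON
#'
#' Serializes a [fit_growth()] result, a [rank_models()] table, or a
#' [verify_catalog()] report. Columns come out in a deterministic order;
#' p-values in CSV rankings carry significance stars; numbers round-trip
#' at 12 significant digits.
#'
#' @param x The object to write.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default guessed from the file
#'   extension, falling back to json).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  format <- match.arg(format, c("csv", "json"))
  if (inherits(x, "growth_fit")) {
    if (format == "json") {
      jsonlite::write_json(fit_to_list(x), path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    } else {
      df <- data.frame(parameter = x$free,
                       estimate = signif(x$estimates[x$free], 12),
                       se = signif(x$se, 12),
                       tstat = signif(x$tstat, 12),
                       pvalue = paste0(signif(x$pvalue, 12), p_stars(x$pvalue)),
                       stringsAsFactors = FALSE)
      utils::write.csv(df, path, row.names = FALSE)
    }
  } else if (inherits(x, "growth_ranking") || is.data.frame(x)) {
    df <- ranking_to_df(x)
    if (format == "json") {
      jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else {
      utils::write.csv(df, path, row.names = FALSE)
    }
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write a simulated series to CSV
#'
#' @param series A [growth_series()].
#' @param path Output path; written with header `t,y`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  series <- as_growth_series(series)
  utils::write.csv(data.frame(t = series$t, y = series$y), path,
                   row.names = FALSE)
  invisible(path)
}
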