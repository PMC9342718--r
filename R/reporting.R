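# Reporting: percentage shares, fixture arithmetic, deterministic renderers.
# All rounding here is nearest-with-ties-away-from-zero, one decimal for
# shares and rates, whole children for lives saved — the convention every
# printed cell of the packaged tables follows.

#' Percentage shares of lives saved by channel
#'
#' Shares are computed from the unrounded channel values against the
#' unrounded total, then rounded to one decimal; displayed lives-saved values
#' are rounded to integers. Negative channels (coverage fell) yield negative
#' shares. The total row is the rounded sum of the unrounded values.
#'
#' @param values Named numeric vector, channel -> lives saved (may be an
#'   unrounded engine output or printed integers).
#' @return A data frame of class `share_table` with columns `channel`,
#'   `lives_saved` (rounded), `share` (percent, one decimal), plus attributes
#'   `total` (rounded) and `total_unrounded`.
#' @examples
#' shares(c(a = 300, b = 100))
#' @export
shares <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values) || all(values == 0)) stop("empty share base")
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop_validation("shares: values must be named by channel")
  }
  total <- sum(values)
  out <- data.frame(channel = names(values),
                    lives_saved = round_half_away(as.numeric(values)),
                    share = round_half_away(100 * as.numeric(values) / total, 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, total = round_half_away(total), total_unrounded = total,
            class = c("share_table", "data.frame"))
}

#' @export
print.share_table <- function(x, ...) {
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("%-45s %10s(%s)\n", df$channel[i], format_count(df$lives_saved[i]),
                formatC(df$share[i], format = "f", digits = 1)))
  }
  cat(sprintf("%-45s %10s(100)\n", "Total", format_count(attr(x, "total"))))
  invisible(x)
}

#' Sum a printed lives-saved column of a packaged fixture
#'
#' Integer sum of the per-row printed values; `NA` cells (channels disabled in
#' the table's mode) are skipped; negative rows (coverage declines) are
#' included.
#'
#' @param table A fixture data frame from [load_fixture()].
#' @param column Name of the numeric column to sum.
#' @return Integer total.
#' @examples
#' \dontrun{aggregate_fixture(load_fixture("table1"), "lives_saved_direct")}
#' @export
aggregate_fixture <- function(table, column) {
  if (!column %in% names(table)) {
    stop_validation("aggregate_fixture: unknown column '", column, "'")
  }
  as.integer(round_half_away(sum(table[[column]], na.rm = TRUE)))
}

#' Coverage change in percentage points
#'
#' `endline - baseline`, rounded to one decimal; rows with a missing anchor
#' return `NA`.
#'
#' @param table A data frame with `baseline_coverage` and `endline_coverage`
#'   columns (percent).
#' @param row Optional row label (matched against the first column); default
#'   computes the whole column.
#' @return Numeric vector (or scalar if `row` given) of percentage-point
#'   changes.
#' @export
coverage_change <- function(table, row = NULL) {
  need <- c("baseline_coverage", "endline_coverage")
  if (!all(need %in% names(table))) {
    stop_validation("coverage_change: table lacks ", paste(need, collapse = "/"),
                    " columns")
  }
  if (!is.null(row)) {
    i <- match(row, table[[1]])
    if (is.na(i)) stop_validation("coverage_change: unknown row '", row, "'")
    table <- table[i, , drop = FALSE]
  }
  round_half_away(table$endline_coverage - table$baseline_coverage, 1)
}

#' Render a result deterministically
#'
#' Serialises a [lives_saved()] result, a [shares()] table, or a
#' [missed_opportunity()] ranking with stable row ordering and fixed decimal
#' formatting, so that the same input always produces the same bytes. CSV is
#' the canonical machine format (plain integers, no thousands separators);
#' `text` is the human-readable `value(share)` style with thousands
#' separators; `json` uses row-wise records.
#'
#' @param x Object to render.
#' @param format `"csv"`, `"json"`, or `"text"`.
#' @param path Optional file path; when given, the lines are written there.
#' @param ... Unused.
#' @return Character vector of output lines, invisibly when `path` is given.
#' @export
render <- function(x, format = c("csv", "json", "text"), path = NULL, ...) {
  UseMethod("render")
}

render_finish <- function(lines, path) {
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

df_to_csv <- function(df, formats) {
  cols <- names(formats)
  body <- vapply(seq_len(nrow(df)), function(i) {
    paste(vapply(cols, function(cl) {
      v <- df[[cl]][i]
      if (is.na(v)) "NA"
      else if (is.character(v)) v
      else if (formats[[cl]] == "%d") sprintf("%d", as.integer(v))
      else sprintf(formats[[cl]], v)
    }, character(1)), collapse = ",")
  }, character(1))
  c(paste(cols, collapse = ","), body)
}

df_to_json <- function(df) {
  as.character(jsonlite::toJSON(df, dataframe = "rows", digits = 10,
                                na = "null", pretty = FALSE))
}

#' @rdname render
#' @export
render.share_table <- function(x, format = c("csv", "json", "text"),
                               path = NULL, ...) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  lines <- switch(format,
    csv = {
      body <- df_to_csv(df, c(channel = "%s", lives_saved = "%d", share = "%.1f"))
      c(body, sprintf("Total,%d,100.0", as.integer(attr(x, "total"))))
    },
    json = df_to_json(rbind(df, data.frame(channel = "Total",
                                           lives_saved = attr(x, "total"),
                                           share = 100))),
    text = c(
      vapply(seq_len(nrow(df)), function(i) {
        sprintf("%-45s %12s(%s)", df$channel[i], format_count(df$lives_saved[i]),
                formatC(df$share[i], format = "f", digits = 1))
      }, character(1)),
      sprintf("%-45s %12s(100)", "Total", format_count(attr(x, "total")))))
  render_finish(lines, path)
}

#' @rdname render
#' @export
render.lives_saved_result <- function(x, format = c("csv", "json", "text"),
                                      path = NULL, ...) {
  format <- match.arg(format)
  led <- x$ledger[order(x$ledger$channel, x$ledger$year, x$ledger$age_band), ,
                  drop = FALSE]
  rownames(led) <- NULL
  lines <- switch(format,
    csv = df_to_csv(led, c(channel = "%s", year = "%d", age_band = "%s",
                           averted = "%.6f")),
    json = df_to_json(led),
    text = {
      st <- shares(x$totals)
      c(sprintf("Lives saved %d-%d (%s)", x$span[["t0"]], x$span[["t1"]], x$mode),
        render(st, "text"))
    })
  render_finish(lines, path)
}

#' @rdname render
#' @export
render.mot_table <- function(x, format = c("csv", "json", "text"),
                             path = NULL, ...) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  df$averted_neonatal <- round_half_away(df$averted_neonatal)
  df$averted_1to59 <- round_half_away(df$averted_1to59)
  df$averted_total <- round_half_away(df$averted_total)
  lines <- switch(format,
    csv = df_to_csv(df, c(intervention_id = "%s", name = "%s",
                          baseline_coverage = "%.1f", averted_neonatal = "%d",
                          averted_1to59 = "%d", averted_total = "%d")),
    json = df_to_json(df),
    text = c(sprintf("Missed opportunities: scale-up to %s%% over %d years",
                     formatC(attr(x, "threshold"), format = "fg"),
                     as.integer(attr(x, "horizon"))),
             vapply(seq_len(nrow(df)), function(i) {
               sprintf("%-45s %6.1f %10s %10s", df$name[i],
                       df$baseline_coverage[i],
                       format_count(df$averted_neonatal[i]),
                       format_count(df$averted_1to59[i]))
             }, character(1))))
  render_finish(lines, path)
}
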