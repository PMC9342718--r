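# Methods for lives_saved_result objects.

#' @export
print.lives_saved_result <- function(x, ...) {
  cat("Lives-saved evaluation (", x$mode, "), ",
      x$span[["t0"]], " -> ", x$span[["t1"]], "\n", sep = "")
  cat("  grand total:", format_count(x$grand_total), "deaths averted\n")
  top <- sort(x$totals, decreasing = TRUE)
  top <- top[seq_len(min(5L, length(top)))]
  if (length(top) && is.finite(x$grand_total) && x$grand_total != 0) {
    cat("  leading channels:\n")
    for (ch in names(top)) {
      cat(sprintf("    %-30s %10s (%s%%)\n", ch, format_count(top[[ch]]),
                  formatC(round_half_away(x$shares[[ch]], 1), format = "f", digits = 1)))
    }
  }
  invisible(x)
}

#' @export
summary.lives_saved_result <- function(object, ...) {
  by_band <- tapply(object$ledger$averted, object$ledger$age_band, sum)
  last <- object$rates[which.max(object$rates$year), ]
  structure(
    list(mode = object$mode, span = object$span,
         grand_total = object$grand_total,
         by_band = by_band[AGE_BANDS],
         totals = sort(object$totals, decreasing = TRUE),
         shares = object$shares,
         endline_rates = last),
    class = "summary.lives_saved_result")
}

#' @export
print.summary.lives_saved_result <- function(x, ...) {
  cat("Lives-saved evaluation (", x$mode, "), ",
      x$span[["t0"]], " -> ", x$span[["t1"]], "\n", sep = "")
  cat("  deaths averted: ", format_count(x$grand_total),
      "  (neonatal ", format_count(x$by_band[["neonatal"]]),
      ", 1-59 months ", format_count(x$by_band[["1-59 months"]]), ")\n", sep = "")
  cat("  endline scenario rates: NMR ",
      formatC(round_half_away(x$endline_rates$nmr, 1), format = "f", digits = 1),
      ", U5MR ",
      formatC(round_half_away(x$endline_rates$u5mr, 1), format = "f", digits = 1),
      " per 1,000 live births\n", sep = "")
  cat("  per-channel totals:\n")
  for (ch in names(x$totals)) {
    cat(sprintf("    %-30s %10s\n", ch, format_count(x$totals[[ch]])))
  }
  invisible(x)
}

#' @export
as.data.frame.lives_saved_result <- function(x, ...) {
  x$ledger
}

#' Bar chart of per-channel shares of lives saved
#'
#' @param x A `lives_saved_result`.
#' @param top Number of channels to display (largest absolute totals).
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot.lives_saved_result <- function(x, top = 15L, ...) {
  tot <- x$totals[order(-abs(x$totals))]
  tot <- tot[seq_len(min(top, length(tot)))]
  graphics::barplot(rev(tot), horiz = TRUE, las = 1,
                    xlab = "deaths averted",
                    main = paste0("Lives saved ", x$span[["t0"]], "-",
                                  x$span[["t1"]], " (", x$mode, ")"),
                    cex.names = 0.7, ...)
}
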