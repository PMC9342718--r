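#' Load a packaged evaluation table
#'
#' The package ships, as plain tab-separated fixtures, the printed tables of a
#' published Ghana 2008-2014 lives-saved evaluation: the baseline/endline
#' coverage and per-channel lives-saved table in both analysis modes
#' (`"table1"`), the 90% one-at-a-time missed-opportunity ranking
#' (`"table2"`), the 100% universal scale-up table (`"table3"`), and the
#' baseline/endline mortality rates with provenance notes (`"rates"`). Values
#' are transcribed exactly as printed: coverages as decimals, lives saved as
#' integers, and `NA` marking channels disabled in a mode (never zero —
#' zero means "no lives saved"). These tables are the acceptance surface for
#' the reporting arithmetic; the tool's internal effectiveness and
#' affected-fraction database behind them is not published and is not
#' reproduced here.
#'
#' @param table One of `"table1"`, `"table2"`, `"table3"`, `"rates"`.
#' @return A data frame with the printed rows and columns.
#' @examples
#' t1 <- load_fixture("table1")
#' sum(t1$lives_saved_direct, na.rm = TRUE)  # 48084
#' @export
load_fixture <- function(table = c("table1", "table2", "table3", "rates")) {
  table <- match.arg(table)
  path <- system.file("extdata", "fixtures", paste0(table, ".tsv"),
                      package = "livesaved", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", comment.char = "#", quote = "",
                    na.strings = "NA", check.names = TRUE,
                    stringsAsFactors = FALSE)
}
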