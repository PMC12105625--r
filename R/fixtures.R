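# Packaged transcriptions of the benchmark/prediction tables: experimental
# potentials and pKa ladders, gas-phase/acetonitrile benchmark, aqueous
# M1/M2, aqueous M3/M4, absolute M1/M4 predictions and the linearly
# adjusted values. Each CSV ships with a sidecar JSON describing units,
# censored columns and footnotes (e.g. the mole fractions used by the
# mixed-pathway rows).

.fixture_files <- c(table1 = "table1_experimental",
                    table2 = "table2_benchmark",
                    table3 = "table3_aqueous_m1_m2",
                    table4 = "table4_aqueous_m3_m4",
                    table5 = "table5_absolute",
                    table6 = "table6_adjusted")

#' Load a packaged table fixture
#'
#' Censored entries (printed as ">x") are parsed to their bound value with
#' a `<column>_censoring` companion column flagging `"lower_bound"`; all
#' other entries are flagged `"exact"`. The sidecar metadata (units,
#' footnotes, printed summary metrics) is attached as the `"meta"`
#' attribute, and the verbatim printed strings as the `"printed"`
#' attribute.
#'
#' @param table One of `"table1"` ... `"table6"`.
#' @return A data.frame with parsed numeric columns.
#' @export
load_fixture <- function(table = c("table1", "table2", "table3", "table4",
                                   "table5", "table6")) {
  table <- match.arg(table)
  stem <- .fixture_files[[table]]
  csv <- system.file("extdata", paste0(stem, ".csv"), package = "redoxpH",
                     mustWork = TRUE)
  meta <- jsonlite::read_json(system.file("extdata", paste0(stem, ".json"),
                                          package = "redoxpH", mustWork = TRUE),
                              simplifyVector = TRUE)
  raw <- utils::read.csv(csv, colClasses = "character", check.names = FALSE)
  df <- raw
  for (col in meta$numeric_columns) {
    x <- trimws(raw[[col]])
    censored <- grepl("^>", x)
    df[[col]] <- suppressWarnings(as.numeric(sub("^>", "", x)))
    if (col %in% meta$censored_columns) {
      df[[paste0(col, "_censoring")]] <-
        ifelse(x == "", NA_character_,
               ifelse(censored, "lower_bound", "exact"))
    }
  }
  attr(df, "meta") <- meta
  attr(df, "printed") <- raw
  df
}
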