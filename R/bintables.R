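#' Load the bundled declarative bin-table resource
#'
#' The scoresheet and the comparator point tables also ship as versioned JSON
#' transcriptions under `inst/extdata/`, so the code tables can be diffed
#' against an independent declarative source (the test suite does exactly
#' that).
#'
#' @param score one of `"incns"`, `"apache2"`, `"saps2"`.
#' @return the parsed JSON as a list.
#' @export
load_bin_table <- function(score = c("incns", "apache2", "saps2")) {
  score <- match.arg(score)
  path <- system.file("extdata", paste0(score, "_bins.json"),
                      package = "incns", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# JSON bins -> the internal (lower, points, digits) representation,
# for the code-vs-transcription diff tests
json_bins_to_internal <- function(item) {
  lo <- vapply(item$bins, function(b) b$lo %||% -Inf, numeric(1))
  pts <- vapply(item$bins, function(b) as.integer(b$points), integer(1))
  ord <- order(lo)
  list(digits = as.integer(item$digits), lower = lo[ord][-1],
       points = pts[ord])
}
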