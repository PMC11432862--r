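#' Write a visit table to CSV with a JSON column dictionary
#'
#' Nested columns (`vitals`, `labs`, `order_counts`) are serialized as JSON
#' strings inside the CSV so the file stays a plain-text single table; a
#' `<path>.dict.json` sidecar records column types for faithful reading.
#'
#' @param table a `visit_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  flat <- as.data.frame(table[setdiff(names(table),
                                      c("vitals", "labs", "order_counts"))])
  for (col in c("vitals", "labs", "order_counts")) {
    flat[[col]] <- vapply(table[[col]], function(v)
      as.character(jsonlite::toJSON(as.list(v), auto_unbox = FALSE,
                                    digits = NA)),
      character(1))
  }
  utils::write.csv(flat, path, row.names = FALSE)
  dict <- lapply(flat, function(col) class(col)[1])
  dict$vitals <- dict$labs <- dict$order_counts <- "json"
  jsonlite::write_json(dict, paste0(path, ".dict.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a visit table written by [write_cohort()]
#'
#' @param path CSV path.
#' @return a `visit_table`.
#' @export
read_cohort <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("vitals", "labs")) {
    flat[[col]] <- lapply(flat[[col]], function(s)
      lapply(jsonlite::fromJSON(s, simplifyVector = TRUE), as.numeric))
  }
  flat$order_counts <- lapply(flat$order_counts, function(s) {
    v <- jsonlite::fromJSON(s, simplifyVector = TRUE)
    if (length(v)) vapply(v, as.integer, integer(1)) else integer(0)
  })
  class(flat) <- c("visit_table", "data.frame")
  flat
}
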