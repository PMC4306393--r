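# JSON interchange for coefficient sets and band tables.

.JSON_SCHEMA_VERSION <- 1L

#' Read / write a coefficient file
#'
#' JSON interchange for score coefficient sets, with explicit field names
#' and a `schema_version`, so alternative coefficient sets (e.g. a refit on
#' another cohort) can be shipped and loaded without code changes.
#'
#' @param path file path.
#' @return `read_coefficients` returns a [suspekt_coefficients()] object;
#'   `write_coefficients` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$schema_version) || j$schema_version != .JSON_SCHEMA_VERSION)
    .stopf("unsupported coefficient-file schema_version")
  b <- j$coefficients
  need <- c("b_glucose", "b_relvol", "b_sbp", "b_ivh", "b_potassium",
            "b_potassium_sq", "b_age", "constant")
  miss <- setdiff(need, names(b))
  if (length(miss)) .stopf("coefficient file missing field(s): %s", paste(miss, collapse = ", "))
  do.call(suspekt_coefficients, lapply(b[need], as.numeric))
}

#' @rdname read_coefficients
#' @param b a [suspekt_coefficients()] object.
#' @export
write_coefficients <- function(b, path) {
  stopifnot(inherits(b, "suspekt_coefficients"))
  v <- unclass(b)
  jsonlite::write_json(list(
    schema_version = .JSON_SCHEMA_VERSION,
    coefficients = list(b_glucose = v[["glucose"]], b_relvol = v[["relvol"]],
                        b_sbp = v[["sbp"]], b_ivh = v[["ivh"]],
                        b_potassium = v[["potassium"]],
                        b_potassium_sq = v[["potassium_sq"]],
                        b_age = v[["age"]], constant = v[["constant"]])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a band-table file
#'
#' JSON interchange for percentile band tables (11 anchors: minimum,
#' 10th--90th percentiles, maximum).
#'
#' @param path file path.
#' @return `read_band_table` returns a [suspekt_band_table()];
#'   `write_band_table` returns `path` invisibly.
#' @export
read_band_table <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$schema_version) || j$schema_version != .JSON_SCHEMA_VERSION)
    .stopf("unsupported band-table schema_version")
  suspekt_band_table(as.numeric(j$anchors))
}

#' @rdname read_band_table
#' @param table a [suspekt_band_table()] object.
#' @export
write_band_table <- function(table, path) {
  stopifnot(inherits(table, "band_table"))
  jsonlite::write_json(list(schema_version = .JSON_SCHEMA_VERSION,
                            anchors = as.numeric(table)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
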