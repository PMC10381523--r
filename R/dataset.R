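## Builtin study table and tabular I/O.
##
## The table is stored flat: one row per biomaterial, composition in wt%,
## each measured property as <prop>_mean / <prop>_sd / <prop>_n. Group means
## are used throughout because the per-sample histomorphometry is not
## published (n = 6 for macroporosity, BMC and regenerated area; n = 3
## images for the roughness parameters).

#' @keywords internal
gpls_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "graftPLS_error")))
}

.composition_cols <- c("hap_wt", "btcp_wt", "caco3_wt", "collagen_wt",
                       "h2o_wt", "ti_wt")
.property_cols <- c("macroporosity", "pa", "pt", "pq", "bmc_6mo",
                    "regenerated_area_6mo")
.percent_props <- c("macroporosity", "bmc_6mo", "regenerated_area_6mo")

.graft_table_cols <- function() {
  c("name", "origin", .composition_cols, "size_min_um", "size_max_um",
    as.vector(t(outer(.property_cols, c("mean", "sd", "n"), paste, sep = "_"))))
}

#' Validate and class a graft study table
#'
#' Checks the flat one-row-per-biomaterial schema: composition columns in
#' wt% summing to 95--105 (rounding slack), percent-valued means in
#' \[0, 100\], non-negative SDs, counts >= 1 and unique names.
#'
#' @param x data frame with the columns listed in the CSV schema
#'   (see [write_graft_table()]).
#' @return `x` with class `graft_table` prepended.
#' @export
as_graft_table <- function(x) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(.graft_table_cols(), names(x))
  if (length(missing_cols) > 0L)
    gpls_error(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
               "graftPLS_schema_error")
  if (nrow(x) == 0L)
    gpls_error("table has no rows", "graftPLS_schema_error")
  if (anyDuplicated(x$name))
    gpls_error("biomaterial names must be unique", "graftPLS_schema_error")

  comp <- as.matrix(x[, .composition_cols])
  if (any(!is.finite(comp)) || any(comp < 0) || any(comp > 100))
    gpls_error("composition wt% must lie in [0, 100]", "graftPLS_range_error")
  csum <- rowSums(comp)
  if (any(csum < 95 | csum > 105))
    gpls_error("composition wt% must sum to 95-105 per biomaterial",
               "graftPLS_range_error")
  for (p in .property_cols) {
    m <- x[[paste0(p, "_mean")]]
    s <- x[[paste0(p, "_sd")]]
    n <- x[[paste0(p, "_n")]]
    if (any(!is.finite(m)))
      gpls_error(paste0("non-finite mean in ", p), "graftPLS_range_error")
    if (p %in% .percent_props && any(m < 0 | m > 100))
      gpls_error(paste0(p, " mean must lie in [0, 100]"), "graftPLS_range_error")
    if (any(!is.finite(s)) || any(s < 0))
      gpls_error(paste0(p, " sd must be >= 0"), "graftPLS_range_error")
    if (any(!is.finite(n)) || any(n < 1))
      gpls_error(paste0(p, " n must be >= 1"), "graftPLS_range_error")
  }
  if (any(x$size_min_um > x$size_max_um))
    gpls_error("particle size interval must have min <= max",
               "graftPLS_range_error")
  class(x) <- c("graft_table", "data.frame")
  x
}

#' The seven-biomaterial study table
#'
#' Composition (wt%), particle size, macroporosity, profile roughness
#' (Pa, Pt, Pq), six-month bone-to-material contact (BMC) and six-month
#' regenerated area for the seven commercial intra-oral graft substitutes,
#' as group means +/- SD.
#'
#' Two coding conventions are offered for the collagen-enriched Bio-Oss
#' variant, whose composition is only stated as the base granulate plus 10%
#' collagen: `"rescaled"` (default) mass-balances the base composition into
#' the final product (HAp 84.24, CaCO3 3.06, collagen 12.7), `"nominal"`
#' keeps CaCO3 at the base value 3.4 (HAp 83.6, collagen 13). MP3's
#' "bone mix" is coded as pure HAp; pre-hydration water and trace phases are
#' set to 0, since no finer decomposition is published.
#'
#' @param convention composition coding for BioOss-Collagen, `"rescaled"`
#'   or `"nominal"`.
#' @return A `graft_table` with 7 rows.
#' @examples
#' tab <- builtin_grafts()
#' tab[tab$name == "Ostim", c("h2o_wt", "macroporosity_mean", "bmc_6mo_mean")]
#' @export
builtin_grafts <- function(convention = c("rescaled", "nominal")) {
  convention <- match.arg(convention)
  bo_col <- switch(convention,
    rescaled = c(hap = 84.24, caco3 = 3.06, collagen = 12.7),
    nominal  = c(hap = 83.60, caco3 = 3.40, collagen = 13.0))

  tab <- data.frame(
    name   = c("BioOss", "BioOss-Collagen", "BoneCeramic", "Cerasorb",
               "MP3", "Natix", "Ostim"),
    origin = c("bovine", "bovine/porcine", "synthetic", "synthetic",
               "porcine", "synthetic", "synthetic"),
    hap_wt      = c(93.6, bo_col[["hap"]], 60, 0, 90, 0, 35),
    btcp_wt     = c(0, 0, 40, 100, 0, 0, 0),
    caco3_wt    = c(3.4, bo_col[["caco3"]], 0, 0, 0, 0, 0),
    collagen_wt = c(3, bo_col[["collagen"]], 0, 0, 10, 0, 0),
    h2o_wt      = c(0, 0, 0, 0, 0, 0, 65),
    ti_wt       = c(0, 0, 0, 0, 0, 100, 0),
    size_min_um = c(250, 250, 400, 500, 600, 700, 0.001),
    size_max_um = c(1000, 1000, 700, 1000, 1000, 1000, 0.05),
    macroporosity_mean = c(58.79, 65.73, 70.23, 63.44, 58.12, 67.12, 15.81),
    macroporosity_sd   = c(2.72, 4.07, 5.21, 3.83, 9.02, 1.94, 3.18),
    macroporosity_n    = rep(6L, 7),
    pa_mean = c(0.54, 0.67, 0.39, 1.35, 0.95, 1.29, 0.90),
    pa_sd   = c(0.19, 0.10, 0.01, 0.17, 0.02, 0.04, 0.07),
    pa_n    = rep(3L, 7),
    pt_mean = c(3.40, 3.70, 2.18, 5.81, 6.80, 6.85, 5.40),
    pt_sd   = c(1.04, 1.77, 0.28, 0.66, 2.12, 0.72, 0.65),
    pt_n    = rep(3L, 7),
    pq_mean = c(0.67, 0.84, 0.47, 1.52, 1.26, 1.55, 1.13),
    pq_sd   = c(0.24, 0.20, 0.04, 0.16, 0.11, 0.07, 0.14),
    pq_n    = rep(3L, 7),
    bmc_6mo_mean = c(49.01, 48.99, 25.94, 44.17, 33.68, 14.12, 53.98),
    bmc_6mo_sd   = c(4.4, 4.3, 10.9, 16.5, 8.3, 4.8, 14.7),
    bmc_6mo_n    = rep(6L, 7),
    regenerated_area_6mo_mean = c(96.42, 95.87, 95.63, 93.83, 85.02,
                                  95.95, 49.47),
    regenerated_area_6mo_sd   = c(3.27, 4.57, 5.09, 6.17, 15.43, 4.44, 16.14),
    regenerated_area_6mo_n    = rep(6L, 7),
    stringsAsFactors = FALSE
  )
  as_graft_table(tab)
}

#' Predictor names accepted by [design_matrix()]
#' @return character vector of valid predictor labels.
#' @export
graft_predictors <- function() {
  c(.composition_cols, "macroporosity", "pa", "pt", "pq")
}

#' Build a predictor matrix and BMC response from a graft table
#'
#' Scalar predictors take the mean of the corresponding measured property;
#' the response is always the six-month BMC group mean. Rows keep the table
#' order minus exclusions.
#'
#' @param table a `graft_table`.
#' @param predictors character vector drawn from [graft_predictors()].
#' @param exclude biomaterial names to drop.
#' @return list with `X` (numeric matrix, rownames = biomaterials),
#'   `y` (named numeric), `labels` (= colnames of `X`).
#' @examples
#' dm <- design_matrix(builtin_grafts(),
#'                     c("caco3_wt", "ti_wt", "macroporosity"))
#' dm$X["Natix", ]
#' @export
design_matrix <- function(table, predictors, exclude = character()) {
  table <- as_graft_table(table)
  bad <- setdiff(predictors, graft_predictors())
  if (length(bad) > 0L)
    gpls_error(paste0("unknown predictor(s): ", paste(bad, collapse = ", ")),
               "graftPLS_schema_error")
  bad <- setdiff(exclude, table$name)
  if (length(bad) > 0L)
    gpls_error(paste0("unknown biomaterial(s) in exclude: ",
                      paste(bad, collapse = ", ")), "graftPLS_schema_error")
  keep <- !(table$name %in% exclude)
  if (!any(keep))
    gpls_error("all rows excluded: empty design", "graftPLS_schema_error")
  tab <- table[keep, , drop = FALSE]
  cols <- ifelse(predictors %in% .composition_cols, predictors,
                 paste0(predictors, "_mean"))
  X <- as.matrix(tab[, cols, drop = FALSE])
  dimnames(X) <- list(tab$name, predictors)
  y <- setNames(tab$bmc_6mo_mean, tab$name)
  list(X = X, y = y, labels = predictors)
}

#' Read / write a graft study table
#'
#' CSV: one row per biomaterial, header mandatory, `.` decimal separator,
#' columns `name, origin, hap_wt, btcp_wt, caco3_wt, collagen_wt, h2o_wt,
#' ti_wt, size_min_um, size_max_um`, then `<prop>_mean, <prop>_sd, <prop>_n`
#' for each of `macroporosity, pa, pt, pq, bmc_6mo, regenerated_area_6mo`.
#' JSON: an array of record objects with the same fields. Write followed by
#' read is the identity on all fields to 1e-9.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return [read_graft_table()] returns a `graft_table`;
#'   [write_graft_table()] returns `path` invisibly.
#' @export
read_graft_table <- function(path, format = c("auto", "csv", "json")) {
  format <- .table_format(match.arg(format), path)
  if (!file.exists(path))
    gpls_error(paste0("no such file: ", path), "graftPLS_io_error")
  x <- tryCatch(
    switch(format,
      csv  = read.csv(path, stringsAsFactors = FALSE),
      json = as.data.frame(jsonlite::fromJSON(path))),
    error = function(e)
      gpls_error(paste0("malformed ", format, " file: ", conditionMessage(e)),
                 "graftPLS_parse_error"))
  as_graft_table(x)
}

#' @rdname read_graft_table
#' @param table a `graft_table` (or coercible data frame).
#' @export
write_graft_table <- function(table, path, format = c("auto", "csv", "json")) {
  table <- as_graft_table(table)
  format <- .table_format(match.arg(format), path)
  df <- as.data.frame(table)[, .graft_table_cols()]
  switch(format,
    csv  = write.csv(df, path, row.names = FALSE, quote = TRUE),
    json = jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                                auto_unbox = FALSE))
  invisible(path)
}

.table_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) return(ext)
  gpls_error(paste0("cannot infer table format from extension: ", path),
             "graftPLS_io_error")
}

#' @export
print.graft_table <- function(x, ...) {
  cat("Graft study table:", nrow(x), "biomaterials\n")
  print.data.frame(x[, c("name", "origin", .composition_cols,
                         "macroporosity_mean", "pa_mean", "bmc_6mo_mean")],
                   row.names = FALSE, ...)
  invisible(x)
}
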