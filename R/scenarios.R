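## The three published modelling scenarios, end to end.
##
## all_grafts: all seven biomaterials, predictors CaCO3 wt%, Ti wt%,
## macroporosity. exclude_natix: the six CaP-based grafts, Ti replaced by
## H2O wt%. exclude_ostim: the six non-paste grafts, same predictors as
## all_grafts. In each scenario the number of components is selected by
## leave-one-out RMSE and the fitted model is exported as an original-scale
## affine equation.

.scenario_presets <- list(
  all_grafts    = list(exclude = character(),
                       predictors = c("caco3_wt", "ti_wt", "macroporosity")),
  exclude_natix = list(exclude = "Natix",
                       predictors = c("caco3_wt", "h2o_wt", "macroporosity")),
  exclude_ostim = list(exclude = "Ostim",
                       predictors = c("caco3_wt", "ti_wt", "macroporosity"))
)

#' Describe a modelling scenario
#'
#' The three named presets carry the published predictor sets and
#' exclusions; `"custom"` takes free-form predictors and exclusions.
#'
#' @param name `"all_grafts"`, `"exclude_natix"`, `"exclude_ostim"` or
#'   `"custom"`.
#' @param predictors,exclude required for `"custom"`, ignored otherwise.
#' @param a_max optional cap on the number of components tried; default
#'   `min(p, n - 2)` evaluated against the design.
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(name = c("all_grafts", "exclude_natix",
                                   "exclude_ostim", "custom"),
                          predictors = NULL, exclude = NULL, a_max = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(predictors))
      gpls_error("custom scenario needs predictors", "graftPLS_schema_error")
    exclude <- exclude %||% character()
  } else {
    preset <- .scenario_presets[[name]]
    predictors <- preset$predictors
    exclude <- preset$exclude
  }
  structure(list(name = name, predictors = predictors, exclude = exclude,
                 a_max = a_max),
            class = "scenario_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one modelling scenario on a graft table
#'
#' Builds the design through [design_matrix()], selects the number of
#' components by LOO RMSE (capped at `min(p, n - 2)` and the spec's
#' `a_max`), fits the final model, and back-transforms the equation to
#' original units. Fully deterministic.
#'
#' @param table a `graft_table` (typically [builtin_grafts()]).
#' @param spec a `scenario_spec` or a preset name.
#' @param scale scale predictors/response to unit variance (default `TRUE`).
#' @return a `scenario_report`: list with `spec`, `labels`, `n`,
#'   `biomaterials`, `equation` (`pls_equation`), `model` (`pls_model`),
#'   `cv` (`pls_cv`), `loo_predictions` (held-out, at the selected A),
#'   `fitted`, `residuals` (measured - fitted), `measured`, `r_loo`,
#'   `r_fitted`, `hull` (per-predictor training min/max).
#' @examples
#' rep <- run_scenario(builtin_grafts(), "all_grafts")
#' rep$equation
#' rep$cv$selected
#' @export
run_scenario <- function(table, spec = "all_grafts", scale = TRUE) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  dm <- design_matrix(table, spec$predictors, spec$exclude)
  n <- nrow(dm$X); p <- ncol(dm$X)
  a_max <- min(spec$a_max %||% Inf, p, n - 2L)
  cv <- pls_loo(dm$X, dm$y, a_max = a_max, scale = scale)
  model <- pls_fit(dm$X, dm$y, ncomp = cv$selected, scale = scale)
  equation <- pls_equation(model)
  fitted <- predict(equation, dm$X)
  loo_pred <- cv$predictions[, cv$selected]
  structure(list(
    spec = spec, labels = dm$labels, n = n, biomaterials = rownames(dm$X),
    equation = equation, model = model, cv = cv,
    loo_predictions = loo_pred, fitted = fitted,
    residuals = dm$y - fitted, measured = dm$y,
    r_loo = prediction_correlation(loo_pred, dm$y),
    r_fitted = prediction_correlation(fitted, dm$y),
    hull = apply(dm$X, 2L, range)
  ), class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Scenario:", x$spec$name, " (n =", x$n, ")\n")
  cat("  ", format(x$equation), "\n")
  cat("   components:", x$cv$selected,
      "| LOO RMSE:", round(min(x$cv$rmse, na.rm = TRUE), 3),
      "| r (LOO):", round(x$r_loo, 3),
      "| r (fitted):", round(x$r_fitted, 3), "\n")
  invisible(x)
}

#' Run the three published scenarios and summarize them side by side
#'
#' @inheritParams run_scenario
#' @return list with `reports` (named list of `scenario_report`) and
#'   `summary` (data frame of intercepts and coefficients by scenario,
#'   plus selected components and the two correlation modes).
#' @export
run_all_scenarios <- function(table = builtin_grafts(), scale = TRUE) {
  names <- c("all_grafts", "exclude_natix", "exclude_ostim")
  reports <- lapply(names, function(nm) run_scenario(table, nm, scale = scale))
  names(reports) <- names
  all_labels <- unique(unlist(lapply(reports, `[[`, "labels")))
  summary <- do.call(rbind, lapply(reports, function(r) {
    co <- setNames(rep(NA_real_, length(all_labels)), all_labels)
    co[names(r$equation$coefficients)] <- r$equation$coefficients
    data.frame(scenario = r$spec$name, n = r$n,
               selected_A = r$cv$selected,
               intercept = r$equation$intercept, t(co),
               loo_rmse = min(r$cv$rmse, na.rm = TRUE),
               r_loo = r$r_loo, r_fitted = r$r_fitted,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(reports = reports, summary = summary)
}

#' Predict BMC for new physico-chemical characteristics
#'
#' Evaluates the scenario's original-scale equation on new predictor
#' values. Inputs outside the training hull (the per-predictor min/max box)
#' are flagged with a warning and recorded in the `outside_hull` attribute;
#' negative composition or porosity values are errors.
#'
#' @param object a `scenario_report`.
#' @param newdata data frame / matrix / named list with the scenario's
#'   predictor columns.
#' @param ... unused.
#' @return numeric predictions (%BMC) with attribute `outside_hull`
#'   (logical per row).
#' @examples
#' rep <- run_scenario(builtin_grafts(), "all_grafts")
#' predict(rep, data.frame(caco3_wt = 3.4, ti_wt = 0, macroporosity = 58.79))
#' @export
predict.scenario_report <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata))
    newdata <- as.data.frame(newdata)
  X <- .newdata_matrix(newdata, object$labels)
  if (any(X < 0))
    gpls_error("negative predictor values are not physical",
               "graftPLS_range_error")
  lo <- object$hull[1L, object$labels]
  hi <- object$hull[2L, object$labels]
  outside <- apply(X, 1L, function(r) any(r < lo | r > hi))
  if (any(outside))
    warning("input outside the training hull; extrapolating", call. = FALSE)
  out <- predict(object$equation, X)
  attr(out, "outside_hull") <- unname(outside)
  out
}

#' Serialize a scenario report to JSON (and back)
#'
#' The JSON carries the equation, CV curve, per-biomaterial predictions and
#' residuals, correlations and the training hull at full precision;
#' [scenario_report_from_json()] restores the numeric content (as plain
#' lists/vectors, not refitted objects).
#'
#' @param report a `scenario_report`.
#' @param path output file.
#' @return `path` invisibly; the reader returns the parsed list.
#' @export
scenario_report_json <- function(report, path) {
  stopifnot(inherits(report, "scenario_report"))
  obj <- list(
    package = "graftPLS",
    version = as.character(utils::packageVersion("graftPLS")),
    scenario = report$spec$name,
    predictors = report$labels,
    excluded = report$spec$exclude,
    n = report$n,
    biomaterials = report$biomaterials,
    equation = list(intercept = report$equation$intercept,
                    coefficients = as.list(report$equation$coefficients),
                    text = format(report$equation)),
    cv = list(rmse_by_components = as.list(report$cv$rmse),
              selected_A = report$cv$selected),
    loo_predictions = as.list(report$loo_predictions),
    fitted = as.list(report$fitted),
    residuals = as.list(report$residuals),
    measured = as.list(report$measured),
    r_loo = report$r_loo,
    r_fitted = report$r_fitted,
    hull = list(min = as.list(report$hull[1L, ]),
                max = as.list(report$hull[2L, ]))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname scenario_report_json
#' @export
scenario_report_from_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Coefficient summary of one report as a plain data frame (CSV-ready)
#'
#' @param report a `scenario_report`.
#' @return data frame with one row per term (intercept first).
#' @export
scenario_coefficients <- function(report) {
  stopifnot(inherits(report, "scenario_report"))
  data.frame(term = c("(intercept)", names(report$equation$coefficients)),
             estimate = c(report$equation$intercept,
                          unname(report$equation$coefficients)),
             stringsAsFactors = FALSE)
}
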