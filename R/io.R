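#' Read a model definition from CSV files
#'
#' The groups file has columns `name`, `role`, `B`, `PB`, `QB`, `Ui` and
#' optionally `catch`, `export`, `BA`. The diet file is a matrix with prey
#' names (optionally including `import`) in the first column and predator
#' names as remaining column headers.
#'
#' @param groups_file,diet_file CSV paths
#' @param name model name (defaults to the groups file name)
#' @return a [model_definition()]
#' @export
read_model_csv <- function(groups_file, diet_file,
                           name = sub("\\.csv$", "", basename(groups_file))) {
  g <- utils::read.csv(groups_file, stringsAsFactors = FALSE,
                       check.names = FALSE)
  d <- utils::read.csv(diet_file, stringsAsFactors = FALSE,
                       check.names = FALSE)
  rn <- d[[1]]
  diet <- as.matrix(d[, -1, drop = FALSE])
  rownames(diet) <- rn
  model_definition(g, diet, name = name)
}

#' Write a model definition to CSV files
#'
#' Inverse of [read_model_csv()]; values are written at full precision so a
#' write/read round trip is lossless.
#'
#' @param model a [model_definition()]
#' @param groups_file,diet_file output CSV paths
#' @return the input, invisibly
#' @export
write_model_csv <- function(model, groups_file, diet_file) {
  utils::write.csv(model$groups, groups_file, row.names = FALSE)
  d <- data.frame(prey = rownames(model$diet), model$diet,
                  check.names = FALSE)
  utils::write.csv(d, diet_file, row.names = FALSE)
  invisible(model)
}

#' Read and write a model definition as JSON
#'
#' One-to-one JSON mirror of the CSV interchange format.
#'
#' @param model a [model_definition()]
#' @param file JSON path
#' @return `write_model_json()` returns the input invisibly;
#'   `read_model_json()` returns a [model_definition()].
#' @export
write_model_json <- function(model, file) {
  payload <- list(name = model$name, groups = model$groups,
                  diet = list(prey = rownames(model$diet),
                              predators = colnames(model$diet),
                              values = unname(model$diet)))
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE)
  invisible(model)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  diet <- as.matrix(payload$diet$values)
  dimnames(diet) <- list(payload$diet$prey, payload$diet$predators)
  model_definition(as.data.frame(payload$groups), diet, name = payload$name)
}

#' Serialize an ENA index set to a one-row data frame
#'
#' Flat record keyed by model name, suitable for CSV/JSON reporting of one
#' ecosystem per row.
#'
#' @param indices an `ena_index_set`
#' @param name model name
#' @return one-row data frame
#' @export
index_set_record <- function(indices, name = "model") {
  cbind(data.frame(name = name), as.data.frame(unclass(indices)))
}

#' Write an evaluation result as a JSON report
#'
#' The report mirrors the published membership-table layout: one object per
#' indicator with its five grade memberships, the weighted aggregate vector,
#' and the final grade.
#'
#' @param evaluation an [evaluate_status()] result
#' @param file JSON path
#' @return the input, invisibly
#' @export
write_evaluation_json <- function(evaluation, file) {
  payload <- list(
    membership = as.data.frame(evaluation$membership),
    aggregate = as.list(evaluation$aggregate),
    grade = evaluation$grade
  )
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE)
  invisible(evaluation)
}

#' Write a scenario-suite report table
#'
#' Indicator values are rounded to two decimals at this reporting layer and
#' non-evaluable scenarios are marked `"/"`, mirroring the published
#' scenario tables; internal values keep full precision.
#'
#' @param suite a [run_scenario_suite()] result
#' @param file CSV path
#' @return the formatted data frame, invisibly
#' @export
write_suite_csv <- function(suite, file) {
  tab <- suite$table
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "scenario"
  out <- tab
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(tab[[j]]), "/", formatC(round(tab[[j]], 2),
                                                     format = "fg"))
  }
  out$grade[is.na(tab$grade)] <- "/"
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
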