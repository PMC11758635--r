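#' Define a static mass-balance food-web model
#'
#' A model definition couples a table of per-group input parameters with a
#' prey-by-predator diet-composition matrix. Groups are the functional groups
#' of an Ecopath-style model: consumers, primary producers, and exactly one
#' detritus pool. All biomasses are wet weight in t/km2, rates are per year,
#' and flows are t/km2/a.
#'
#' @param groups data frame with columns `name`, `role` (one of `"consumer"`,
#'   `"producer"`, `"detritus"`), `B` (biomass, t/km2), `PB` (production /
#'   biomass, /a), `QB` (consumption / biomass, /a; `NA` for producers and
#'   detritus), `Ui` (unassimilated fraction of consumption, 0--1; `NA` for
#'   producers and detritus). Optional columns `catch`, `export`, `BA`
#'   (biomass accumulation), all t/km2/a, default 0.
#' @param diet numeric matrix of diet fractions: `diet[i, j]` is the fraction
#'   of predator `j`'s consumption taken from prey `i`. Row names are group
#'   names, optionally plus a final `"import"` row; column names are group
#'   names. Consumer columns must sum to 1 (tolerance 1e-6); producer and
#'   detritus columns must be absent or all zero.
#' @param name model name used in reports.
#'
#' @return An object of class `model_definition`: a list with elements
#'   `groups`, `diet` (square living+detritus matrix plus import row,
#'   complete and ordered like `groups`), and `name`.
#' @export
#' @examples
#' g <- data.frame(
#'   name = c("phyto", "zoo", "det"),
#'   role = c("producer", "consumer", "detritus"),
#'   B = c(20, 2, 10), PB = c(100, 30, NA), QB = c(NA, 120, NA),
#'   Ui = c(NA, 0.3, NA)
#' )
#' d <- matrix(0, 3, 3, dimnames = list(g$name, g$name))
#' d["phyto", "zoo"] <- 0.7
#' d["det", "zoo"] <- 0.3
#' m <- model_definition(g, d, name = "toy")
model_definition <- function(groups, diet, name = "model") {
  stopifnot(is.data.frame(groups))
  required <- c("name", "role", "B", "PB")
  missing_cols <- setdiff(required, names(groups))
  if (length(missing_cols) > 0) {
    stop("groups table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  groups$name <- as.character(groups$name)
  groups$role <- match.arg(as.character(groups$role),
                           c("consumer", "producer", "detritus"),
                           several.ok = TRUE)
  if (anyDuplicated(groups$name)) stop("duplicated group names")
  for (col in c("QB", "Ui", "catch", "export", "BA")) {
    if (is.null(groups[[col]])) groups[[col]] <- NA_real_
  }
  groups$catch[is.na(groups$catch)] <- 0
  groups$export[is.na(groups$export)] <- 0
  groups$BA[is.na(groups$BA)] <- 0

  n_det <- sum(groups$role == "detritus")
  if (n_det != 1) stop("model must contain exactly one detritus group, found ", n_det)
  if (sum(groups$role == "producer") < 1) stop("model must contain at least one producer")

  with_rows <- function(msg, bad) {
    if (any(bad)) stop(msg, ": ", paste(groups$name[bad], collapse = ", "))
  }
  with_rows("negative biomass", groups$B < 0)
  cons <- groups$role == "consumer"
  with_rows("negative P/B", !is.na(groups$PB) & groups$PB < 0)
  with_rows("detritus must not carry P/B",
            groups$role == "detritus" & !is.na(groups$PB))
  with_rows("consumers need Q/B > 0", cons & (is.na(groups$QB) | groups$QB <= 0))
  with_rows("consumers need Ui in [0, 1)",
            cons & (is.na(groups$Ui) | groups$Ui < 0 | groups$Ui >= 1))
  with_rows("producers/detritus must not carry Q/B or Ui",
            !cons & (!is.na(groups$QB) | !is.na(groups$Ui)))
  with_rows("negative catch/export", groups$catch < 0 | groups$export < 0)

  diet <- normalize_diet(diet, groups)

  structure(list(groups = groups, diet = diet, name = name),
            class = "model_definition")
}

# Expand/validate the diet matrix into a full (n_groups + import) x n_groups
# matrix in group order. Unknown row/column names are an error.
normalize_diet <- function(diet, groups) {
  if (!is.matrix(diet)) diet <- as.matrix(diet)
  storage.mode(diet) <- "double"
  nm <- groups$name
  bad_rows <- setdiff(rownames(diet), c(nm, "import"))
  bad_cols <- setdiff(colnames(diet), nm)
  if (length(bad_rows) > 0) stop("unknown diet prey rows: ", paste(bad_rows, collapse = ", "))
  if (length(bad_cols) > 0) stop("unknown diet predator columns: ", paste(bad_cols, collapse = ", "))

  full <- matrix(0, nrow = length(nm) + 1L, ncol = length(nm),
                 dimnames = list(c(nm, "import"), nm))
  full[rownames(diet), colnames(diet)] <- diet
  if (any(!is.finite(full))) stop("non-finite diet entries")
  if (any(full < -1e-12) || any(full > 1 + 1e-12)) {
    stop("diet fractions must lie in [0, 1]")
  }
  full[full < 0] <- 0

  cons <- groups$role == "consumer"
  csum <- colSums(full)
  bad <- cons & abs(csum - 1) > 1e-6
  if (any(bad)) {
    stop("consumer diet columns must sum to 1: ",
         paste(sprintf("%s (%.6f)", nm[bad], csum[bad]), collapse = ", "))
  }
  if (any(!cons & csum > 1e-12)) {
    stop("producer/detritus diet columns must be all zero: ",
         paste(nm[!cons & csum > 1e-12], collapse = ", "))
  }
  full
}

#' @export
print.model_definition <- function(x, ...) {
  cat(sprintf("<model_definition> %s: %d groups (%d consumers, %d producers)\n",
              x$name, nrow(x$groups),
              sum(x$groups$role == "consumer"),
              sum(x$groups$role == "producer")))
  invisible(x)
}

#' Number of groups of a model definition
#' @param model a `model_definition`
#' @return integer
#' @export
n_groups <- function(model) nrow(model$groups)

# Convenience accessors used across modules.
group_names <- function(model) model$groups$name
is_consumer <- function(model) model$groups$role == "consumer"
is_producer <- function(model) model$groups$role == "producer"
is_detritus <- function(model) model$groups$role == "detritus"
living <- function(model) model$groups$role != "detritus"
diet_living <- function(model) model$diet[group_names(model), , drop = FALSE]
diet_import <- function(model) model$diet["import", ]
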