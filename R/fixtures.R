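#' Load a packaged fixture
#'
#' The package ships transcriptions of the published marine-ranching study
#' tables: per-group parameter tables for the marine ranching (23 groups)
#' and control (19 groups) ecosystems, the quintile grade scale, the
#' indicator weights, the system attribute totals, the published ENA
#' indicator values, and the carrying-capacity table.
#'
#' The group tables carry the published trophic levels and ecotrophic
#' efficiencies in `TL_published` / `EE_published` columns for reference; the
#' study's full diet-composition matrices were published only in appendix
#' material that is not packaged, so `diet` in the returned model fixtures is
#' `NULL` and flagged as a placeholder — these fixtures support parameter
#' lookups and trophic-structure sums, not full re-solution.
#'
#' @param name one of `"ranch"`, `"control"`, `"grade_scale"`, `"weights"`,
#'   `"attributes"`, `"ena_indices"`, `"capacity"`
#' @return for the ecosystem fixtures, a list with `groups` (data frame) and
#'   `diet = NULL` (attribute `placeholder = TRUE`); `"grade_scale"` returns
#'   a [grade_scale()]; `"weights"` a named numeric vector; `"attributes"`
#'   a list of two [attribute_record()]s plus published TSTs;
#'   `"ena_indices"` a list of two named indicator vectors; `"capacity"` a
#'   data frame.
#' @export
load_fixture <- function(name = c("ranch", "control", "grade_scale",
                                  "weights", "attributes", "ena_indices",
                                  "capacity")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "ranchena",
                                  mustWork = TRUE)
  read <- function(f) utils::read.csv(path(f), check.names = FALSE,
                                      stringsAsFactors = FALSE)
  switch(name,
    ranch = ,
    control = {
      g <- read(paste0(name, "_groups.csv"))
      out <- list(groups = g, diet = NULL, name = name)
      attr(out, "placeholder_diet") <- TRUE
      out
    },
    grade_scale = {
      d <- read("grade_scale.csv")
      pts <- as.matrix(d[, 2:6])
      rownames(pts) <- d$indicator
      grade_scale(pts)
    },
    weights = {
      d <- read("weights.csv")
      stats::setNames(d$weight, d$indicator)
    },
    attributes = {
      d <- read("attributes.csv")
      val <- function(eco, what) d[[eco]][d$attribute == what]
      mk <- function(eco) attribute_record(
        total_consumption = val(eco, "total_consumption"),
        total_export = val(eco, "total_export"),
        total_respiration = val(eco, "total_respiration"),
        total_flow_to_detritus = val(eco, "total_flow_to_detritus"),
        total_production = val(eco, "total_production"),
        total_primary_production = val(eco, "total_primary_production"),
        total_biomass = val(eco, "total_biomass"),
        name = eco
      )
      list(ranch = mk("ranch"), control = mk("control"),
           TST_published = c(ranch = val("ranch", "TST_published"),
                             control = val("control", "TST_published")))
    },
    ena_indices = {
      d <- read("ena_indices.csv")
      list(ranch = stats::setNames(d$ranch, d$indicator),
           control = stats::setNames(d$control, d$indicator))
    },
    capacity = read("capacity.csv")
  )
}
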