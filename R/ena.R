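#' System-level flow and biomass attributes
#'
#' Sums each flow class over groups: total consumption, total export
#' (catches plus other exports plus the unconsumed detritus surplus), total
#' respiration, and total flow to detritus. Total system throughput (TST) is
#' by definition the sum of those four classes. Also reports total
#' production, total primary production (TPP), total living biomass, and each
#' class's share of TST.
#'
#' @param balanced a [solve_mass_balance()] result
#' @return an `attribute_summary` (see [attribute_record()]).
#' @export
attribute_summary <- function(balanced) {
  g <- balanced$definition$groups
  live <- g$role != "detritus"
  attribute_record(
    total_consumption = sum(balanced$Q),
    total_export = sum(balanced$export),
    total_respiration = sum(balanced$R),
    total_flow_to_detritus = sum(balanced$flow_to_detritus),
    total_production = sum(balanced$P[live]),
    total_primary_production = sum(balanced$P[g$role == "producer"]),
    total_biomass = sum(g$B[live]),
    name = balanced$definition$name
  )
}

#' Assemble an attribute summary from flow totals
#'
#' Useful when the four flow-class totals are known (e.g. transcribed from a
#' published table) but the underlying model is not. TST is always computed
#' as the exact four-component sum.
#'
#' @param total_consumption,total_export,total_respiration,total_flow_to_detritus
#'   flow-class totals, t/km2/a
#' @param total_production,total_primary_production total (living) production
#'   and primary production, t/km2/a
#' @param total_biomass total living biomass, t/km2
#' @param name label
#' @return an `attribute_summary` list with the inputs, `TST`, and
#'   `share_of_TST` (fraction of TST in each flow class).
#' @export
attribute_record <- function(total_consumption, total_export,
                             total_respiration, total_flow_to_detritus,
                             total_production = NA_real_,
                             total_primary_production = NA_real_,
                             total_biomass = NA_real_, name = "model") {
  tst <- total_consumption + total_export + total_respiration +
    total_flow_to_detritus
  structure(list(
    name = name,
    total_consumption = total_consumption,
    total_export = total_export,
    total_respiration = total_respiration,
    total_flow_to_detritus = total_flow_to_detritus,
    TST = tst,
    total_production = total_production,
    total_primary_production = total_primary_production,
    total_biomass = total_biomass,
    share_of_TST = c(consumption = total_consumption,
                     export = total_export,
                     respiration = total_respiration,
                     flow_to_detritus = total_flow_to_detritus) / tst
  ), class = "attribute_summary")
}

#' @export
print.attribute_summary <- function(x, ...) {
  cat(sprintf("<attribute_summary> %s: TST = %.2f t/km2/a\n", x$name, x$TST))
  invisible(x)
}

#' Pairwise ratios between two attribute summaries
#'
#' @param a,b `attribute_summary` objects (numerator / denominator)
#' @return named vector of ratios for TST, total production, and total
#'   biomass.
#' @export
attribute_ratios <- function(a, b) {
  c(TST = a$TST / b$TST,
    total_production = a$total_production / b$total_production,
    total_biomass = a$total_biomass / b$total_biomass)
}

# Apportion every group's throughput over integer trophic levels.
# f[j, k] is the fraction of group j's ingestion acting at integer TL k:
# producers and detritus are wholly at level 1; a consumer's level-k fraction
# is the diet-weighted level-(k-1) fraction of its prey, with imports at
# level 1 (hence entering the consumer at level 2). The forward recursion is
# truncated once the residual mass is below `tol` and rows are renormalised.
tl_fractions <- function(balanced, max_tl = 50L, tol = 1e-10) {
  model <- balanced$definition
  nm <- group_names(model)
  n <- length(nm)
  dc <- diet_living(model)
  cons <- is_consumer(model)
  imp <- diet_import(model)

  fr <- matrix(0, n, max_tl, dimnames = list(nm, NULL))
  fr[!cons, 1] <- 1
  for (k in 2:max_tl) {
    fr[cons, k] <- as.numeric(t(dc[, cons, drop = FALSE]) %*% fr[, k - 1]) +
      if (k == 2) imp[cons] else 0
    if (all(abs(rowSums(fr) - 1) < tol)) break
  }
  keep <- which(colSums(fr) > 0)
  fr <- fr[, seq_len(max(keep)), drop = FALSE]
  sweep(fr, 1, rowSums(fr), `/`)
}

#' Lindeman spine: flows aggregated onto integer trophic levels
#'
#' Each group's consumption is apportioned over integer trophic levels by its
#' fractional trophic composition (derived from the diet matrix); producers
#' and detritus occupy level I. Transfer efficiency (TE) at a level is the
#' flow passed on to the next level plus the exports leaving at that level,
#' divided by the level's throughput.
#'
#' @param balanced a [solve_mass_balance()] result
#' @param te_levels integer levels over which the mean TE is taken
#'   (default II--V).
#' @param te_mean `"geometric"` (default) or `"arithmetic"` averaging of the
#'   step efficiencies.
#' @return a `lindeman_spine` list: `throughput` per level (level I holds
#'   primary production plus detrital inflow), `inflow` per level (ingestion
#'   arriving at levels >= II), `passed_on` (flow from each level to the
#'   next), `exports` per level, `TE` per level, `TE_mean` (percent),
#'   `detritivory`, `herbivory`, and `DH`.
#' @export
lindeman_spine <- function(balanced, te_levels = 2:5,
                           te_mean = c("geometric", "arithmetic")) {
  te_mean <- match.arg(te_mean)
  model <- balanced$definition
  if (!any(is_producer(model))) stop("model has no producers")
  nm <- group_names(model)
  cons <- is_consumer(model)
  det <- which(is_detritus(model))
  prod <- which(is_producer(model))
  dc <- diet_living(model)

  fr <- tl_fractions(balanced)
  K <- ncol(fr)

  Qv <- balanced$Q
  # ingestion arriving at each level (consumers only; level 1 has none)
  inflow <- as.numeric(t(fr[cons, , drop = FALSE]) %*% Qv[cons])
  # flow drawn from prey acting at level k, i.e. passed from k to k+1
  prey_draw <- sweep(dc, 2, Qv, `*`) # prey x predator flows
  passed <- as.numeric(t(fr) %*% rowSums(prey_draw))
  exports <- as.numeric(t(fr) %*% balanced$export)

  throughput <- inflow
  throughput[1] <- sum(balanced$P[prod]) + balanced$detritus_inflow

  TE <- rep(NA_real_, K)
  for (k in 2:K) {
    if (throughput[k] > 0) TE[k] <- (passed[k] + exports[k]) / throughput[k]
  }

  detritivory <- sum(prey_draw[det, ])
  herbivory <- sum(prey_draw[prod, , drop = FALSE])

  steps <- TE[te_levels[te_levels <= K]]
  steps <- steps[is.finite(steps)]
  te_avg <- if (length(steps) == 0) {
    NA_real_
  } else if (te_mean == "geometric") {
    # a zero step (nothing passed on or exported) makes the mean 0
    if (any(steps == 0)) 0 else exp(mean(log(steps)))
  } else {
    mean(steps)
  }

  structure(list(
    throughput = throughput,
    inflow = inflow,
    passed_on = passed,
    exports = exports,
    TE = TE,
    TE_mean = 100 * te_avg,
    detritivory = detritivory,
    herbivory = herbivory,
    DH = if (herbivory > 0) detritivory / herbivory else Inf
  ), class = "lindeman_spine")
}

#' @export
print.lindeman_spine <- function(x, ...) {
  cat("<lindeman_spine>\n  TL throughput:",
      paste(sprintf("%.2f", x$throughput), collapse = " "), "\n")
  cat(sprintf("  mean TE = %.2f%%, D/H = %.3f\n", x$TE_mean, x$DH))
  invisible(x)
}

# Internal compartment flow matrix (living + detritus) with exogenous inputs,
# exports and respiration, shared by the cycling and information indices.
compartment_flows <- function(balanced) {
  model <- balanced$definition
  nm <- group_names(model)
  n <- length(nm)
  det <- which(is_detritus(model))
  prod <- is_producer(model)

  Fm <- balanced$predation_flows # prey x predator; detritus column is zero
  Fm[, det] <- balanced$flow_to_detritus

  z <- numeric(n)
  z[prod] <- balanced$P[prod]
  z <- z + balanced$import

  list(F = Fm, imports = z, exports = balanced$export, resp = balanced$R,
       throughflow = z + colSums(Fm))
}

# Finn's cycling index via the Leontief inverse of the fractional outflow
# matrix: n_jj is the mean number of visits a unit of throughflow makes to
# compartment j; the cycled fraction of T_j is (n_jj - 1) / n_jj.
finn_cycling <- function(balanced, tst) {
  cf <- compartment_flows(balanced)
  Tf <- cf$throughflow
  ok <- Tf > 0
  G <- cf$F
  G[ok, ] <- cf$F[ok, ] / Tf[ok]
  G[!ok, ] <- 0
  N <- solve(diag(nrow(G)) - G)
  cycled <- sum(Tf[ok] * (diag(N)[ok] - 1) / diag(N)[ok])
  100 * cycled / tst
}

# Ascendancy (A) and development capacity (C) on the extended flow matrix:
# compartments plus an import row and export/respiration columns; log base 2.
ascendancy <- function(balanced) {
  cf <- compartment_flows(balanced)
  n <- nrow(cf$F)
  M <- rbind(cbind(cf$F, cf$exports, cf$resp), c(cf$imports, 0, 0))
  tot <- sum(M)
  ri <- rowSums(M)
  cj <- colSums(M)
  A <- C <- 0
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      t_ij <- M[i, j]
      if (t_ij > 0) {
        A <- A + t_ij * log2(t_ij * tot / (ri[i] * cj[j]))
        C <- C - t_ij * log2(t_ij / tot)
      }
    }
  }
  c(A = unname(A), C = unname(C))
}

#' Compute the ecological-network-analysis status indicators
#'
#' The ten indicators used for status grading: detritivory/herbivory (D/H),
#' mean transfer efficiency (TE, percent), relative ascendancy (A/C),
#' connectance index (CI), system omnivory index (SOI), Finn's cycling index
#' (FCI, percent of TST), Finn's mean path length (FML), and the maturity
#' ratios TPP/TR, TPP/TB and TB/TST.
#'
#' @param balanced a [solve_mass_balance()] result
#' @param te_mean averaging rule for TE, see [lindeman_spine()].
#' @param soi_min_q consumers with consumption at or below this value are
#'   excluded from the SOI weighting (log-consumption weights).
#' @return an `ena_index_set` named list, plus attributes `A` and `C` (bits).
#' @export
compute_index_set <- function(balanced, te_mean = c("geometric", "arithmetic"),
                              soi_min_q = 1) {
  te_mean <- match.arg(te_mean)
  model <- balanced$definition
  nm <- group_names(model)
  n_living <- sum(living(model))
  det <- which(is_detritus(model))
  dc <- diet_living(model)
  cons <- is_consumer(model)

  attr_sum <- attribute_summary(balanced)
  tst <- attr_sum$TST
  diss <- attr_sum$total_export + attr_sum$total_respiration
  if (diss <= 0) stop("exports + respiration are zero; FML undefined")

  spine <- lindeman_spine(balanced, te_mean = te_mean)

  # connectance: realised feeding links among living groups plus links from
  # detritus, over N(N-1) with N living groups
  live_idx <- which(living(model))
  links_living <- sum(dc[live_idx, live_idx, drop = FALSE] > 0)
  links_det <- sum(dc[det, ] > 0)
  CI <- (links_living + links_det) / (n_living * (n_living - 1))

  # system omnivory: consumption-weighted variance of prey trophic levels
  TL <- balanced$TL
  OI <- rep(NA_real_, length(nm))
  for (i in which(cons)) {
    w <- dc[, i]
    OI[i] <- sum(w * (TL - (TL[i] - 1))^2)
  }
  qw <- which(cons & balanced$Q > soi_min_q)
  SOI <- if (length(qw) > 0) {
    sum(OI[qw] * log(balanced$Q[qw])) / sum(log(balanced$Q[qw]))
  } else NA_real_

  ac <- ascendancy(balanced)

  out <- structure(list(
    DH = spine$DH,
    TE_mean = spine$TE_mean,
    AC = unname(ac["A"] / ac["C"]),
    CI = CI,
    SOI = SOI,
    FCI = finn_cycling(balanced, tst),
    FML = tst / diss,
    TPP_TR = attr_sum$total_primary_production / attr_sum$total_respiration,
    TPP_TB = attr_sum$total_primary_production / attr_sum$total_biomass,
    TB_TST = attr_sum$total_biomass / tst
  ), class = "ena_index_set")
  attr(out, "A_bits") <- unname(ac["A"])
  attr(out, "C_bits") <- unname(ac["C"])
  out
}

#' @export
print.ena_index_set <- function(x, ...) {
  v <- unlist(x)
  cat("<ena_index_set>\n")
  print(round(v, 4))
  invisible(x)
}

#' Living biomass summed over integer trophic levels
#'
#' Groups are assigned to the integer level nearest their trophic level
#' (half-up, so TL 2.5 falls in level III); producers and detritus are
#' level I. Detritus biomass, where present, is counted in level I.
#'
#' @param tl either a `balanced_model` or a numeric TL vector
#' @param biomass,role biomass and role vectors, required when `tl` is
#'   numeric; `role` uses the `model_definition` vocabulary.
#' @param max_level optional top reported class: groups rounding above it are
#'   pooled into it, the usual convention when a trophic pyramid truncates at
#'   its highest occupied level.
#' @return named numeric vector, one entry per occupied integer level.
#' @export
biomass_by_integer_tl <- function(tl, biomass = NULL, role = NULL,
                                  max_level = Inf) {
  if (inherits(tl, "balanced_model")) {
    b <- tl
    role <- b$definition$groups$role
    biomass <- b$definition$groups$B
    tl <- b$TL
  }
  stopifnot(length(tl) == length(biomass), length(tl) == length(role))
  bin <- pmin(floor(tl + 0.5), max_level)
  bin[role %in% c("producer", "detritus")] <- 1L
  out <- tapply(biomass, bin, sum)
  stats::setNames(as.numeric(out), names(out))
}
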