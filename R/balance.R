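#' Compute trophic levels from the diet matrix
#'
#' Producers and detritus sit at trophic level (TL) 1. A consumer's TL is one
#' plus the diet-weighted mean TL of its prey, solved simultaneously as a
#' linear system so that loops (e.g. cannibalism, mutual predation) are
#' handled exactly. Diet imports contribute at `import_tl` (default 1).
#'
#' @param model a [model_definition()]
#' @param import_tl trophic level attributed to imported diet fractions.
#' @return named numeric vector of trophic levels, one per group.
#' @export
compute_trophic_levels <- function(model, import_tl = 1) {
  nm <- group_names(model)
  n <- length(nm)
  dc <- diet_living(model)
  cons <- is_consumer(model)

  # A %*% TL = b; producers/detritus pinned at 1.
  A <- diag(n)
  b <- rep(1, n)
  for (j in which(cons)) {
    A[j, ] <- A[j, ] - dc[, j]
    b[j] <- 1 + diet_import(model)[j] * import_tl
  }
  tl <- tryCatch(solve(A, b), error = function(e) {
    heavy <- nm[cons][order(-diag(dc)[cons])][1]
    stop("trophic-level system is singular (cyclic diets too strong, e.g. ",
         heavy, "); cannot solve within tolerance", call. = FALSE)
  })
  stats::setNames(as.numeric(tl), nm)
}

#' Solve the mass-balance (Ecopath master) equation
#'
#' With biomass known for every group, ecotrophic efficiency (EE) is the
#' unknown of the master equation for producers and consumers:
#' `EE_i = (Y_i + E_i + BA_i + sum_j Q_j * DC_ij) / (B_i * PB_i)`.
#' Consumer respiration is `R_i = (1 - Ui_i) * Q_i - P_i`; flow to detritus is
#' `D_i = B_i * PB_i * (1 - EE_i) + Q_i * Ui_i`. Detritus EE is the fraction
#' of total detrital inflow that is consumed; the surplus leaves the system
#' as detritus export.
#'
#' @param model a [model_definition()]
#' @return an object of class `balanced_model`: the definition plus `TL`,
#'   `EE`, `Q`, `P`, `R`, `flow_to_detritus`, `predation_flows` (prey x
#'   predator matrix, t/km2/a), `export` (catch + other export per group,
#'   with the detritus surplus on the detritus row), and `import` (imported
#'   consumption per group).
#' @export
solve_mass_balance <- function(model) {
  g <- model$groups
  nm <- g$name
  cons <- is_consumer(model)
  prod <- is_producer(model)
  det <- which(is_detritus(model))
  dc <- diet_living(model)

  Q <- ifelse(cons, g$B * g$QB, 0)
  P <- ifelse(is_detritus(model), 0, g$B * g$PB)

  # predation flows T[i, j] = Q_j * DC[i, j]
  Tm <- sweep(dc, 2, Q, `*`)
  dimnames(Tm) <- list(nm, nm)
  predation <- rowSums(Tm)
  demand <- g$catch + g$export + g$BA + predation

  EE <- rep(NA_real_, length(nm))
  live <- !is_detritus(model)
  zero_prod <- live & P <= 0 & demand > 1e-12
  if (any(zero_prod)) {
    stop("infeasible: zero production but nonzero demand for ",
         paste(nm[zero_prod], collapse = ", "))
  }
  EE[live] <- ifelse(P[live] > 0, demand[live] / P[live], 0)

  R <- rep(0, length(nm))
  R[cons] <- (1 - g$Ui[cons]) * Q[cons] - P[cons]

  Ui <- ifelse(cons, g$Ui, 0)
  # Unconsumed production P*(1-EE) plus egestion Q*Ui. If EE > 1 the model is
  # infeasible; the negative unconsumed-production term is floored at 0 so
  # detrital bookkeeping stays non-negative (diagnose() reports the EE breach).
  flow_to_det <- rep(0, length(nm))
  flow_to_det[live] <- pmax(P[live] * (1 - EE[live]), 0) + Q[live] * Ui[live]

  detritivory <- sum(Tm[det, ])
  det_inflow <- sum(flow_to_det)
  EE[det] <- if (det_inflow > 0) detritivory / det_inflow else 0
  det_surplus <- max(det_inflow - detritivory, 0)

  export <- g$catch + g$export
  export[det] <- export[det] + det_surplus

  TL <- compute_trophic_levels(model)

  structure(list(
    definition = model,
    TL = stats::setNames(TL, nm),
    EE = stats::setNames(EE, nm),
    Q = stats::setNames(Q, nm),
    P = stats::setNames(P, nm),
    R = stats::setNames(R, nm),
    flow_to_detritus = stats::setNames(flow_to_det, nm),
    predation_flows = Tm,
    import = stats::setNames(diet_import(model) * Q, nm),
    export = stats::setNames(export, nm),
    detritus_inflow = det_inflow,
    detritus_surplus = det_surplus
  ), class = "balanced_model")
}

#' @export
print.balanced_model <- function(x, ...) {
  cat(sprintf("<balanced_model> %s: %d groups, EE in [%.3f, %.3f]%s\n",
              x$definition$name, length(x$EE), min(x$EE), max(x$EE),
              if (max(x$EE) > 1 + 1e-9) " (INFEASIBLE)" else ""))
  invisible(x)
}

#' Balancing diagnostics for a solved model
#'
#' Reports the per-consumer gross food-conversion efficiency (GE = P/Q),
#' respiration/assimilation and production/respiration ratios, and the
#' violation lists used during model balancing: EE above 1, GE outside the
#' plausible physiological window, R/A at or above 1, P/R at or above 1, and
#' negative respiration. Feasibility is judged on EE alone; the ratio checks
#' are balancing guidance, not hard constraints.
#'
#' @param balanced a [solve_mass_balance()] result
#' @param ge_range plausible gross-efficiency window, default `c(0.1, 0.3)`.
#' @return a `diagnostics_report` list with per-consumer ratios, violation
#'   character vectors, and a logical `feasible`.
#' @export
diagnose <- function(balanced, ge_range = c(0.1, 0.3)) {
  g <- balanced$definition$groups
  cons <- g$role == "consumer"
  nm <- g$name

  GE <- RA <- PR <- stats::setNames(rep(NA_real_, sum(cons)), nm[cons])
  Qc <- balanced$Q[cons]
  Pc <- balanced$P[cons]
  Rc <- balanced$R[cons]
  A <- (1 - g$Ui[cons]) * Qc
  GE[] <- Pc / Qc
  RA[] <- ifelse(A > 0, Rc / A, NA_real_)
  PR[] <- ifelse(Rc > 0, Pc / Rc, Inf)

  ee_bad <- nm[balanced$EE > 1 + 1e-9]
  ge_bad <- names(GE)[GE < ge_range[1] | GE > ge_range[2]]
  ra_bad <- names(RA)[!is.na(RA) & RA >= 1]
  pr_bad <- names(PR)[PR >= 1]
  rneg <- names(Rc)[Rc < 0]

  structure(list(
    GE = GE, RA = RA, PR = PR,
    violations = list(
      ee_above_1 = ee_bad,
      ge_outside_range = ge_bad,
      ra_at_least_1 = ra_bad,
      pr_at_least_1 = pr_bad,
      negative_respiration = rneg
    ),
    feasible = length(ee_bad) == 0
  ), class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("<diagnostics_report> feasible: %s\n", x$feasible))
  for (nm in names(x$violations)) {
    v <- x$violations[[nm]]
    if (length(v) > 0) cat(sprintf("  %s: %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Is a solved model feasible (all EE at most 1)?
#' @param balanced a `balanced_model`
#' @param tol slack on the EE bound.
#' @return logical
#' @export
is_feasible <- function(balanced, tol = 1e-9) {
  all(balanced$EE <= 1 + tol)
}
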