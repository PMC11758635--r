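#' Trophic-level-derived vulnerability parameters
#'
#' Vulnerability expresses whether a predator-prey interaction is bottom-up
#' (low values) or top-down (high values) controlled. In the absence of time
#' series to fit, it is set from the trophic level by the empirical relation
#' `v = 0.1515 * TL + 0.0485`, then mapped onto the multiplier scale used by
#' the foraging-arena model via `log(v_new) = 2.301958 * v + 0.001051`
#' (natural logarithm), so the mixed-control value `v = 0.3` gives a
#' vulnerability multiplier of about 2.
#'
#' @param TL numeric vector of trophic levels (>= 1)
#' @return list with `v` (0--1 control scale) and `v_new` (multiplier >= 1),
#'   both named like `TL`.
#' @export
vulnerability_params <- function(TL) {
  stopifnot(all(TL >= 1 - 1e-9))
  v <- 0.1515 * TL + 0.0485
  v_new <- exp(2.301958 * v + 0.001051)
  list(v = v, v_new = v_new)
}

#' Calibrate foraging-arena consumption to a balanced model
#'
#' For every realised predation link the arena flow is
#' `Q(Bi, Bj) = v * a * Bi * Bj / (v + a * Bj)` with the exchange rate `v`
#' set so that predation mortality on the prey saturates at `v_new[pred]`
#' times its baseline value, and the search rate `a` set so that the flow at
#' baseline biomasses equals the mass-balance flow exactly. The calibration
#' also fixes growth efficiencies (baseline P/Q), other mortality
#' (`PB * (1 - EE)`), per-biomass import intake, per-biomass non-fishery
#' export, baseline fishing mortality (`catch / B`), a saturating primary-
#' production response for producers (maximum P/B twice baseline), and the
#' detrital export rate, so that the unperturbed system is stationary.
#'
#' @param balanced a feasible [solve_mass_balance()] result
#' @param v optional [vulnerability_params()]; computed from the model's
#'   trophic levels when omitted.
#' @return an `arena_calibration` object.
#' @export
calibrate_arena <- function(balanced, v = NULL) {
  model <- balanced$definition
  if (!is_feasible(balanced)) stop("cannot calibrate an infeasible model")
  g <- model$groups
  nm <- g$name
  n <- length(nm)
  if (is.null(v)) v <- vulnerability_params(balanced$TL)
  cons <- is_consumer(model)
  det <- which(is_detritus(model))

  Tm <- balanced$predation_flows
  links <- which(Tm > 0, arr.ind = TRUE)
  B0 <- g$B
  link_df <- data.frame(
    prey = links[, 1], pred = links[, 2],
    flow0 = Tm[links]
  )
  link_df$v_rate <- v$v_new[link_df$pred] * link_df$flow0 / B0[link_df$prey]
  link_df$a <- link_df$flow0 * link_df$v_rate /
    (B0[link_df$pred] * (link_df$v_rate * B0[link_df$prey] - link_df$flow0))

  live <- g$role != "detritus"
  M0 <- numeric(n)
  M0[live] <- g$PB[live] * (1 - balanced$EE[live])

  structure(list(
    model = model,
    balanced = balanced,
    links = link_df,
    v = v,
    B0 = stats::setNames(B0, nm),
    GE = stats::setNames(ifelse(cons, balanced$P / pmax(balanced$Q, 1e-300), 0), nm),
    M0 = stats::setNames(M0, nm),
    Ui = stats::setNames(ifelse(cons, g$Ui, 0), nm),
    import_rate = stats::setNames(
      ifelse(B0 > 0, balanced$import / B0, 0), nm),
    export_rate = stats::setNames(
      ifelse(B0 > 0, g$export / B0, 0), nm),
    F0 = stats::setNames(ifelse(B0 > 0, g$catch / B0, 0), nm),
    pmax_pb = stats::setNames(ifelse(g$role == "producer", 2 * g$PB, 0), nm),
    detritus = det,
    det_export_rate = if (B0[det] > 0) balanced$detritus_surplus / B0[det] else 0
  ), class = "arena_calibration")
}

# Arena flows for a biomass state; `vmult` multiplies the exchange rate per
# link (mediation). Returns the per-link flow vector.
arena_flows <- function(arena, B, vmult = 1) {
  L <- arena$links
  v <- L$v_rate * vmult
  bi <- B[L$prey]
  bj <- B[L$pred]
  v * L$a * bi * bj / (v + L$a * bj)
}

#' Specify a mediation effect
#'
#' A mediator group's biomass rescales the vulnerability exchange rate of
#' selected predator-prey links through a sigmoid normalised to 1 at the
#' mediator's baseline biomass. Positive steepness means more mediator
#' biomass strengthens predation (facilitation); negative steepness weakens
#' it (sheltering).
#'
#' @param mediators character vector of mediator group names
#' @param links two-column matrix or data frame of (prey, predator) names
#' @param floor,ceiling multiplier bounds, `floor <= 1 <= ceiling`
#' @param steepness sigmoid slope on the relative-biomass axis
#' @return a `mediation_spec`
#' @export
mediation_spec <- function(mediators, links, floor = 0.5, ceiling = 2,
                           steepness = -2) {
  stopifnot(floor <= 1, ceiling >= 1, floor > 0)
  links <- as.matrix(links)
  if (ncol(links) != 2) stop("links must be (prey, predator) pairs")
  structure(list(mediators = mediators, links = links, floor = floor,
                 ceiling = ceiling, steepness = steepness),
            class = "mediation_spec")
}

# raw sigmoid and normalisation at baseline relative biomass 1
mediation_multiplier <- function(spec, rel_biomass) {
  raw <- function(x) {
    spec$floor + (spec$ceiling - spec$floor) *
      stats::plogis(spec$steepness * (x - 1))
  }
  raw(rel_biomass) / raw(1)
}

#' Specify a simulation scenario
#'
#' @param enhanced named numeric vector: target biomass (t/km2) per enhanced
#'   group; may be empty.
#' @param fishing logical; when `TRUE` the baseline fishing mortalities
#'   (`catch / B`) are applied as constant rates.
#' @param years simulation horizon (years)
#' @param ramp years over which enhanced groups are ramped linearly from
#'   baseline to target, after which they are held.
#' @param name scenario label
#' @return a `scenario_spec`
#' @export
scenario_spec <- function(enhanced = numeric(0), fishing = FALSE, years = 14,
                          ramp = 1, name = NULL) {
  if (length(enhanced) > 0 && is.null(names(enhanced))) {
    stop("enhanced targets must be named by group")
  }
  if (is.null(name)) {
    name <- if (length(enhanced) == 0 && !fishing) "baseline"
    else paste0(paste(names(enhanced), collapse = " + "),
                if (fishing) if (length(enhanced) > 0) " + fishing" else "fishing")
  }
  structure(list(enhanced = enhanced, fishing = fishing, years = years,
                 ramp = ramp, name = name), class = "scenario_spec")
}

#' Simulate food-web dynamics under a scenario
#'
#' Integrates the foraging-arena biomass dynamics with fixed-step
#' fourth-order Runge-Kutta on a monthly grid. Consumers grow by growth
#' efficiency times arena intake and lose biomass to predation, other
#' mortality, non-fishery export and (optionally) fishing; producers follow
#' the calibrated saturating production response; the detritus pool receives
#' egestion and other-mortality flows and loses to detritivory and detrital
#' export. Enhanced groups are forced: ramped linearly to their target over
#' the ramp period, then held.
#'
#' @param arena an [calibrate_arena()] result
#' @param scenario a [scenario_spec()]
#' @param mediation list of [mediation_spec()] objects
#' @param collapse_frac collapse threshold as a fraction of baseline biomass.
#' @param substeps integration sub-steps per month; by default chosen from
#'   the fastest baseline turnover rate so that rate x step stays well inside
#'   the stability region of the explicit integrator. The reported grid is
#'   always monthly.
#' @return a `trajectory`: `time` (years), `biomass` (time x group matrix),
#'   `collapsed` (named logical), `evaluable` (no living group collapsed),
#'   plus the scenario and arena for downstream snapshots.
#' @export
simulate_scenario <- function(arena, scenario, mediation = list(),
                              collapse_frac = 1e-3, substeps = NULL) {
  model <- arena$model
  nm <- group_names(model)
  n <- length(nm)
  forced <- match(names(scenario$enhanced), nm)
  if (any(is.na(forced))) {
    stop("unknown enhanced groups: ",
         paste(names(scenario$enhanced)[is.na(forced)], collapse = ", "))
  }
  B0 <- arena$B0
  slope <- numeric(n)
  if (length(forced) > 0) {
    slope[forced] <- (scenario$enhanced - B0[forced]) / scenario$ramp
  }
  Fmort <- if (scenario$fishing) arena$F0 else numeric(n)

  med_links <- lapply(mediation, function(ms) {
    prey <- match(ms$links[, 1], nm)
    pred <- match(ms$links[, 2], nm)
    if (any(is.na(prey)) || any(is.na(pred))) stop("unknown mediation link group")
    match(paste(prey, pred), paste(arena$links$prey, arena$links$pred))
  })
  med_groups <- lapply(mediation, function(ms) match(ms$mediators, nm))

  cons <- is_consumer(model)
  prod <- is_producer(model)
  det <- arena$detritus
  live <- seq_len(n) != det
  preyL <- arena$links$prey
  predL <- arena$links$pred
  nl <- nrow(arena$links)
  # link-to-group aggregation matrices, built once
  Ain <- matrix(0, n, nl)
  Ain[cbind(predL, seq_len(nl))] <- 1
  Aout <- matrix(0, n, nl)
  Aout[cbind(preyL, seq_len(nl))] <- 1

  deriv <- function(t, B, parms) {
    B <- pmax(B, 0)
    vmult <- rep(1, nl)
    for (k in seq_along(mediation)) {
      rel <- sum(B[med_groups[[k]]]) / sum(B0[med_groups[[k]]])
      idx <- med_links[[k]]
      vmult[idx[!is.na(idx)]] <- vmult[idx[!is.na(idx)]] *
        mediation_multiplier(mediation[[k]], rel)
    }
    q <- arena_flows(arena, B, vmult)
    intake <- as.numeric(Ain %*% q)
    loss <- as.numeric(Aout %*% q)
    intake <- intake + arena$import_rate * B

    dB <- numeric(n)
    dB[cons] <- arena$GE[cons] * intake[cons] - loss[cons] -
      (arena$M0[cons] + arena$export_rate[cons] + Fmort[cons]) * B[cons]
    dB[prod] <- arena$pmax_pb[prod] * B[prod] / (1 + B[prod] / B0[prod]) -
      loss[prod] -
      (arena$M0[prod] + arena$export_rate[prod] + Fmort[prod]) * B[prod]
    det_in <- sum(arena$Ui * intake) + sum(arena$M0[live] * B[live])
    dB[det] <- det_in - loss[det] - arena$det_export_rate * B[det]

    if (length(forced) > 0) {
      dB[forced] <- ifelse(t < scenario$ramp, slope[forced], 0)
    }
    if (any(!is.finite(dB))) {
      stop("non-finite derivative at t = ", signif(t, 4), " for ",
           paste(nm[!is.finite(dB)], collapse = ", "))
    }
    list(dB)
  }

  if (is.null(substeps)) {
    bal <- arena$balanced
    turnover <- pmax(bal$Q, bal$P, arena$M0 * B0, na.rm = TRUE) /
      pmax(B0, 1e-12)
    turnover[det] <- bal$detritus_inflow / max(B0[det], 1e-12)
    substeps <- max(1L, ceiling(max(turnover, na.rm = TRUE) / 12 / 0.2))
  }
  months <- round(scenario$years * 12)
  times <- seq(0, scenario$years, length.out = months * substeps + 1L)
  sol <- deSolve::ode(y = stats::setNames(as.numeric(B0), nm), times = times,
                      func = deriv, parms = NULL, method = "rk4")
  keep <- seq(1L, length(times), by = substeps)
  bio <- unname(sol[keep, -1, drop = FALSE])
  times <- times[keep]
  colnames(bio) <- nm
  if (any(!is.finite(bio))) stop("integration produced non-finite biomass")

  thresh <- collapse_frac * B0
  collapsed <- vapply(seq_len(n), function(j) any(bio[, j] < thresh[j]), logical(1))
  names(collapsed) <- nm

  structure(list(
    time = times,
    biomass = bio,
    collapsed = collapsed,
    evaluable = !any(collapsed[live]),
    scenario = scenario,
    mediation = mediation,
    arena = arena
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d groups x %d months, %s\n",
              x$scenario$name, ncol(x$biomass), length(x$time) - 1,
              if (x$evaluable) "evaluable"
              else paste("collapsed:",
                         paste(names(x$collapsed)[x$collapsed], collapse = ", "))))
  invisible(x)
}

#' Extract a mass-balance snapshot from a trajectory and grade it
#'
#' Rebuilds a model definition at the requested year: biomasses from the
#' trajectory, diet columns recomputed from the realised arena flows at that
#' time, baseline P/B, Q/B and unassimilated fractions retained, and catches
#' set to the applied fishing mortality times the snapshot biomass. The
#' snapshot is solved, its ENA indicator set computed, and (when a scale and
#' weights are supplied) graded by fuzzy comprehensive evaluation.
#'
#' @param trajectory a [simulate_scenario()] result
#' @param year snapshot year (must not exceed the horizon)
#' @param scale optional [grade_scale()]
#' @param weights optional weight vector for [evaluate_status()]
#' @return a list with `model`, `balanced`, `indices`, `feasible`, and
#'   `evaluation` (or `NULL`); if any living group collapsed, the string
#'   `"not evaluable"` (class `not_evaluable`) is returned instead.
#' @export
snapshot_and_evaluate <- function(trajectory, year = 10, scale = NULL,
                                  weights = NULL) {
  if (year > max(trajectory$time)) stop("trajectory shorter than snapshot year")
  if (!trajectory$evaluable) {
    return(structure("not evaluable", class = "not_evaluable",
                     collapsed = names(trajectory$collapsed)[trajectory$collapsed]))
  }
  arena <- trajectory$arena
  model <- arena$model
  nm <- group_names(model)
  n <- length(nm)
  ti <- which.min(abs(trajectory$time - year))
  B <- pmax(trajectory$biomass[ti, ], 0)

  vmult <- rep(1, nrow(arena$links))
  for (k in seq_along(trajectory$mediation)) {
    ms <- trajectory$mediation[[k]]
    gi <- match(ms$mediators, nm)
    rel <- sum(B[gi]) / sum(arena$B0[gi])
    idx <- match(paste(match(ms$links[, 1], nm), match(ms$links[, 2], nm)),
                 paste(arena$links$prey, arena$links$pred))
    vmult[idx[!is.na(idx)]] <- vmult[idx[!is.na(idx)]] *
      mediation_multiplier(ms, rel)
  }
  q <- arena_flows(arena, B, vmult)
  imp <- arena$import_rate * B

  dc <- matrix(0, n + 1L, n, dimnames = list(c(nm, "import"), nm))
  for (l in seq_len(nrow(arena$links))) {
    dc[arena$links$prey[l], arena$links$pred[l]] <-
      dc[arena$links$prey[l], arena$links$pred[l]] + q[l]
  }
  dc["import", ] <- imp
  tot_in <- colSums(dc)
  cons <- is_consumer(model)
  for (j in which(cons)) {
    if (tot_in[j] > 0) dc[, j] <- dc[, j] / tot_in[j]
  }
  dc[, !cons] <- 0

  g <- model$groups
  g$B <- as.numeric(B)
  Fmort <- if (trajectory$scenario$fishing) arena$F0 else numeric(n)
  g$catch <- as.numeric(Fmort * B)
  g$export <- as.numeric(arena$export_rate * B)

  snap_model <- model_definition(g, dc,
                                 name = paste0(model$name, "@year", year))
  bal <- solve_mass_balance(snap_model)
  feasible <- is_feasible(bal)
  indices <- compute_index_set(bal)
  evaluation <- if (!is.null(scale) && !is.null(weights)) {
    evaluate_status(indices, scale, weights)
  } else NULL

  list(model = snap_model, balanced = bal, indices = indices,
       feasible = feasible,
       infeasible_groups = names(bal$EE)[bal$EE > 1 + 1e-9],
       evaluation = evaluation)
}

#' Run the full stock-enhancement scenario suite
#'
#' Enumerates every non-empty combination of the supplied enhancement groups,
#' each with and without fishing, plus a fishing-only scenario: with three
#' enhancement groups this is the full 15-scenario design. Each scenario is
#' simulated, snapshot at `snapshot_year`, and graded.
#'
#' @param arena an [calibrate_arena()] result (typically on the merged-MOB
#'   model)
#' @param targets named numeric vector of target biomasses (t/km2), usually
#'   the carrying capacities of the enhancement groups
#' @param scale a [grade_scale()]
#' @param weights indicator weights
#' @param years,snapshot_year horizon and evaluation year
#' @param mediation list of [mediation_spec()]s applied to every scenario
#' @return a `scenario_suite` list: `results` (per-scenario list with
#'   `trajectory` and snapshot output) and `table` (per-scenario data frame
#'   of indicator values and grades, `NA` for non-evaluable scenarios).
#' @export
run_scenario_suite <- function(arena, targets, scale, weights, years = 14,
                               snapshot_year = 10, mediation = list()) {
  stopifnot(length(targets) >= 1, !is.null(names(targets)))
  labels <- names(targets)
  combos <- unlist(lapply(seq_along(labels), function(k) {
    utils::combn(labels, k, simplify = FALSE)
  }), recursive = FALSE)

  scenarios <- list()
  for (cmb in combos) {
    for (fish in c(FALSE, TRUE)) {
      scenarios[[length(scenarios) + 1]] <-
        scenario_spec(enhanced = targets[cmb], fishing = fish, years = years)
    }
  }
  scenarios[[length(scenarios) + 1]] <-
    scenario_spec(fishing = TRUE, years = years, name = "fishing only")

  results <- lapply(scenarios, function(sc) {
    traj <- simulate_scenario(arena, sc, mediation = mediation)
    snap <- snapshot_and_evaluate(traj, year = snapshot_year, scale = scale,
                                  weights = weights)
    list(scenario = sc, trajectory = traj, snapshot = snap)
  })

  rows <- lapply(results, function(r) {
    base <- data.frame(scenario = r$scenario$name,
                       fishing = r$scenario$fishing,
                       evaluable = r$trajectory$evaluable)
    if (inherits(r$snapshot, "not_evaluable")) {
      idx <- as.data.frame(as.list(rep(NA_real_, 10)))
      names(idx) <- names_index_set()
      base <- cbind(base, idx, grade = NA_character_)
    } else {
      idx <- as.data.frame(r$snapshot$indices[names_index_set()])
      base <- cbind(base, idx,
                    grade = if (!is.null(r$snapshot$evaluation))
                      r$snapshot$evaluation$grade else NA_character_)
    }
    base
  })
  structure(list(results = results, table = do.call(rbind, rows)),
            class = "scenario_suite")
}

names_index_set <- function() {
  c("DH", "TE_mean", "AC", "CI", "SOI", "FCI", "FML", "TPP_TR", "TPP_TB",
    "TB_TST")
}

#' @export
print.scenario_suite <- function(x, ...) {
  cat(sprintf("<scenario_suite> %d scenarios (%d evaluable)\n",
              nrow(x$table), sum(x$table$evaluable)))
  invisible(x)
}
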