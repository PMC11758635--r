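# Replace one group's biomass and re-solve.
set_biomass <- function(model, group, b) {
  model$groups$B[model$groups$name == group] <- b
  model
}

# Which EE bound binds first when the target is pushed just past capacity?
binding_group <- function(model, group, b, tol = 1e-9) {
  bal <- solve_mass_balance(set_biomass(model, group, b))
  bad <- names(bal$EE)[bal$EE > 1 + tol]
  if (length(bad) == 0) NA_character_ else bad[which.max(bal$EE[bal$EE > 1 + tol])]
}

#' Ecological carrying capacity of one functional group
#'
#' The carrying capacity is the largest biomass of the target group for which
#' the whole model stays mass-balanced (every ecotrophic efficiency at most
#' 1), with every other input held fixed. The search expands the biomass
#' geometrically until balance fails, then bisects the bracket to a relative
#' tolerance. The group whose EE first exceeds 1 just past the capacity is
#' reported as the binding constraint.
#'
#' @param model a feasible [model_definition()]
#' @param group name of the target group (living)
#' @param rel_tol relative bisection tolerance on the capacity.
#' @param expand geometric expansion factor for bracketing.
#' @param max_factor expansion cap, as a multiple of the baseline biomass;
#'   if no EE reaches 1 below it the capacity is reported as unbounded.
#' @return a `carrying_capacity_result`: `group`, `carrying_capacity`,
#'   `baseline_biomass`, `enhancement_potential` (capacity minus baseline),
#'   `limiting_group`, `unbounded`, and the group's trophic level `TL`.
#' @export
carrying_capacity <- function(model, group, rel_tol = 1e-4, expand = 2,
                              max_factor = 1e6) {
  g <- model$groups
  if (!group %in% g$name) stop("unknown group: ", group)
  if (g$role[g$name == group] == "detritus") stop("detritus has no carrying capacity")
  b0 <- g$B[g$name == group]

  base <- solve_mass_balance(model)
  if (!is_feasible(base)) {
    stop("baseline model is infeasible (EE > 1): ",
         paste(names(base$EE)[base$EE > 1 + 1e-9], collapse = ", "))
  }

  feasible_at <- function(b) {
    is_feasible(solve_mass_balance(set_biomass(model, group, b)))
  }

  # bracket [lo feasible, hi infeasible] by geometric expansion
  lo <- b0
  hi <- max(b0, 1e-9) * expand
  unbounded <- FALSE
  while (feasible_at(hi)) {
    lo <- hi
    hi <- hi * expand
    if (hi > max(b0, 1e-9) * max_factor) {
      unbounded <- TRUE
      break
    }
  }

  if (unbounded) {
    cap <- Inf
    limiting <- NA_character_
  } else {
    while ((hi - lo) > rel_tol * hi) {
      mid <- (lo + hi) / 2
      if (feasible_at(mid)) lo <- mid else hi <- mid
    }
    cap <- lo
    limiting <- binding_group(model, group, hi)
  }

  structure(list(
    group = group,
    carrying_capacity = cap,
    baseline_biomass = b0,
    enhancement_potential = cap - b0,
    limiting_group = limiting,
    unbounded = unbounded,
    TL = unname(base$TL[group])
  ), class = "carrying_capacity_result")
}

#' @export
print.carrying_capacity_result <- function(x, ...) {
  cat(sprintf("<carrying_capacity> %s: %.4g t/km2 (baseline %.4g, potential %.4g)%s\n",
              x$group, x$carrying_capacity, x$baseline_biomass,
              x$enhancement_potential,
              if (x$unbounded) " [unbounded]" else
                sprintf(", limited by %s", x$limiting_group)))
  invisible(x)
}

#' Trophic-level bin of a group
#'
#' Bins follow the stock-enhancement screening convention: TL 2.0--2.5,
#' 2.5--3.0 and 3.0--3.5, with the lower bound inclusive and the upper bound
#' exclusive.
#'
#' @param tl numeric trophic level(s)
#' @return character bin label, `NA` outside the covered range.
#' @export
tl_bin <- function(tl) {
  labs <- c("TL 2.0-2.5", "TL 2.5-3.0", "TL 3.0-3.5")
  idx <- findInterval(tl, c(2.0, 2.5, 3.0, 3.5), rightmost.closed = FALSE)
  out <- rep(NA_character_, length(tl))
  out[idx >= 1 & idx <= 3 & tl < 3.5] <- labs[idx[idx >= 1 & idx <= 3 & tl < 3.5]]
  out
}

#' Stock-enhancement potential table, ranked within trophic-level bins
#'
#' Potential is carrying capacity minus current biomass; groups are assigned
#' to TL bins and ranked by descending potential within each bin.
#'
#' @param capacities list of [carrying_capacity()] results, or a data frame
#'   with columns `group`, `carrying_capacity`, `baseline_biomass`, `TL`.
#' @return data frame with columns `bin`, `group`, `TL`,
#'   `carrying_capacity`, `baseline_biomass`, `potential`, ordered by bin
#'   (ascending TL range) and descending potential.
#' @export
enhancement_potential_table <- function(capacities) {
  if (is.data.frame(capacities)) {
    df <- capacities
  } else {
    df <- do.call(rbind, lapply(capacities, function(x) {
      data.frame(group = x$group,
                 carrying_capacity = x$carrying_capacity,
                 baseline_biomass = x$baseline_biomass,
                 TL = x$TL)
    }))
  }
  df$potential <- df$carrying_capacity - df$baseline_biomass
  df$bin <- tl_bin(df$TL)
  df <- df[order(df$bin, -df$potential), ]
  rownames(df) <- NULL
  df[, c("bin", "group", "TL", "carrying_capacity", "baseline_biomass",
         "potential")]
}

#' Merge living groups into a single aggregate group
#'
#' The merged group takes the summed biomass; biomass-weighted mean P/B and
#' Q/B; consumption-weighted mean unassimilated fraction; a consumption-
#' weighted average diet column; and prey/predator diet fractions pointing at
#' the members are summed onto the merged group. Catches, exports and biomass
#' accumulation are summed. Total biomass, production, consumption and every
#' predator's intake are conserved.
#'
#' @param model a [model_definition()]
#' @param members character vector (length >= 2) of living member groups
#' @param new_name name of the merged group
#' @return a new [model_definition()]
#' @export
merge_groups <- function(model, members, new_name) {
  g <- model$groups
  if (length(members) == 0) stop("empty member list")
  if (anyDuplicated(members)) stop("member named twice")
  bad <- setdiff(members, g$name)
  if (length(bad) > 0) stop("unknown groups: ", paste(bad, collapse = ", "))
  if (any(g$role[g$name %in% members] == "detritus")) {
    stop("cannot merge the detritus group")
  }
  if (new_name %in% setdiff(g$name, members)) {
    stop("new name collides with an existing group")
  }

  idx <- match(members, g$name)
  first <- min(idx)
  roles <- unique(g$role[idx])
  if (length(roles) > 1) stop("members must share a role")

  B <- g$B[idx]
  Bsum <- sum(B)
  wB <- if (Bsum > 0) B / Bsum else rep(1 / length(B), length(B))
  Q <- ifelse(g$role[idx] == "consumer", g$B[idx] * g$QB[idx], 0)
  Qsum <- sum(Q)
  wQ <- if (Qsum > 0) Q / Qsum else wB

  merged <- data.frame(
    name = new_name,
    role = roles,
    B = Bsum,
    PB = sum(wB * g$PB[idx]),
    QB = if (roles == "consumer") Qsum / Bsum else NA_real_,
    Ui = if (roles == "consumer") sum(wQ * g$Ui[idx]) else NA_real_,
    catch = sum(g$catch[idx]),
    export = sum(g$export[idx]),
    BA = sum(g$BA[idx])
  )

  keep <- setdiff(seq_len(nrow(g)), idx)
  # insert the merged group at the first member's position
  before <- keep[keep < first]
  after <- keep[keep >= first]
  new_g <- rbind(g[before, ], merged, g[after, ])
  rownames(new_g) <- NULL

  d <- model$diet
  # predators' fractions on members are summed into the merged prey row
  member_rows <- colSums(d[members, , drop = FALSE])
  # merged diet column: consumption-weighted average of member columns
  merged_col <- as.numeric(d[, members, drop = FALSE] %*% wQ)
  names(merged_col) <- rownames(d)

  nm_new <- new_g$name
  nd <- matrix(0, length(nm_new) + 1L, length(nm_new),
               dimnames = list(c(nm_new, "import"), nm_new))
  old_cols <- setdiff(colnames(d), members)
  old_rows <- setdiff(rownames(d), c(members, "import"))
  nd[old_rows, old_cols] <- d[old_rows, old_cols]
  nd["import", old_cols] <- d["import", old_cols]
  nd[new_name, old_cols] <- member_rows[old_cols]
  if (roles == "consumer") {
    nd[old_rows, new_name] <- merged_col[old_rows]
    nd["import", new_name] <- merged_col["import"]
    nd[new_name, new_name] <- sum(merged_col[members])
  }

  model_definition(new_g, nd, name = model$name)
}
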