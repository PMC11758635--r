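# Shared toy webs and independent oracles.

# Producer--herbivore pair with detritus; herbivore eats only the producer.
toy_chain <- function(herb_B = 1, herb_QB = 50, herb_PB = 10,
                      prod_B = 10, prod_PB = 100, catch = c(0, 0, 0)) {
  g <- data.frame(
    name = c("producer", "herbivore", "detritus"),
    role = c("producer", "consumer", "detritus"),
    B = c(prod_B, herb_B, 5),
    PB = c(prod_PB, herb_PB, NA),
    QB = c(NA, herb_QB, NA),
    Ui = c(NA, 0.2, NA),
    catch = catch
  )
  d <- matrix(0, 3, 3, dimnames = list(g$name, g$name))
  d["producer", "herbivore"] <- 1
  model_definition(g, d, name = "toy_chain")
}

# Four-group web (producer, herbivore, carnivore, detritus) with detrital
# feeding, used for spine/cycling tests.
toy_web <- function(det_frac = 0.3) {
  g <- data.frame(
    name = c("phyto", "herb", "carn", "det"),
    role = c("producer", "consumer", "consumer", "detritus"),
    B = c(10, 1, 0.05, 5),
    PB = c(100, 30, 10, NA),
    QB = c(NA, 120, 40, NA),
    Ui = c(NA, 0.3, 0.2, NA)
  )
  d <- matrix(0, 4, 4, dimnames = list(g$name, g$name))
  d["phyto", "herb"] <- 1 - det_frac
  d["det", "herb"] <- det_frac
  d["herb", "carn"] <- 1
  model_definition(g, d, name = "toy_web")
}

# Fixed-point iteration oracle for trophic levels on acyclic diets.
tl_fixed_point <- function(model, iters = 200) {
  dc <- model$diet[model$groups$name, , drop = FALSE]
  cons <- model$groups$role == "consumer"
  imp <- model$diet["import", ]
  tl <- rep(1, nrow(model$groups))
  for (i in seq_len(iters)) {
    tl_new <- tl
    tl_new[cons] <- 1 + as.numeric(t(dc[, cons, drop = FALSE]) %*% tl) +
      imp[cons] * 1
    tl <- tl_new
  }
  stats::setNames(tl, model$groups$name)
}

# Walk-summation oracle for Finn's cycling index: sums the visit-count
# series I + G + G^2 + ... term by term instead of inverting the matrix.
fci_power_series <- function(balanced, terms = 4000) {
  cf <- ranchena:::compartment_flows(balanced)
  Tf <- cf$throughflow
  ok <- Tf > 0
  G <- cf$F
  G[ok, ] <- cf$F[ok, ] / Tf[ok]
  G[!ok, ] <- 0
  N <- diag(nrow(G))
  term <- diag(nrow(G))
  for (k in seq_len(terms)) {
    term <- term %*% G
    N <- N + term
    if (max(abs(term)) < 1e-14) break
  }
  cycled <- sum(Tf[ok] * (diag(N)[ok] - 1) / diag(N)[ok])
  a <- attribute_summary(balanced)
  100 * cycled / a$TST
}

# Path-enumeration oracle for integer-TL fractions on acyclic webs:
# enumerates every prey chain below each group and accumulates the product
# of diet fractions at the chain's length.
tl_fraction_paths <- function(model, max_tl = 10) {
  nm <- model$groups$name
  dc <- model$diet[nm, , drop = FALSE]
  imp <- model$diet["import", ]
  cons <- model$groups$role == "consumer"
  fr <- matrix(0, length(nm), max_tl, dimnames = list(nm, NULL))
  # level fraction of group j = sum over prey chains of product of fractions
  memo <- new.env()
  frac_of <- function(j) {
    key <- as.character(j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- numeric(max_tl)
    if (!cons[j]) {
      out[1] <- 1
    } else {
      out[2] <- imp[j]
      for (i in which(dc[, j] > 0)) {
        fi <- frac_of(i)
        out[2:max_tl] <- out[2:max_tl] + dc[i, j] * fi[1:(max_tl - 1)]
      }
    }
    memo[[key]] <- out
    out
  }
  for (j in seq_along(nm)) fr[j, ] <- frac_of(j)
  fr
}

# Independently coded scalar RK4 integration of the unfished, unforced
# three-group arena system (producer, one consumer, detritus), written from
# the equations rather than from the package's vectorised integrator.
scalar_arena_oracle <- function(arena, years, steps_per_year) {
  L <- arena$links
  stopifnot(nrow(L) == 1) # single consumer->producer link
  i <- L$prey; j <- L$pred
  v <- L$v_rate; a <- L$a
  det <- arena$detritus
  B0 <- as.numeric(arena$B0)
  pm <- arena$pmax_pb[i]
  ge <- arena$GE[j]
  ui <- arena$Ui[j]
  m0 <- as.numeric(arena$M0)
  kdet <- arena$det_export_rate

  f <- function(s) {
    q <- v * a * s[i] * s[j] / (v + a * s[j])
    d <- numeric(3)
    d[i] <- pm * s[i] / (1 + s[i] / B0[i]) - q - m0[i] * s[i]
    d[j] <- ge * q - m0[j] * s[j]
    d[det] <- ui * q + m0[i] * s[i] + m0[j] * s[j] - kdet * s[det]
    d
  }
  s <- B0
  h <- 1 / steps_per_year
  for (n in seq_len(years * steps_per_year)) {
    k1 <- f(s); k2 <- f(s + h / 2 * k1)
    k3 <- f(s + h / 2 * k2); k4 <- f(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s
}

# Brute-force grid scan oracle for carrying capacity: finest feasible
# biomass on a regular grid.
capacity_grid_scan <- function(model, group, upper, step_frac = 1e-3) {
  grid <- seq(model$groups$B[model$groups$name == group], upper,
              by = step_frac * upper)
  best <- NA_real_
  for (b in grid) {
    m2 <- model
    m2$groups$B[m2$groups$name == group] <- b
    if (is_feasible(solve_mass_balance(m2))) best <- b else break
  }
  best
}
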