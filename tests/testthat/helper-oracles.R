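# Independent oracles: exhaustive enumeration over binary indicator
# assignments with per-assignment feasibility LPs. These deliberately avoid
# the branch-and-bound MILP path they are used to check.

# option sets per reaction given its trilevel state; each option modifies
# the reaction's bounds and contributes 0/1 to the agreement count
indicator_options <- function(model, states, eps = 1, default_bound = 1000) {
  bnd <- fluxcond:::model_bounds(model, default_bound)
  rids <- names(model$reactions)
  opts <- list()
  for (j in seq_along(rids)) {
    st <- states$state_of[[rids[j]]]
    lb <- unname(bnd$lb[j]); ub <- unname(bnd$ub[j])
    if (st == "HIGH") {
      o <- list(list(lb = lb, ub = ub, credit = 0),
                list(lb = max(lb, eps), ub = ub, credit = 1))
      if (lb < 0) {
        o[[3]] <- list(lb = lb, ub = min(ub, -eps), credit = 1)
      }
      opts[[rids[j]]] <- o
    } else if (st == "LOW") {
      opts[[rids[j]]] <- list(
        list(lb = lb, ub = ub, credit = 0),
        list(lb = max(lb, 0), ub = min(ub, 0), credit = 1))
    } else {
      opts[[rids[j]]] <- list(list(lb = lb, ub = ub, credit = 0))
    }
  }
  opts
}

# exhaustive iMAT oracle: max agreement over all indicator assignments,
# each checked by a phase-1 feasibility LP on {S v = 0, modified bounds}
imat_oracle <- function(model, states, eps = 1, default_bound = 1000,
                        keep_optimal = FALSE) {
  S <- stoichiometric_matrix(model)
  b0 <- rep(0, nrow(S))
  opts <- indicator_options(model, states, eps, default_bound)
  n_opt <- vapply(opts, length, integer(1))
  grid <- expand.grid(lapply(n_opt, seq_len))
  best <- -1L
  best_bounds <- list()
  for (i in seq_len(nrow(grid))) {
    sel <- as.integer(grid[i, ])
    credit <- 0L
    lb <- ub <- numeric(length(opts))
    for (j in seq_along(opts)) {
      o <- opts[[j]][[sel[j]]]
      lb[j] <- o$lb; ub[j] <- o$ub
      credit <- credit + o$credit
    }
    if (credit < best || any(lb > ub + 1e-12)) next
    feas <- fluxcond:::lp_feasible(S, b0, lb, ub)
    if (feas$feasible) {
      if (credit > best) {
        best <- credit
        best_bounds <- list()
      }
      if (keep_optimal) {
        best_bounds[[length(best_bounds) + 1L]] <- list(lb = lb, ub = ub)
      }
    }
  }
  list(agreement = best, optimal_bounds = best_bounds)
}

# exhaustive agreement-constrained FVA oracle: per reaction, min/max flux
# over all assignments attaining the maximal agreement
fva_oracle <- function(model, states, eps = 1, default_bound = 1000) {
  S <- stoichiometric_matrix(model)
  b0 <- rep(0, nrow(S))
  res <- imat_oracle(model, states, eps, default_bound, keep_optimal = TRUE)
  n <- length(model$reactions)
  mins <- rep(Inf, n); maxs <- rep(-Inf, n)
  for (bb in res$optimal_bounds) {
    for (j in seq_len(n)) {
      e <- numeric(n); e[j] <- 1
      lo <- fluxcond:::lp_solve(e, A_eq = S, b_eq = b0, lb = bb$lb,
                                ub = bb$ub)
      hi <- fluxcond:::lp_solve(e, A_eq = S, b_eq = b0, lb = bb$lb,
                                ub = bb$ub, maximize = TRUE)
      mins[j] <- min(mins[j], lo$obj)
      maxs[j] <- max(maxs[j], hi$obj)
    }
  }
  data.frame(reaction = names(model$reactions), min = mins, max = maxs,
             stringsAsFactors = FALSE)
}

# hypergeometric survival oracle: enumerate all C(M, N) draws from a
# population whose first K objects form the category
hyper_oracle <- function(x, M, K, N) {
  if (x == 0) return(1)
  draws <- utils::combn(M, N)
  mean(apply(draws, 2, function(d) sum(d <= K)) >= x)
}

# direct running-sum ES oracle (plain loop over the ranked list);
# positive extreme wins a magnitude tie, matching the package convention
es_oracle <- function(pos, absw, G) {
  K <- length(pos)
  nr <- sum(absw[pos])
  run <- 0
  profile <- numeric(G)
  for (i in seq_len(G)) {
    run <- run + if (i %in% pos) {
      if (nr > 0) absw[i] / nr else 1 / K
    } else {
      -1 / (G - K)
    }
    profile[i] <- run
  }
  hi <- max(profile)
  lo <- min(c(0, profile))
  if (hi >= -lo - 1e-12) hi else lo
}
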