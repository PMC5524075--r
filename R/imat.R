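#' iMAT configuration
#'
#' @param epsilon minimum flux magnitude for a reaction to count as active
#'   (flux units; default 1).
#' @param default_bound magnitude substituted for infinite bounds.
#' @param mip_gap relative optimality tolerance of the branch and bound.
#' @param feas_tol feasibility tolerance for steady-state residuals.
#' @return list of class `imat_config`.
#' @export
imat_config <- function(epsilon = 1.0, default_bound = 1000,
                        mip_gap = 1e-9, feas_tol = 1e-9) {
  stopifnot(epsilon > 0, default_bound > epsilon)
  structure(list(epsilon = epsilon, default_bound = default_bound,
                 mip_gap = mip_gap, feas_tol = feas_tol),
            class = "imat_config")
}

# Assemble the iMAT MILP:
#   max sum(y)  s.t.  S v = 0, lb <= v <= ub,
#   HIGH r:  y+ = 1 -> v_r >= eps;  y- = 1 (reversible only) -> v_r <= -eps;
#            y+ + y- <= 1
#   LOW  r:  y0 = 1 -> v_r = 0
# Indicator implications are big-M rows using the reaction's own bounds.
build_imat_problem <- function(model, states, config = imat_config()) {
  rids <- reaction_ids(model)
  stopifnot(setequal(names(states$state_of), rids))
  st <- states$state_of[rids]
  n <- length(rids)
  bnd <- model_bounds(model, config$default_bound)
  lb_v <- unname(bnd$lb)
  ub_v <- unname(bnd$ub)
  eps <- config$epsilon
  S <- stoichiometric_matrix(model)

  bin <- list()  # one entry per binary: reaction index, kind
  rows <- list() # A_le rows over (v, y); rhs collected alongside
  rhs <- numeric(0)
  add_row <- function(vcol, vco, ycol, yco, b) {
    rows[[length(rows) + 1L]] <<- list(vcol = vcol, vco = vco,
                                       ycol = ycol, yco = yco)
    rhs[length(rhs) + 1L] <<- b
  }
  for (j in seq_len(n)) {
    if (st[j] == "HIGH") {
      yp <- length(bin) + 1L
      bin[[yp]] <- list(rxn = j, kind = "y_plus")
      add_row(j, -1, yp, eps - lb_v[j], -lb_v[j])
      if (lb_v[j] < 0) {
        ym <- length(bin) + 1L
        bin[[ym]] <- list(rxn = j, kind = "y_minus")
        add_row(j, 1, ym, eps + ub_v[j], ub_v[j])
        add_row(integer(0), numeric(0), c(yp, ym), c(1, 1), 1)
      }
    } else if (st[j] == "LOW") {
      y0 <- length(bin) + 1L
      bin[[y0]] <- list(rxn = j, kind = "y_zero")
      add_row(j, 1, y0, ub_v[j], ub_v[j])
      add_row(j, -1, y0, -lb_v[j], -lb_v[j])
    }
  }
  nb <- length(bin)
  ntot <- n + nb
  A_le <- matrix(0, length(rows), ntot)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r$vcol)) A_le[i, r$vcol] <- r$vco
    if (length(r$ycol)) A_le[i, n + r$ycol] <- r$yco
  }
  A_eq <- cbind(S, matrix(0, nrow(S), nb))
  obj <- c(rep(0, n), rep(1, nb))
  list(obj = obj, A_eq = A_eq, b_eq = rep(0, nrow(S)),
       A_le = A_le, b_le = rhs,
       lb = c(lb_v, rep(0, nb)), ub = c(ub_v, rep(1, nb)),
       int_idx = if (nb > 0) (n + 1):ntot else integer(0),
       n_rxn = n, rids = rids, bin = bin, states = st)
}

#' Solve the iMAT mixed-integer program
#'
#' Finds a steady-state flux distribution maximizing the number of
#' reactions whose activity agrees with their trilevel expression state:
#' a HIGH reaction agrees when it carries flux of magnitude at least
#' `epsilon` (either direction, if reversible), a LOW reaction agrees when
#' its flux is zero; MODERATE reactions carry no indicator.
#'
#' @param model a `metabolic_model`.
#' @param states a reaction state (list with `condition`, `state_of`) from
#'   [reaction_states()].
#' @param config an [imat_config()].
#' @return list of class `imat_solution`: `flux` (named vector),
#'   `agreement` (objective value), `active_high`, `silenced_low`,
#'   `indicators`, `condition`, `status`.
#' @export
solve_imat <- function(model, states, config = imat_config()) {
  prob <- build_imat_problem(model, states, config)
  res <- milp_solve(prob$obj, prob$A_eq, prob$b_eq, prob$A_le, prob$b_le,
                    prob$lb, prob$ub, prob$int_idx, maximize = TRUE)
  if (res$status != "optimal") {
    stop("solve_imat: model infeasible (no steady-state flux within bounds)")
  }
  flux <- setNames(res$x[seq_len(prob$n_rxn)], prob$rids)
  resid <- max(abs(prob$A_eq[, seq_len(prob$n_rxn), drop = FALSE] %*% flux))
  if (length(resid) && resid > max(config$feas_tol, 1e-6)) {
    stop("solve_imat: steady-state residual ", format(resid),
         " exceeds tolerance")
  }
  yv <- round(res$x[prob$int_idx])
  agreement <- as.integer(round(res$obj))
  active_high <- list()
  silenced_low <- list()
  for (i in seq_along(prob$bin)) {
    b <- prob$bin[[i]]
    rid <- prob$rids[b$rxn]
    if (b$kind == "y_plus" && yv[i] == 1) active_high[[rid]] <- "forward-active"
    if (b$kind == "y_minus" && yv[i] == 1) active_high[[rid]] <- "reverse-active"
    if (b$kind == "y_zero") {
      silenced_low[[rid]] <- if (yv[i] == 1) "silent" else "active"
    }
  }
  for (rid in prob$rids[prob$states == "HIGH"]) {
    if (is.null(active_high[[rid]])) active_high[[rid]] <- "inactive"
  }
  structure(list(flux = flux, agreement = agreement,
                 active_high = active_high, silenced_low = silenced_low,
                 indicators = yv, condition = states$condition,
                 status = "optimal"),
            class = "imat_solution")
}

#' Write an iMAT solution as TSV plus a JSON summary
#' @param sol an `imat_solution`.
#' @param states the reaction states it was solved against.
#' @param path_tsv,path_json output paths (either may be NULL to skip).
#' @return invisible NULL.
#' @export
write_imat_solution <- function(sol, states, path_tsv = NULL,
                                path_json = NULL) {
  if (!is.null(path_tsv)) {
    ind <- vapply(names(sol$flux), function(rid) {
      if (!is.null(sol$active_high[[rid]])) sol$active_high[[rid]]
      else if (!is.null(sol$silenced_low[[rid]])) sol$silenced_low[[rid]]
      else ""
    }, character(1))
    df <- data.frame(reaction = names(sol$flux), flux = unname(sol$flux),
                     indicator = unname(ind),
                     state = unname(states$state_of[names(sol$flux)]))
    utils::write.table(df, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(condition = sol$condition,
                              agreement = sol$agreement,
                              status = sol$status),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
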