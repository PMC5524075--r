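#' Flux variability analysis at maximal expression agreement
#'
#' First solves the iMAT program to obtain the maximal agreement level A*,
#' then, for every reaction, minimizes and maximizes its flux under all
#' iMAT constraints plus the additional constraint that the indicator sum
#' equals A*.
#'
#' @inheritParams solve_imat
#' @param imat_solution optionally a precomputed [solve_imat()] result
#'   (saves one MILP solve).
#' @return list of class `fva_result`: `condition`, `agreement_fixed`,
#'   `bounds` (data.frame reaction/min/max).
#' @export
fva_at_max_agreement <- function(model, states, config = imat_config(),
                                 imat_solution = NULL) {
  if (is.null(imat_solution)) imat_solution <- solve_imat(model, states, config)
  a_star <- imat_solution$agreement
  prob <- build_imat_problem(model, states, config)
  nb <- length(prob$bin)
  A_eq <- prob$A_eq
  b_eq <- prob$b_eq
  if (nb > 0) {
    A_eq <- rbind(A_eq, c(rep(0, prob$n_rxn), rep(1, nb)))
    b_eq <- c(b_eq, a_star)
  }
  n <- prob$n_rxn
  mins <- maxs <- numeric(n)
  for (j in seq_len(n)) {
    e <- rep(0, n + nb); e[j] <- 1
    lo <- milp_solve(e, A_eq, b_eq, prob$A_le, prob$b_le, prob$lb, prob$ub,
                     prob$int_idx, maximize = FALSE)
    hi <- milp_solve(e, A_eq, b_eq, prob$A_le, prob$b_le, prob$lb, prob$ub,
                     prob$int_idx, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("fva_at_max_agreement: internal consistency error - ",
           "infeasible at fixed agreement ", a_star)
    }
    mins[j] <- lo$obj
    maxs[j] <- hi$obj
  }
  structure(list(condition = states$condition, agreement_fixed = a_star,
                 bounds = data.frame(reaction = prob$rids, min = mins,
                                     max = maxs, stringsAsFactors = FALSE)),
            class = "fva_result")
}

#' Plain flux variability analysis (no expression constraints)
#'
#' @param model a `metabolic_model`.
#' @param default_bound magnitude substituted for infinite bounds.
#' @return data.frame reaction/min/max.
#' @export
fva_plain <- function(model, default_bound = 1000) {
  S <- stoichiometric_matrix(model)
  bnd <- model_bounds(model, default_bound)
  n <- length(bnd$lb)
  mins <- maxs <- numeric(n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- 1
    mins[j] <- lp_solve(e, S, rep(0, nrow(S)), lb = unname(bnd$lb),
                        ub = unname(bnd$ub))$obj
    maxs[j] <- lp_solve(e, S, rep(0, nrow(S)), lb = unname(bnd$lb),
                        ub = unname(bnd$ub), maximize = TRUE)$obj
  }
  data.frame(reaction = reaction_ids(model), min = mins, max = maxs,
             stringsAsFactors = FALSE)
}

# run expr with the RNG seeded, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Monte-Carlo sampling of the agreement-constrained flux space
#'
#' Draws `n_samples` approximately uniform flux vectors from the polytope
#' `{S v = 0, fva$min <= v <= fva$max}` by coordinate-free hit-and-run in
#' the polytope's affine hull: directions are isotropic in the null space
#' of S (restricted to non-degenerate coordinates), chord endpoints come
#' from the box bounds, and the chain starts at a most-interior
#' (max-min-slack) point. Burn-in and thinning are fixed and recorded.
#'
#' @param model a `metabolic_model`.
#' @param fva an `fva_result` (or any list with a `bounds` data.frame).
#' @param n_samples number of flux vectors to return (default 2000).
#' @param seed RNG seed; runs are deterministic given the seed.
#' @param burn_in discarded initial steps.
#' @param thin chain steps per retained sample.
#' @param box_only drop the steady-state constraint and sample the bound box
#'   directly (sensitivity mode; not a flux distribution).
#' @return list of class `flux_samples`: `samples`
#'   (n_samples x n_reactions matrix), `condition`, `seed`, `burn_in`,
#'   `thin`, `box_only`.
#' @export
sample_flux_space <- function(model, fva, n_samples = 2000, seed = 1,
                              burn_in = 1000, thin = 10, box_only = FALSE) {
  rids <- reaction_ids(model)
  bd <- fva$bounds
  stopifnot(setequal(bd$reaction, rids))
  bd <- bd[match(rids, bd$reaction), ]
  l <- bd$min
  u <- bd$max
  n <- length(rids)
  if (any(u - l < -1e-9)) stop("sample_flux_space: empty polytope (min > max)")
  wtol <- 1e-9
  fixed <- (u - l) <= wtol

  make_out <- function(samp) {
    colnames(samp) <- rids
    structure(list(condition = fva$condition, samples = samp, seed = seed,
                   n_samples = n_samples, burn_in = burn_in, thin = thin,
                   box_only = box_only),
              class = "flux_samples")
  }

  if (box_only) {
    return(with_seed(seed, {
      samp <- matrix(runif(n_samples * n), n_samples, n)
      samp <- sweep(sweep(samp, 2, u - l, `*`), 2, l, `+`)
      make_out(samp)
    }))
  }

  S <- stoichiometric_matrix(model)
  aug <- S
  if (any(fixed)) {
    E <- matrix(0, sum(fixed), n)
    E[cbind(seq_len(sum(fixed)), which(fixed))] <- 1
    aug <- rbind(S, E)
  }
  sv <- svd(aug, nu = 0, nv = n)
  dtol <- max(dim(aug)) * max(sv$d, 0) * .Machine$double.eps
  rank <- sum(sv$d > max(dtol, 1e-10))
  k <- n - rank
  mid <- (l + u) / 2

  if (k == 0) {
    # zero-dimensional polytope: the unique point, replicated
    feas <- lp_feasible(S, rep(0, nrow(S)), l, u)
    if (!feas$feasible) stop("sample_flux_space: empty polytope")
    warning("sample_flux_space: zero-volume polytope; returning the unique ",
            "point replicated ", n_samples, " times")
    return(make_out(matrix(rep(feas$x, each = n_samples), n_samples, n)))
  }
  N <- sv$v[, (rank + 1):n, drop = FALSE]

  # most-interior start: maximize the minimum slack delta on free coordinates
  free <- which(!fixed)
  nf <- length(free)
  A_le <- matrix(0, 2 * nf, n + 1)
  b_le <- numeric(2 * nf)
  for (i in seq_len(nf)) {
    j <- free[i]
    A_le[2 * i - 1, j] <- -1; A_le[2 * i - 1, n + 1] <- 1
    b_le[2 * i - 1] <- -l[j]
    A_le[2 * i, j] <- 1; A_le[2 * i, n + 1] <- 1
    b_le[2 * i] <- u[j]
  }
  obj <- c(rep(0, n), 1)
  ctr <- lp_solve(obj, A_eq = cbind(S, 0), b_eq = rep(0, nrow(S)),
                  A_le = A_le, b_le = b_le,
                  lb = c(l, 0), ub = c(u, max(u - l) / 2 + 1),
                  maximize = TRUE)
  if (ctr$status != "optimal") stop("sample_flux_space: empty polytope")
  v <- ctr$x[seq_len(n)]
  v[fixed] <- mid[fixed]

  with_seed(seed, {
    samp <- matrix(0, n_samples, n)
    total <- burn_in + thin * n_samples
    got <- 0L
    for (step in seq_len(total)) {
      g <- rnorm(k)
      d <- as.vector(N %*% g)
      nz <- which(abs(d) > 1e-12)
      if (length(nz) == 0) next
      alo <- -Inf; ahi <- Inf
      for (j in nz) {
        r1 <- (l[j] - v[j]) / d[j]
        r2 <- (u[j] - v[j]) / d[j]
        if (r1 > r2) { tmp <- r1; r1 <- r2; r2 <- tmp }
        if (r1 > alo) alo <- r1
        if (r2 < ahi) ahi <- r2
      }
      if (!is.finite(alo) || !is.finite(ahi) || ahi < alo) next
      a <- runif(1, alo, ahi)
      v <- v + a * d
      v <- pmin(pmax(v, l), u)  # clip O(eps) roundoff excursions
      if (step > burn_in && (step - burn_in) %% thin == 0) {
        got <- got + 1L
        samp[got, ] <- v
      }
    }
    if (got < n_samples) {
      samp[(got + 1):n_samples, ] <- matrix(rep(v, each = n_samples - got),
                                            n_samples - got, n)
    }
    make_out(samp)
  })
}

#' Write FVA bounds and flux samples to disk
#' @param fva an `fva_result`.
#' @param path output TSV.
#' @return invisible path.
#' @export
write_fva <- function(fva, path) {
  utils::write.table(fva$bounds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fva
#' @param samples a `flux_samples` object.
#' @param path_meta JSON metadata path (seed, burn-in, thinning).
#' @export
write_samples <- function(samples, path, path_meta = NULL) {
  con <- gzfile(paste0(path, ".gz"), "w")
  utils::write.table(samples$samples, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  if (!is.null(path_meta)) {
    jsonlite::write_json(
      list(condition = samples$condition, seed = samples$seed,
           n_samples = nrow(samples$samples), burn_in = samples$burn_in,
           thin = samples$thin, box_only = samples$box_only),
      path_meta, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
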