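#' Call per-reaction direction changes from sampled flux medians
#'
#' A reaction is UP when the condition-B median flux exceeds the
#' condition-A median by more than `tol * max(1, |median_A|)` (a relative
#' tolerance with an absolute floor of one flux unit, so sampler noise
#' around zero is not called); DOWN symmetrically; otherwise UNCHANGED.
#'
#' @param samples_a,samples_b `flux_samples` for the two conditions, over
#'   identical reaction lists.
#' @param tol relative tolerance (default 0.05).
#' @return data.frame of class `direction_table`: reaction, median_a,
#'   median_b, call.
#' @export
median_direction_calls <- function(samples_a, samples_b, tol = 0.05) {
  ra <- colnames(samples_a$samples)
  rb <- colnames(samples_b$samples)
  if (!identical(ra, rb)) {
    stop("median_direction_calls: sample sets cover different reaction lists")
  }
  med_a <- apply(samples_a$samples, 2, median)
  med_b <- apply(samples_b$samples, 2, median)
  thr <- tol * pmax(1, abs(med_a))
  call <- ifelse(med_b - med_a > thr, "UP",
                 ifelse(med_a - med_b > thr, "DOWN", "UNCHANGED"))
  structure(data.frame(reaction = ra, median_a = unname(med_a),
                       median_b = unname(med_b), call = unname(call),
                       stringsAsFactors = FALSE),
            class = c("direction_table", "data.frame"))
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= x) when drawing `N` objects without replacement from `M` objects
#' of which `K` are in the category, by exact summation of the
#' hypergeometric mass function (no normal approximation).
#'
#' @param x observed category count.
#' @param M population size.
#' @param K category size.
#' @param N number of draws.
#' @return the survival probability (with the atom at `x` included).
#' @export
hypergeometric_sf <- function(x, M, K, N) {
  stopifnot(x >= 0, K >= 0, N >= 0, K <= M, N <= M, x <= min(K, N))
  hi <- min(K, N)
  if (x == 0) return(1)
  sum(stats::dhyper(x:hi, m = K, n = M - K, k = N))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, returned in the input order and
#' capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted q-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Hypergeometric pathway enrichment of direction calls
#'
#' For each pathway and each direction separately, tests whether the
#' pathway's reactions are over-represented among the UP (or DOWN) calls.
#' The universe `M` contains only reactions carrying at least one pathway
#' label; `K` is the pathway's size within that universe, `N` the total
#' directional calls in the universe, `x` the directional calls inside the
#' pathway. All pathway-by-direction tests form one joint BH family.
#'
#' @param table a `direction_table` from [median_direction_calls()].
#' @param model a `metabolic_model` supplying pathway labels.
#' @return data.frame (pathway, direction, x, K, N, M, p_value, q_value)
#'   sorted by q then p.
#' @export
enrich_pathways <- function(table, model) {
  labeled <- unique(unlist(model$pathways))
  tab <- table[table$reaction %in% labeled, ]
  if (nrow(tab) == 0) {
    warning("enrich_pathways: no called reactions in any labeled pathway")
    return(data.frame(pathway = character(0), direction = character(0),
                      x = integer(0), K = integer(0), N = integer(0),
                      M = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  }
  M <- nrow(tab)
  res <- list()
  for (pw in names(model$pathways)) {
    in_pw <- tab$reaction %in% model$pathways[[pw]]
    K <- sum(in_pw)
    if (K == 0) next
    for (dir in c("UP", "DOWN")) {
      called <- tab$call == dir
      N <- sum(called)
      x <- sum(called & in_pw)
      p <- if (N == 0) 1 else hypergeometric_sf(x, M, K, N)
      res[[length(res) + 1L]] <- data.frame(
        pathway = pw, direction = dir, x = x, K = K, N = N, M = M,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out[order(out$q_value, out$p_value, out$pathway, out$direction), ]
}
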