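#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a line are dropped.
#'
#' @param path GMT file.
#' @return list of gene sets, each `list(name, description, genes)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("GMT format error at line ", i, ": fewer than 3 fields")
    }
    list(name = f[1], description = f[2], genes = unique(f[-(1:2)]))
  })
  out
}

#' Write gene sets to a GMT file
#' @param sets list of gene sets.
#' @param path output file.
#' @return invisible path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict gene sets to measured genes and filter by size
#'
#' Each set is first intersected with the measured genes; it is kept iff
#' the restricted size lies in `[min_size, max_size]` (the Broad GSEA
#' defaults of 15 and 500).
#'
#' @param sets list of gene sets from [read_gmt()].
#' @param measured_genes character vector of genes on the platform.
#' @param min_size,max_size inclusive size bounds after restriction.
#' @return filtered list of gene sets (with restricted membership).
#' @export
filter_gene_sets <- function(sets, measured_genes, min_size = 15,
                             max_size = 500) {
  out <- lapply(sets, function(s) {
    s$genes <- intersect(s$genes, measured_genes)
    s
  })
  keep <- vapply(out, function(s) {
    length(s$genes) >= min_size && length(s$genes) <= max_size
  }, logical(1))
  out[keep]
}

#' Rank genes by signal-to-noise between two conditions
#'
#' Score = `(mean_a - mean_b) / (sd_a' + sd_b')` where each standard
#' deviation is floored at `max(0.2 * |mean|, 0.2)` (the Broad GSEA
#' convention, keeping scores finite for low-variance genes). Genes are
#' returned in descending score order with ties broken by gene id.
#'
#' @param expr an [expression_matrix()].
#' @param condition_a,condition_b condition labels (>= 2 samples each).
#' @return named numeric vector of scores, names = gene ids, descending.
#' @export
rank_genes <- function(expr, condition_a, condition_b) {
  sa <- names(expr$condition_of)[expr$condition_of == condition_a]
  sb <- names(expr$condition_of)[expr$condition_of == condition_b]
  if (length(sa) < 2 || length(sb) < 2) {
    stop("rank_genes: signal-to-noise needs >= 2 samples per condition; ",
         "use a fold-change ranking for smaller groups")
  }
  va <- expr$values[, sa, drop = FALSE]
  vb <- expr$values[, sb, drop = FALSE]
  ma <- rowMeans(va)
  mb <- rowMeans(vb)
  sda <- apply(va, 1, sd)
  sdb <- apply(vb, 1, sd)
  sda <- pmax(sda, 0.2 * abs(ma), 0.2)
  sdb <- pmax(sdb, 0.2 * abs(mb), 0.2)
  score <- (ma - mb) / (sda + sdb)
  o <- order(-score, names(score))
  score[o]
}

# ES from sorted hit ranks. absw: |score|^weight over the full ranked list.
# Candidate extremes of the running sum occur just after each hit (local
# maxima) and just before each hit (local minima); the signed extreme of
# largest magnitude is the enrichment score.
es_from_positions <- function(pos, absw, G) {
  K <- length(pos)
  w <- absw[pos]
  NR <- sum(w)
  if (NR <= 0) w[] <- 1 / K else w <- w / NR
  miss <- 1 / (G - K)
  cw <- cumsum(w)
  after <- cw - (pos - seq_len(K)) * miss
  before <- c(0, cw[-K]) - (pos - seq_len(K)) * miss
  hi <- max(after)
  lo <- min(before)
  # positive wins a tie in magnitude (tolerance guards float noise)
  if (hi >= -lo - 1e-12) hi else lo
}

#' GSEA enrichment score and running-sum profile
#'
#' Walks the ranked list; at a set member the running sum rises by the
#' member's `|score|^weight` (normalized by the set total), at a non-member
#' it falls by `1/(G - K)`. The enrichment score is the signed deviation of
#' largest magnitude.
#'
#' @param ranked a ranked list from [rank_genes()] (named scores,
#'   descending).
#' @param set a gene set (`list(name, genes)` or a character vector);
#'   must be a proper nonempty subset of the ranked genes.
#' @param weight hit-weighting exponent (0 = classic Kolmogorov-Smirnov,
#'   1 = Broad default).
#' @return list with `es` and `running` (length-G profile).
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  genes <- if (is.list(set)) set$genes else set
  G <- length(ranked)
  pos <- match(genes, names(ranked))
  if (anyNA(pos)) stop("enrichment_score: set contains unranked genes")
  pos <- sort(pos)
  K <- length(pos)
  if (K == 0 || K == G) {
    stop("enrichment_score: set must be a nonempty proper subset")
  }
  absw <- abs(unname(ranked))^weight
  w <- absw[pos]
  NR <- sum(w)
  incr <- rep(-1 / (G - K), G)
  incr[pos] <- if (NR <= 0) 1 / K else w / NR
  running <- cumsum(incr)
  es <- es_from_positions(pos, absw, G)
  list(es = es, running = running)
}

#' Run GSEA with a gene-set-randomization null
#'
#' Scores each filtered set on the fixed signal-to-noise ranking; the null
#' distribution for a set of size K is obtained by recomputing the
#' enrichment score for `n_perm` random gene sets of size K drawn
#' uniformly without replacement from the measured genes (gene-set
#' randomization, appropriate for very small sample sizes where phenotype
#' permutation is underpowered). P-values are same-sign one-tailed with an
#' add-one correction; NES divides ES by the mean magnitude of same-sign
#' null scores; FDR q compares NES against the pooled normalized null
#' (`fdr_method = "broad"`) or applies BH to the permutation p-values
#' (`fdr_method = "bh"`).
#'
#' @param expr an [expression_matrix()].
#' @param sets gene sets (already filtered, or raw - they are restricted
#'   and size-filtered against the measured genes here).
#' @param condition_a,condition_b condition labels; defaults to the first
#'   two condition labels in `expr`.
#' @param n_perm permutations per set size (default 1000).
#' @param weight hit-weighting exponent.
#' @param seed RNG seed (results are deterministic given the seed).
#' @param min_size,max_size set-size filter bounds.
#' @param fdr_method `"broad"` or `"bh"`.
#' @return data.frame (set, size, es, nes, p_value, q_value) sorted by
#'   decreasing NES.
#' @export
run_gsea <- function(expr, sets, condition_a = NULL, condition_b = NULL,
                     n_perm = 1000, weight = 1, seed = 1,
                     min_size = 15, max_size = 500,
                     fdr_method = c("broad", "bh")) {
  fdr_method <- match.arg(fdr_method)
  if (n_perm < 100) {
    warning("run_gsea: n_perm < 100 gives unstable q-values")
  }
  conds <- unique(unname(expr$condition_of))
  if (is.null(condition_a)) condition_a <- conds[1]
  if (is.null(condition_b)) condition_b <- conds[2]
  ranked <- rank_genes(expr, condition_a, condition_b)
  sets <- filter_gene_sets(sets, names(ranked), min_size, max_size)
  if (length(sets) == 0) stop("run_gsea: no gene sets survive filtering")
  G <- length(ranked)
  absw <- abs(unname(ranked))^weight

  sizes <- vapply(sets, function(s) length(s$genes), integer(1))
  es_obs <- vapply(sets, function(s) {
    es_from_positions(sort(match(s$genes, names(ranked))), absw, G)
  }, numeric(1))

  null_by_size <- with_seed(seed, {
    out <- list()
    for (K in sort(unique(sizes))) {
      out[[as.character(K)]] <- vapply(seq_len(n_perm), function(i) {
        es_from_positions(sort(sample.int(G, K)), absw, G)
      }, numeric(1))
    }
    out
  })

  nes <- p <- numeric(length(sets))
  null_nes_pool <- list()
  for (i in seq_along(sets)) {
    nulls <- null_by_size[[as.character(sizes[i])]]
    pos_n <- nulls[nulls >= 0]
    neg_n <- nulls[nulls < 0]
    same <- if (es_obs[i] >= 0) pos_n else neg_n
    p[i] <- (1 + sum(abs(same) >= abs(es_obs[i]))) / (1 + length(same))
    denom <- if (length(same) > 0) mean(abs(same)) else NA_real_
    nes[i] <- if (is.na(denom) || denom == 0) 0 else es_obs[i] / denom
    mp <- if (length(pos_n) > 0) mean(pos_n) else NA_real_
    mn <- if (length(neg_n) > 0) mean(abs(neg_n)) else NA_real_
    null_nes_pool[[i]] <- c(if (!is.na(mp) && mp > 0) pos_n / mp,
                            if (!is.na(mn) && mn > 0) neg_n / mn)
  }

  if (fdr_method == "bh") {
    q <- bh_adjust(p)
  } else {
    pool <- unlist(null_nes_pool)
    q <- vapply(seq_along(sets), function(i) {
      s <- nes[i]
      if (s >= 0) {
        num_d <- sum(pool >= 0)
        den_d <- sum(nes >= 0)
        if (num_d == 0 || den_d == 0) return(1)
        num <- sum(pool >= s) / num_d
        den <- sum(nes >= s) / den_d
      } else {
        num_d <- sum(pool < 0)
        den_d <- sum(nes < 0)
        if (num_d == 0 || den_d == 0) return(1)
        num <- sum(pool <= s) / num_d
        den <- sum(nes <= s) / den_d
      }
      if (den == 0) return(1)
      min(1, num / den)
    }, numeric(1))
    # step-up monotonicity in |NES| within each sign: a more extreme score
    # may inherit a smaller q from the less extreme tail, never a larger one
    for (sgn in c(1, -1)) {
      idx <- which(if (sgn > 0) nes >= 0 else nes < 0)
      if (length(idx) > 1) {
        o <- idx[order(-abs(nes[idx]))]
        q[o] <- rev(cummin(rev(q[o])))
      }
    }
  }

  out <- data.frame(set = vapply(sets, `[[`, character(1), "name"),
                    size = sizes, es = es_obs, nes = nes, p_value = p,
                    q_value = q, stringsAsFactors = FALSE)
  out[order(-out$nes), ]
}
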