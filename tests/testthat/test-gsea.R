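test_that("GMT reading and writing round-trip with deduplication", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tg1\tg2", "SETB\tother\tg2\tg3\tg3\tg4"), path)
  sets <- read_gmt(path)
  expect_length(sets, 2)
  expect_equal(sets[[1]]$genes, c("g1", "g2"))
  expect_length(sets[[2]]$genes, 3)  # duplicate g3 dropped
  bad <- tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tg1", "SETB\tonlydesc"), bad)
  expect_error(read_gmt(bad), "line 2")
  empty <- tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_length(read_gmt(empty), 0)

  out <- tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_equal(read_gmt(out), sets)
})

test_that("gene set filtering restricts then applies the 15-500 rule", {
  measured <- paste0("g", 1:600)
  mk <- function(n, from = 1) list(name = paste0("S", n), description = "",
                                   genes = paste0("g", from:(from + n - 1)))
  sets <- list(mk(14), mk(15), mk(500), mk(501),
               list(name = "Spartial", description = "",
                    genes = c(paste0("g", 1:10), paste0("x", 1:10))))
  kept <- filter_gene_sets(sets, measured)
  expect_setequal(vapply(kept, `[[`, character(1), "name"),
                  c("S15", "S500"))
  # restriction happens before the size filter: 10 measured of 20 -> dropped
  expect_false("Spartial" %in% vapply(kept, `[[`, character(1), "name"))
})

test_that("signal-to-noise ranking applies the Broad sd floors", {
  vals <- rbind(
    g_up = c(2, 2, 2, 1, 1, 1),      # sd 0 -> floored
    g_eq = c(1, 1, 1, 1, 1, 1),
    g_var = c(2.5, 2, 1.5, 1.5, 1, 0.5)
  )
  colnames(vals) <- paste0("s", 1:6)
  ex <- expression_matrix(vals, setNames(rep(c("A", "B"), each = 3),
                                         colnames(vals)))
  r <- rank_genes(ex, "A", "B")
  # g_up: means 2 vs 1, sds floored at 0.4 and 0.2 -> 1 / 0.6
  expect_equal(unname(r["g_up"]), 1 / 0.6, tolerance = 1e-12)
  expect_equal(unname(r["g_eq"]), 0)
  # g_var: sds 0.5 each, floors max(0.2*mean, 0.2) larger: 0.4 & 0.2...
  sa <- max(sd(c(2.5, 2, 1.5)), 0.2 * 2, 0.2)
  sb <- max(sd(c(1.5, 1, 0.5)), 0.2 * 1, 0.2)
  expect_equal(unname(r["g_var"]), (2 - 1) / (sa + sb))
  expect_equal(names(r)[1], "g_up")  # descending order
  ex2 <- expression_matrix(vals[, 1:4],
                           setNames(c("A", "A", "A", "B"), paste0("s", 1:4)))
  expect_error(rank_genes(ex2, "A", "B"), "2 samples")
})

test_that("enrichment score hits the documented extremes", {
  ranked <- setNames(seq(10, 1), paste0("g", 1:10))
  top <- enrichment_score(ranked, "g1", weight = 0)
  expect_equal(top$es, 1)
  bottom <- enrichment_score(ranked, "g10", weight = 0)
  expect_equal(bottom$es, -1)
  # running sum ends at zero
  expect_equal(top$running[10], 0, tolerance = 1e-12)
  expect_lt(max(abs(enrichment_score(ranked, c("g2", "g7"))$running[10])),
            1e-12)
  expect_error(enrichment_score(ranked, paste0("g", 1:10)), "proper subset")
  expect_error(enrichment_score(ranked, "nope"), "unranked")
})

test_that("ES at weight 0 is invariant under monotone score transforms", {
  ranked1 <- setNames(seq(20, 1), paste0("g", 1:20))
  ranked2 <- setNames(exp(seq(20, 1) / 3), paste0("g", 1:20))
  set <- c("g3", "g9", "g15")
  expect_equal(enrichment_score(ranked1, set, weight = 0)$es,
               enrichment_score(ranked2, set, weight = 0)$es)
})

test_that("ES matches the brute-force running-sum oracle (all arrangements)", {
  for (G in c(5, 8)) {
    scores <- fluxcond:::with_seed(G, sort(round(runif(G, -2, 3), 2),
                                           decreasing = TRUE))
    ranked <- setNames(scores, paste0("g", seq_len(G)))
    for (K in 1:3) {
      combos <- utils::combn(G, K)
      for (ci in seq_len(ncol(combos))) {
        pos <- combos[, ci]
        for (w in c(0, 1)) {
          absw <- abs(scores)^w
          expect_equal(
            enrichment_score(ranked, paste0("g", pos), weight = w)$es,
            es_oracle(pos, absw, G),
            tolerance = 1e-12,
            info = sprintf("G=%d K=%d ci=%d w=%g", G, K, ci, w))
        }
      }
    }
  }
})

test_that("run_gsea is deterministic and finds a planted set", {
  d <- simulate_gsea_dataset(n_genes = 600, n_sets = 12, set_size = 25,
                             planted_set_count = 2, effect_size = 2,
                             seed = 3)
  r1 <- run_gsea(d$expr, d$sets, n_perm = 300, seed = 11)
  r2 <- run_gsea(d$expr, d$sets, n_perm = 300, seed = 11)
  expect_identical(r1, r2)
  top2 <- r1$set[order(-abs(r1$nes))][1:2]
  expect_setequal(top2, d$truth$planted)
  expect_true(all(r1$q_value[r1$set %in% d$truth$planted] < 0.05))
  expect_true(all(abs(r1$es) <= 1))
  expect_true(all(sign(r1$nes) == sign(r1$es) | r1$es == 0))
})

test_that("gene-set randomization null is sign-symmetric at weight 0", {
  d <- simulate_gsea_dataset(n_genes = 400, n_sets = 5, set_size = 20,
                             planted_set_count = 0, effect_size = 0,
                             seed = 9)
  ranked <- rank_genes(d$expr, "WT", "KO")
  absw <- rep(1, length(ranked))
  nulls <- fluxcond:::with_seed(13, vapply(1:2000, function(i) {
    fluxcond:::es_from_positions(sort(sample.int(length(ranked), 20)),
                                 absw, length(ranked))
  }, numeric(1)))
  expect_lt(abs(mean(nulls > 0) - 0.5), 0.05)
})

test_that("BH fallback FDR agrees with bh_adjust of permutation p-values", {
  d <- simulate_gsea_dataset(n_genes = 400, n_sets = 8, set_size = 20,
                             planted_set_count = 1, effect_size = 1.5,
                             seed = 5)
  r <- run_gsea(d$expr, d$sets, n_perm = 200, seed = 2, fdr_method = "bh")
  expect_equal(r$q_value, bh_adjust(r$p_value))
})
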