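test_that("generated toy networks validate and are reproducible", {
  toy <- make_toy_network(n_pathways = 2, reactions_per_pathway = 3,
                          seed = 4)
  expect_gte(length(toy$model$reactions), 8)
  expect_length(toy$model$pathways, 2)
  rep <- validate_model(toy$model)
  non_blocked <- rep$issues[rep$issues$type != "blocked_reaction", ]
  expect_equal(nrow(non_blocked), 0)
  expect_equal(rep$blocked, "R_blocked")  # exactly the planted dead end
  toy2 <- make_toy_network(n_pathways = 2, reactions_per_pathway = 3,
                           seed = 4)
  expect_equal(write_model_string(toy$model), write_model_string(toy2$model))
  clean <- make_toy_network(include_blocked_branch = FALSE, seed = 4)
  expect_length(validate_model(clean$model)$blocked, 0)
})

test_that("planted flux modes are exactly mass balanced", {
  toy <- make_toy_network(seed = 2)
  eff <- default_condition_effects(toy$layout)
  tr <- plant_condition_fluxes(toy, eff)
  S <- stoichiometric_matrix(toy$model)
  for (cd in tr$conditions) {
    expect_identical(max(abs(S %*% tr$modes[[cd]])), 0)
  }
  # directions follow the effect map: P2 ON->OFF is DOWN, P3 OFF->ON is UP
  expect_true(all(tr$planted_direction[toy$layout$pathways$P2] == "DOWN"))
  expect_true(all(tr$planted_direction[toy$layout$pathways$P3] == "UP"))
  expect_true(all(tr$planted_direction[toy$layout$pathways$P1] ==
                    "UNCHANGED"))
  # scaling a pathway up plants UP
  eff2 <- eff
  eff2[[2]]$P1 <- 2
  tr2 <- plant_condition_fluxes(toy, eff2)
  expect_true(all(tr2$planted_direction[toy$layout$pathways$P1] == "UP"))
  expect_error(plant_condition_fluxes(
    toy, list(A = list(NOPE = "ON"), B = list(NOPE = "ON"))),
    "unknown pathway")
})

test_that("noise-free expression reproduces planted states exactly", {
  toy <- make_toy_network(seed = 1)
  tr <- plant_condition_fluxes(toy, default_condition_effects(toy$layout))
  ex <- simulate_expression(toy$model, tr, noise_sd = 0, seed = 1)
  expect_equal(ncol(ex$values), 7)  # 4 + 3 samples
  gs <- condition_gene_states(ex)
  for (cd in tr$conditions) {
    rs <- reaction_states(gs[[cd]], toy$model)
    active <- tr$active[[cd]]
    for (r in toy$model$reactions) {
      if (is.null(r$gpr_tree)) next
      want <- if (r$id %in% active) "HIGH" else "LOW"
      expect_equal(unname(rs$state_of[r$id]), want,
                   info = paste(cd, r$id))
    }
  }
})

test_that("noisy expression still recovers most states at n = 4 vs 3", {
  toy <- make_toy_network(seed = 1)
  tr <- plant_condition_fluxes(toy, default_condition_effects(toy$layout))
  ex <- simulate_expression(toy$model, tr, noise_sd = 0.5, seed = 1)
  gs <- condition_gene_states(ex)
  hits <- total <- 0
  for (cd in tr$conditions) {
    rs <- reaction_states(gs[[cd]], toy$model)
    for (r in toy$model$reactions) {
      if (is.null(r$gpr_tree)) next
      want <- if (r$id %in% tr$active[[cd]]) "HIGH" else "LOW"
      hits <- hits + (rs$state_of[r$id] == want)
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("expression simulation is seed-deterministic", {
  toy <- make_toy_network(seed = 6)
  tr <- plant_condition_fluxes(toy, default_condition_effects(toy$layout))
  e1 <- simulate_expression(toy$model, tr, noise_sd = 0.5, seed = 3)
  e2 <- simulate_expression(toy$model, tr, noise_sd = 0.5, seed = 3)
  expect_identical(e1$values, e2$values)
  e3 <- simulate_expression(toy$model, tr, noise_sd = 0.5, seed = 4)
  expect_false(identical(e1$values, e3$values))
})

test_that("GSEA dataset generator plants disjoint shifted sets", {
  d <- simulate_gsea_dataset(n_genes = 300, n_sets = 6, set_size = 20,
                             planted_set_count = 2, effect_size = 2,
                             seed = 8)
  expect_length(d$sets, 6)
  allg <- unlist(lapply(d$sets, `[[`, "genes"))
  expect_equal(anyDuplicated(allg), 0)
  planted_genes <- unlist(lapply(d$sets[1:2], `[[`, "genes"))
  ko <- d$expr$values[, d$expr$condition_of == "KO"]
  wt <- d$expr$values[, d$expr$condition_of == "WT"]
  shift <- rowMeans(ko) - rowMeans(wt)
  expect_gt(mean(shift[planted_genes]), 1)
  expect_lt(abs(mean(shift[setdiff(rownames(ko), planted_genes)])), 0.2)
  expect_error(simulate_gsea_dataset(n_genes = 50, n_sets = 10,
                                     set_size = 20), "disjoint")
  d2 <- simulate_gsea_dataset(n_genes = 300, n_sets = 6, set_size = 20,
                              planted_set_count = 2, effect_size = 2,
                              seed = 8)
  expect_identical(d$expr$values, d2$expr$values)
})
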