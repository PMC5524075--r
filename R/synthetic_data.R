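#' Generate a toy metabolic network with labeled parallel pathways
#'
#' Builds `n_pathways` parallel linear pathways, each an uptake exchange
#' feeding a chain of `reactions_per_pathway` internal reactions that ends
#' in a shared hub metabolite drained by a single secretion exchange.
#' Every internal reaction carries a pathway label and a one- or two-gene
#' GPR (genes are reaction-specific); exchanges have no GPR. Optionally a
#' dead-end branch off the hub yields exactly one blocked reaction.
#'
#' @param n_pathways number of parallel pathways.
#' @param reactions_per_pathway internal reactions per pathway.
#' @param include_blocked_branch add a dead-end reaction off the hub.
#' @param reversible_fraction fraction of internal reactions made
#'   reversible (lower bound `-bound`).
#' @param bound flux capacity of pathway reactions.
#' @param seed RNG seed (GPR shapes and reversibility draws).
#' @return list with `model` (a `metabolic_model`) and `layout`
#'   (pathway -> reaction ids, hub/blocked reaction ids, gene map).
#' @export
make_toy_network <- function(n_pathways = 3, reactions_per_pathway = 3,
                             include_blocked_branch = TRUE,
                             reversible_fraction = 0.25, bound = 10,
                             seed = 1) {
  stopifnot(n_pathways * reactions_per_pathway >= 3)
  with_seed(seed, {
    mets <- list()
    rxns <- list()
    layout <- list(pathways = list(), hub_reactions = character(0),
                   blocked_reactions = character(0))
    add_met <- function(id) {
      mets[[length(mets) + 1L]] <<- data.frame(
        id = id, name = id, compartment = "c", stringsAsFactors = FALSE)
    }
    add_met("HUB")
    for (p in seq_len(n_pathways)) {
      pw <- paste0("P", p)
      ids <- character(0)
      chain_mets <- paste0("M_", pw, "_", seq_len(reactions_per_pathway))
      for (m in chain_mets) add_met(m)
      up_id <- paste0("EX_up_", pw)
      rxns[[up_id]] <- list(id = up_id,
                            stoich = setNames(1, chain_mets[1]),
                            lower_bound = 0, upper_bound = bound,
                            gpr = "", pathway = pw, is_exchange = TRUE)
      ids <- c(ids, up_id)
      for (j in seq_len(reactions_per_pathway)) {
        rid <- paste0("R_", pw, "_", j)
        to <- if (j < reactions_per_pathway) chain_mets[j + 1] else "HUB"
        rev <- runif(1) < reversible_fraction
        two <- runif(1) < 0.5
        g1 <- paste0("g", pw, "r", j, "a")
        gpr <- if (two) {
          op <- if (runif(1) < 0.5) " and " else " or "
          paste0(g1, op, paste0("g", pw, "r", j, "b"))
        } else g1
        rxns[[rid]] <- list(id = rid,
                            stoich = setNames(c(-1, 1), c(chain_mets[j], to)),
                            lower_bound = if (rev) -bound else 0,
                            upper_bound = bound,
                            gpr = gpr, pathway = pw, is_exchange = FALSE)
        ids <- c(ids, rid)
      }
      layout$pathways[[pw]] <- ids
    }
    hub_id <- "EX_hub"
    rxns[[hub_id]] <- list(id = hub_id, stoich = c(HUB = -1),
                           lower_bound = 0,
                           upper_bound = 2 * bound * n_pathways,
                           gpr = "", pathway = "", is_exchange = TRUE)
    layout$hub_reactions <- hub_id
    if (include_blocked_branch) {
      add_met("DEADEND")
      rxns[["R_blocked"]] <- list(id = "R_blocked",
                                  stoich = c(HUB = -1, DEADEND = 1),
                                  lower_bound = 0, upper_bound = bound,
                                  gpr = "gBLKa", pathway = "",
                                  is_exchange = FALSE)
      layout$blocked_reactions <- "R_blocked"
    }
    model <- metabolic_model(do.call(rbind, mets), rxns)
    list(model = model, layout = layout)
  })
}

#' Default two-condition effect map for a toy network
#'
#' Condition A switches the last pathway OFF; condition B switches the
#' second pathway OFF (the first pathway stays ON in both, giving planted
#' UNCHANGED reactions). Keeps the per-condition active-gene fraction
#' below the top-quartile capacity of the discretizer.
#'
#' @param layout the `layout` element of [make_toy_network()].
#' @param conditions two condition labels.
#' @return named list of per-condition pathway effect maps.
#' @export
default_condition_effects <- function(layout, conditions = c("WT", "KO")) {
  pw <- names(layout$pathways)
  P <- length(pw)
  eff_a <- setNames(as.list(rep("ON", P)), pw)
  eff_b <- eff_a
  eff_a[[pw[P]]] <- "OFF"
  eff_b[[pw[min(2, P)]]] <- "OFF"
  setNames(list(eff_a, eff_b), conditions)
}

#' Plant per-condition steady-state flux modes in a toy network
#'
#' For each condition, every ON pathway carries `base_flux` through its
#' uptake and chain (`SCALED x k`, given as a number, carries
#' `k * base_flux`), OFF pathways carry zero, and the hub secretion drains
#' the sum; mass balance holds exactly by construction. Planted directions
#' compare the two modes reaction by reaction.
#'
#' @param toy result of [make_toy_network()].
#' @param condition_effects named list (condition -> pathway -> "ON",
#'   "OFF" or a numeric scale factor), e.g.
#'   [default_condition_effects()].
#' @param base_flux flux carried by an ON pathway (>= epsilon).
#' @param epsilon activity threshold used to derive the active sets.
#' @return list of class `synthetic_truth`: `conditions`, `modes` (named
#'   flux vectors satisfying S v = 0 exactly), `active` (reaction sets),
#'   `planted_direction`, `hub_reactions`, `epsilon`.
#' @export
plant_condition_fluxes <- function(toy, condition_effects, base_flux = 5,
                                   epsilon = 1.0) {
  model <- toy$model
  layout <- toy$layout
  rids <- reaction_ids(model)
  conds <- names(condition_effects)
  stopifnot(length(conds) == 2)
  modes <- list()
  for (cd in conds) {
    eff <- condition_effects[[cd]]
    if (!all(names(eff) %in% names(layout$pathways))) {
      stop("plant_condition_fluxes: unknown pathway label in effects for ",
           cd)
    }
    v <- setNames(rep(0, length(rids)), rids)
    for (pw in names(eff)) {
      e <- eff[[pw]]
      f <- if (identical(e, "ON")) base_flux
           else if (identical(e, "OFF")) 0
           else if (is.numeric(e)) e * base_flux
           else stop("plant_condition_fluxes: bad effect '", e, "'")
      v[layout$pathways[[pw]]] <- f
    }
    v[layout$hub_reactions] <- sum(vapply(
      names(layout$pathways),
      function(pw) v[layout$pathways[[pw]]][1], numeric(1)))
    bnd <- model_bounds(model)
    if (any(v < bnd$lb - 1e-12 | v > bnd$ub + 1e-12)) {
      stop("plant_condition_fluxes: planted mode violates bounds in ", cd)
    }
    S <- stoichiometric_matrix(model)
    if (max(abs(S %*% v)) != 0) {
      stop("plant_condition_fluxes: planted mode is not mass balanced")
    }
    modes[[cd]] <- v
  }
  va <- modes[[1]]; vb <- modes[[2]]
  dir <- ifelse(vb > va, "UP", ifelse(vb < va, "DOWN", "UNCHANGED"))
  active <- lapply(modes, function(v) names(v)[abs(v) >= epsilon])
  structure(list(conditions = conds, modes = modes, active = active,
                 planted_direction = setNames(dir, rids),
                 hub_reactions = layout$hub_reactions,
                 blocked_reactions = layout$blocked_reactions,
                 epsilon = epsilon),
            class = "synthetic_truth")
}

#' Simulate an expression matrix encoding planted reaction activity
#'
#' Genes of reactions active in a condition draw from a high stratum,
#' genes of inactive reactions from a low stratum, and filler genes (twice
#' the model gene count, so quartile capacity exceeds the active-gene
#' count) from a middle stratum, on a log2-like scale. At `noise_sd = 0`
#' per-sample quartile discretization plus two-thirds aggregation
#' reproduces the planted states exactly.
#'
#' @param model a `metabolic_model`.
#' @param truth a `synthetic_truth` from [plant_condition_fluxes()].
#' @param n_samples samples per condition (recycled; default 4 and 3,
#'   mirroring a small two-group array design).
#' @param noise_sd Gaussian noise standard deviation.
#' @param strata low/mid/high stratum centers.
#' @param seed RNG seed.
#' @return an [expression_matrix()].
#' @export
simulate_expression <- function(model, truth, n_samples = c(4, 3),
                                noise_sd = 0.5,
                                strata = c(low = 2, mid = 5, high = 8),
                                seed = 1) {
  stopifnot(all(n_samples >= 1))
  n_samples <- rep(n_samples, length.out = length(truth$conditions))
  gene_rxns <- list()
  for (r in model$reactions) {
    for (g in gpr_genes(r$gpr_tree)) {
      gene_rxns[[g]] <- c(gene_rxns[[g]], r$id)
    }
  }
  genes <- model$genes
  fillers <- sprintf("filler_%03d", seq_len(2 * length(genes)))
  all_genes <- c(genes, fillers)
  with_seed(seed, {
    cols <- list()
    cond_of <- character(0)
    for (ci in seq_along(truth$conditions)) {
      cd <- truth$conditions[ci]
      act <- truth$active[[cd]]
      base <- c(
        vapply(genes, function(g) {
          if (any(gene_rxns[[g]] %in% act)) strata[["high"]]
          else strata[["low"]]
        }, numeric(1)),
        rep(strata[["mid"]], length(fillers))
      )
      for (s in seq_len(n_samples[ci])) {
        nm <- paste0(cd, "_s", s)
        cols[[nm]] <- base + rnorm(length(base), sd = noise_sd)
        cond_of[nm] <- cd
      }
    }
    vals <- do.call(cbind, cols)
    rownames(vals) <- all_genes
    expression_matrix(vals, cond_of)
  })
}

#' Simulate a two-condition GSEA dataset with planted gene sets
#'
#' Background genes are Normal(0, 1) in both conditions; the genes of the
#' first `planted_set_count` sets are shifted by `effect_size` in the
#' second condition. Sets are disjoint blocks of a random gene
#' permutation. Sample sizes default to 4 vs 3, the small two-group
#' design this null model is meant for.
#'
#' @param n_genes,n_sets,set_size universe dimensions.
#' @param planted_set_count number of sets receiving the shift.
#' @param effect_size shift (in SD units) added in condition B.
#' @param n_per_condition samples for conditions A and B.
#' @param condition_labels two condition labels.
#' @param seed RNG seed.
#' @return list with `expr` (an [expression_matrix()]), `sets`, `truth`
#'   (planted set names, effect size).
#' @export
simulate_gsea_dataset <- function(n_genes = 2000, n_sets = 50,
                                  set_size = 30, planted_set_count = 3,
                                  effect_size = 2,
                                  n_per_condition = c(4, 3),
                                  condition_labels = c("WT", "KO"),
                                  seed = 1) {
  if (n_sets * set_size > n_genes) {
    stop("simulate_gsea_dataset: disjoint sets need n_sets * set_size <= ",
         "n_genes")
  }
  stopifnot(planted_set_count <= n_sets, length(n_per_condition) == 2)
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    perm <- sample(genes)
    sets <- lapply(seq_len(n_sets), function(i) {
      list(name = sprintf("SET%03d", i), description = "synthetic",
           genes = perm[((i - 1) * set_size + 1):(i * set_size)])
    })
    planted <- vapply(sets[seq_len(planted_set_count)], `[[`,
                      character(1), "name")
    na <- n_per_condition[1]; nb <- n_per_condition[2]
    vals <- matrix(rnorm(n_genes * (na + nb)), n_genes, na + nb)
    rownames(vals) <- genes
    colnames(vals) <- c(paste0(condition_labels[1], "_s", seq_len(na)),
                        paste0(condition_labels[2], "_s", seq_len(nb)))
    shifted <- unlist(lapply(sets[seq_len(planted_set_count)], `[[`,
                             "genes"))
    if (planted_set_count > 0 && effect_size != 0) {
      bcols <- na + seq_len(nb)
      vals[shifted, bcols] <- vals[shifted, bcols] + effect_size
    }
    cond_of <- setNames(rep(condition_labels, c(na, nb)), colnames(vals))
    list(expr = expression_matrix(vals, cond_of), sets = sets,
         truth = list(planted = planted, effect_size = effect_size,
                      shifted_condition = condition_labels[2]))
  })
}

#' Write a synthetic truth object as JSON
#' @param truth a `synthetic_truth`.
#' @param path output file.
#' @return invisible path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(conditions = truth$conditions,
         modes = lapply(truth$modes, as.list),
         active = truth$active,
         planted_direction = as.list(truth$planted_direction),
         hub_reactions = truth$hub_reactions,
         epsilon = truth$epsilon),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
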