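#' Construct a metabolic model
#'
#' A `metabolic_model` holds an ordered metabolite table, an ordered reaction
#' list (stoichiometry, bounds, GPR rule, pathway label, exchange flag), the
#' gene set implied by the GPR rules and a pathway -> reaction map. Exchange
#' reactions are single-sided columns (`\\emptyset -> metabolite`) whose
#' bounds encode uptake/secretion; reversibility is encoded purely by a
#' negative lower bound.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions list of reaction lists, each with fields `id`,
#'   `stoich` (named numeric, negative = consumed), `lower_bound`,
#'   `upper_bound`, and optionally `gpr` (rule string, "" for none),
#'   `pathway` ("" for none) and `is_exchange`.
#' @param validate run structural validation and stop on hard errors.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, validate = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "compartment") %in% names(metabolites)))
  reactions <- lapply(reactions, function(r) {
    r$gpr <- if (is.null(r$gpr)) "" else r$gpr
    r$pathway <- if (is.null(r$pathway)) "" else r$pathway
    r$is_exchange <- isTRUE(r$is_exchange)
    r$stoich <- unlist(r$stoich)
    r$gpr_tree <- if (nzchar(r$gpr)) parse_gpr(r$gpr) else NULL
    r
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  genes <- sort(unique(unlist(lapply(reactions, function(r)
    if (is.null(r$gpr_tree)) character(0) else gpr_genes(r$gpr_tree)))))
  pathways <- split(
    names(reactions),
    vapply(reactions, `[[`, character(1), "pathway")
  )
  pathways <- pathways[nzchar(names(pathways))]
  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         genes = genes, pathways = pathways),
    class = "metabolic_model"
  )
  if (validate) {
    rep <- validate_model(m, check_blocked = FALSE)
    hard <- rep$issues[rep$issues$type %in%
                         c("duplicate_id", "unknown_metabolite",
                           "bound_violation", "empty_stoich"), ]
    if (nrow(hard) > 0) {
      stop("invalid model: ", paste(hard$message, collapse = "; "))
    }
  }
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites, %d reactions, %d genes, %d pathways\n",
              nrow(x$metabolites), length(x$reactions), length(x$genes),
              length(x$pathways)))
  invisible(x)
}

reaction_ids <- function(model) names(model$reactions)
metabolite_ids <- function(model) model$metabolites$id

#' Parse a gene-protein-reaction rule
#'
#' Grammar: identifiers combined with `and` / `or` (case-insensitive) and
#' parentheses; `and` binds tighter than `or`. Returns a tree of nodes
#' `list(op = "gene", gene = id)`, `list(op = "and", children = ...)`,
#' `list(op = "or", children = ...)`.
#'
#' @param rule_text e.g. `"(gA and gB) or gC"`.
#' @return GPR expression tree.
#' @export
parse_gpr <- function(rule_text) {
  stopifnot(is.character(rule_text), length(rule_text) == 1)
  toks <- regmatches(rule_text,
                     gregexpr("\\(|\\)|[^()[:space:]]+", rule_text))[[1]]
  if (length(toks) == 0) stop("GPR parse error: empty rule")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule")
    if (t == "(") {
      take()
      e <- parse_or()
      if (!identical(peek(), ")")) {
        stop("GPR parse error: unbalanced parentheses in '", rule_text, "'")
      }
      take()
      return(e)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or")) {
      stop("GPR parse error: unexpected token '", t, "' in '", rule_text, "'")
    }
    take()
    list(op = "gene", gene = t)
  }
  parse_and <- function() {
    kids <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      take()
      kids[[length(kids) + 1L]] <- parse_factor()
    }
    if (length(kids) == 1) kids[[1]] else list(op = "and", children = kids)
  }
  parse_or <- function() {
    kids <- list(parse_and())
    while (is_kw(peek(), "or")) {
      take()
      kids[[length(kids) + 1L]] <- parse_and()
    }
    if (length(kids) == 1) kids[[1]] else list(op = "or", children = kids)
  }
  e <- parse_or()
  if (!is.na(peek())) {
    stop("GPR parse error: trailing token '", peek(), "' in '", rule_text, "'")
  }
  e
}

#' Genes referenced by a GPR tree
#' @param tree a tree from [parse_gpr()].
#' @return character vector of gene ids.
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$op == "gene") return(tree$gene)
  unique(unlist(lapply(tree$children, gpr_genes)))
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense m x n matrix, metabolites in rows (model order), reactions
#'   in columns (model order); entry (i, j) is the coefficient of metabolite
#'   i in reaction j.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- metabolite_ids(model)
  rxns <- reaction_ids(model)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Validate a metabolic model
#'
#' Reports duplicate ids, references to undeclared metabolites, bound
#' violations (`lower_bound > upper_bound`), internal reactions with empty
#' stoichiometry, GPR genes absent from the model gene set, dangling
#' metabolites (appearing in no reaction), steady-state feasibility of the
#' zero-flux-excluded network, and (optionally) reactions blocked at steady
#' state (min and max flux both zero over `{S v = 0, bounds}`).
#'
#' @param model a `metabolic_model`.
#' @param check_blocked also run per-reaction min/max LPs to find blocked
#'   reactions (needs bounded fluxes).
#' @return list with `ok` (no issues), `issues` (data.frame type/id/message),
#'   `blocked` (reaction ids), `feasible` (steady state exists within bounds).
#' @export
validate_model <- function(model, check_blocked = TRUE) {
  issues <- data.frame(type = character(0), id = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  add <- function(type, id, msg) {
    issues[nrow(issues) + 1L, ] <<- list(type, id, msg)
  }
  mids <- metabolite_ids(model)
  if (anyDuplicated(mids)) {
    for (d in unique(mids[duplicated(mids)]))
      add("duplicate_id", d, paste0("duplicate metabolite id '", d, "'"))
  }
  rids <- reaction_ids(model)
  if (anyDuplicated(rids)) {
    for (d in unique(rids[duplicated(rids)]))
      add("duplicate_id", d, paste0("duplicate reaction id '", d, "'"))
  }
  used_mets <- character(0)
  for (r in model$reactions) {
    st <- r$stoich
    if (length(st) == 0 && !r$is_exchange) {
      add("empty_stoich", r$id,
          paste0("internal reaction '", r$id, "' has empty stoichiometry"))
    }
    unknown <- setdiff(names(st), mids)
    for (u in unknown) {
      add("unknown_metabolite", r$id,
          paste0("reaction '", r$id, "' references undeclared metabolite '",
                 u, "'"))
    }
    if (r$lower_bound > r$upper_bound) {
      add("bound_violation", r$id,
          paste0("reaction '", r$id, "' has lower_bound > upper_bound"))
    }
    missing_genes <- setdiff(gpr_genes(r$gpr_tree), model$genes)
    for (g in missing_genes) {
      add("unknown_gene", r$id,
          paste0("reaction '", r$id, "' GPR gene '", g,
                 "' absent from model gene set"))
    }
    used_mets <- union(used_mets, names(st))
  }
  for (d in setdiff(mids, used_mets)) {
    add("dangling_metabolite", d,
        paste0("metabolite '", d, "' appears in no reaction"))
  }

  feasible <- NA
  blocked <- character(0)
  structural_ok <- !any(issues$type %in%
                          c("duplicate_id", "unknown_metabolite",
                            "bound_violation"))
  if (structural_ok && length(model$reactions) > 0) {
    S <- stoichiometric_matrix(model)
    lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
    ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
    lb <- pmax(lb, -1e4); ub <- pmin(ub, 1e4)
    feas <- lp_feasible(S, rep(0, nrow(S)), lb, ub)
    feasible <- feas$feasible
    if (check_blocked && feasible) {
      for (j in seq_along(rids)) {
        e <- numeric(length(rids)); e[j] <- 1
        vmax <- lp_solve(e, A_eq = S, b_eq = rep(0, nrow(S)),
                         lb = lb, ub = ub, maximize = TRUE)
        vmin <- lp_solve(e, A_eq = S, b_eq = rep(0, nrow(S)),
                         lb = lb, ub = ub, maximize = FALSE)
        if (vmax$status == "optimal" && vmin$status == "optimal" &&
            abs(vmax$obj) < 1e-9 && abs(vmin$obj) < 1e-9) {
          blocked <- c(blocked, rids[j])
        }
      }
      for (bid in blocked) {
        add("blocked_reaction", bid,
            paste0("reaction '", bid, "' is blocked at steady state"))
      }
    }
  }
  list(ok = nrow(issues) == 0, issues = issues, blocked = blocked,
       feasible = feasible)
}

# bounds vectors with infinities replaced by +/- default_bound
model_bounds <- function(model, default_bound = 1000) {
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  lb[!is.finite(lb)] <- -default_bound
  ub[!is.finite(ub)] <- default_bound
  lb <- pmax(lb, -default_bound)
  ub <- pmin(ub, default_bound)
  list(lb = setNames(lb, reaction_ids(model)),
       ub = setNames(ub, reaction_ids(model)))
}
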