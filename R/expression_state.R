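TRILEVEL <- c("LOW", "MODERATE", "HIGH")
.state_ord <- c(LOW = 1L, MODERATE = 2L, HIGH = 3L)

#' Construct an expression matrix with a condition map
#'
#' @param values numeric genes x samples matrix with row and column names;
#'   normalized intensities, no missing values.
#' @param condition_of named character vector mapping each sample (column)
#'   to a condition label.
#' @return object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, condition_of) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)),
            !anyNA(values))
  if (!all(colnames(values) %in% names(condition_of))) {
    stop("condition_of must cover every sample column")
  }
  condition_of <- condition_of[colnames(values)]
  structure(list(values = values, condition_of = condition_of),
            class = "expr_matrix")
}

#' Read an expression TSV and condition map TSV
#'
#' The expression table has gene ids in the first column and one column per
#' sample; the condition map has columns `sample`, `condition`.
#'
#' @param path expression TSV.
#' @param condition_path condition map TSV.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, condition_path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  cm <- utils::read.delim(condition_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(cm))) {
    stop("condition map must have columns 'sample' and 'condition'")
  }
  expression_matrix(vals, setNames(cm$condition, cm$sample))
}

#' Trilevel discretization of one sample
#'
#' Genes in the top quartile by value (count `floor(0.25 * G)`) are HIGH,
#' the bottom quartile LOW, the remainder MODERATE. Ties at a quartile
#' boundary resolve toward MODERATE: a gene enters HIGH only if its value
#' strictly exceeds the first excluded rank's value (symmetrically for LOW),
#' so an all-equal sample is entirely MODERATE.
#'
#' @param column named numeric vector, one value per gene (>= 4 genes).
#' @return named character vector of `"LOW"`, `"MODERATE"`, `"HIGH"`.
#' @export
discretize_sample <- function(column) {
  g <- length(column)
  if (g < 4) stop("discretize_sample: quartiles undefined for < 4 genes")
  stopifnot(!is.null(names(column)), !anyNA(column))
  k <- floor(0.25 * g)
  desc <- sort(column, decreasing = TRUE)
  asc <- sort(column, decreasing = FALSE)
  hi_cut <- desc[k + 1]   # first excluded value from the top
  lo_cut <- asc[k + 1]    # first excluded value from the bottom
  out <- rep("MODERATE", g)
  names(out) <- names(column)
  out[column > hi_cut] <- "HIGH"
  out[column < lo_cut] <- "LOW"
  out
}

#' Aggregate per-sample states into one condition state
#'
#' A gene is HIGH for the condition iff it is HIGH in at least
#' `ceiling(fraction * n_samples)` samples ("at least two-thirds" by
#' default, so 3 of 4 samples are required at n = 4); LOW analogously;
#' otherwise MODERATE.
#'
#' @param sample_states genes x samples character matrix of trilevel states
#'   (or a list of named state vectors from [discretize_sample()]).
#' @param condition condition label to record.
#' @param fraction agreement fraction in (0, 1].
#' @return list with `condition` and `state_of` (named character vector).
#' @export
aggregate_condition <- function(sample_states, condition = "condition",
                                fraction = 2 / 3) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.list(sample_states)) {
    sample_states <- do.call(cbind, sample_states)
  }
  sample_states <- as.matrix(sample_states)
  n <- ncol(sample_states)
  stopifnot(n >= 1)
  thr <- ceiling(fraction * n)
  n_hi <- rowSums(sample_states == "HIGH")
  n_lo <- rowSums(sample_states == "LOW")
  st <- rep("MODERATE", nrow(sample_states))
  st[n_hi >= thr] <- "HIGH"
  st[n_lo >= thr] <- "LOW"
  st[n_hi >= thr & n_lo >= thr] <- "MODERATE"  # unreachable for fraction > 1/2
  list(condition = condition,
       state_of = setNames(st, rownames(sample_states)))
}

#' Discretize and aggregate a full expression matrix
#'
#' Runs [discretize_sample()] on every column and [aggregate_condition()]
#' per condition.
#'
#' @param expr an [expression_matrix()].
#' @param fraction agreement fraction, see [aggregate_condition()].
#' @return named list of condition gene states.
#' @export
condition_gene_states <- function(expr, fraction = 2 / 3) {
  states <- vapply(colnames(expr$values),
                   function(s) discretize_sample(expr$values[, s]),
                   character(nrow(expr$values)))
  rownames(states) <- rownames(expr$values)
  conds <- unique(unname(expr$condition_of))
  out <- lapply(conds, function(cd) {
    cols <- names(expr$condition_of)[expr$condition_of == cd]
    aggregate_condition(states[, cols, drop = FALSE], condition = cd,
                        fraction = fraction)
  })
  setNames(out, conds)
}

# evaluate a GPR tree over trilevel gene states: AND = min, OR = max
eval_gpr_state <- function(tree, ord_of) {
  if (tree$op == "gene") {
    v <- ord_of[tree$gene]
    return(if (is.na(v)) 2L else unname(v))
  }
  vals <- vapply(tree$children, eval_gpr_state, integer(1), ord_of = ord_of)
  if (tree$op == "and") min(vals) else max(vals)
}

#' Map condition gene states onto reactions through GPR logic
#'
#' GPR trees are evaluated under the ordering LOW < MODERATE < HIGH with
#' AND = minimum (a complex is limited by its scarcest subunit) and
#' OR = maximum (any isozyme suffices). Reactions without a GPR, and genes
#' missing from the state map, are MODERATE (no iMAT preference); missing
#' genes are reported in a warning once.
#'
#' @param gene_states a condition gene state (list with `condition`,
#'   `state_of`) from [aggregate_condition()].
#' @param model a `metabolic_model`.
#' @return list with `condition` and `state_of` over all reactions.
#' @export
reaction_states <- function(gene_states, model) {
  ord_of <- .state_ord[gene_states$state_of]
  names(ord_of) <- names(gene_states$state_of)
  missing <- setdiff(model$genes, names(ord_of))
  if (length(missing) > 0) {
    warning("reaction_states: ", length(missing),
            " model gene(s) absent from expression; treated as MODERATE (",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "", ")")
  }
  st <- vapply(model$reactions, function(r) {
    if (is.null(r$gpr_tree)) return("MODERATE")
    TRILEVEL[eval_gpr_state(r$gpr_tree, ord_of)]
  }, character(1))
  list(condition = gene_states$condition, state_of = st)
}
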