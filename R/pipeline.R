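#' Default pipeline configuration
#'
#' @param model path to the model file.
#' @param expression path to the expression TSV.
#' @param conditions path to the condition map TSV.
#' @param out_dir output directory (created if missing).
#' @param ... overrides for the remaining fields: `model_format`,
#'   `model_sidecar`, `gmt`, `condition_a`, `condition_b`, `epsilon`,
#'   `default_bound`, `fraction`, `n_samples`, `burn_in`, `thin`, `tol`,
#'   `n_perm`, `weight`, `seed`.
#' @return named list of effective configuration values.
#' @export
pipeline_config <- function(model, expression, conditions, out_dir, ...) {
  cfg <- list(model = model, expression = expression,
              conditions = conditions, out_dir = out_dir,
              model_format = NULL, model_sidecar = NULL, gmt = NULL,
              condition_a = NULL, condition_b = NULL,
              epsilon = 1.0, default_bound = 1000, fraction = 2 / 3,
              n_samples = 2000, burn_in = 1000, thin = 10, tol = 0.05,
              n_perm = 1000, weight = 1, seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("pipeline_config: unknown field(s) ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Read a pipeline configuration file (JSON, or YAML when available)
#' @param path config file.
#' @return configuration list as for [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config needs the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config,
          c(raw[c("model", "expression", "conditions", "out_dir")],
            raw[setdiff(names(raw),
                        c("model", "expression", "conditions", "out_dir"))]))
}

#' Run the full transcriptome-to-flux pipeline
#'
#' Executes discretize -> aggregate -> reaction states -> iMAT -> FVA at
#' maximal agreement -> flux sampling (per condition) -> median direction
#' calls -> hypergeometric pathway enrichment, and optionally
#' signal-to-noise ranking -> GSEA when a GMT file is configured. Each
#' stage's outputs are written (as TSV/JSON under `out_dir`) before the
#' next stage begins; a stage failure halts the run with the stage named,
#' retaining earlier outputs.
#'
#' @param config a list from [pipeline_config()] / [read_config()], or a
#'   path to a config file.
#' @return run report (list of class `run_report`): per-stage status and
#'   wall-clock seconds, input hashes, output files, effective config.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  for (f in c("model", "expression", "conditions")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
      stop("run_pipeline: config validation failed - missing input '", f,
           "'", if (!is.null(cfg[[f]])) paste0(" (", cfg[[f]], ")"))
    }
  }
  if (!is.null(cfg$gmt) && !file.exists(cfg$gmt)) {
    stop("run_pipeline: config validation failed - missing input 'gmt'")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, paste0(...))

  stages <- data.frame(stage = character(0), status = character(0),
                       seconds = numeric(0), stringsAsFactors = FALSE)
  outputs <- character(0)
  env <- new.env(parent = emptyenv())
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    ok <- !inherits(res, "error")
    stages[nrow(stages) + 1L, ] <<- list(name, if (ok) "ok" else "failed", dt)
    if (!ok) {
      report <- finish_report()
      stop("run_pipeline: stage '", name, "' failed: ",
           conditionMessage(res), call. = FALSE)
    }
    res
  }
  finish_report <- function() {
    report <- structure(
      list(stages = stages,
           inputs = as.list(tools::md5sum(
             unlist(cfg[c("model", "expression", "conditions", "gmt")],
                    use.names = FALSE))),
           outputs = outputs, config = cfg),
      class = "run_report")
    jsonlite::write_json(
      list(stages = stages, inputs = report$inputs, outputs = outputs,
           config = cfg[!vapply(cfg, is.null, logical(1))]),
      out("run_report.json"), auto_unbox = TRUE, digits = NA)
    report
  }
  emit <- function(path) outputs <<- c(outputs, path)

  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       out("effective_config.json"),
                       auto_unbox = TRUE, digits = NA)

  run_stage("load_inputs", function() {
    env$model <- read_model(cfg$model,
                            format = cfg$model_format %||%
                              c("json", "tsv", "sbml"),
                            sidecar = cfg$model_sidecar)
    env$expr <- read_expression(cfg$expression, cfg$conditions)
    conds <- unique(unname(env$expr$condition_of))
    env$cond_a <- cfg$condition_a %||% conds[1]
    env$cond_b <- cfg$condition_b %||% conds[2]
    stopifnot(length(conds) >= 2)
  })

  run_stage("discretize_aggregate", function() {
    env$gene_states <- condition_gene_states(env$expr, cfg$fraction)
    df <- do.call(rbind, lapply(env$gene_states, function(gs) {
      data.frame(gene = names(gs$state_of), condition = gs$condition,
                 state = unname(gs$state_of), stringsAsFactors = FALSE)
    }))
    utils::write.table(df, out("gene_states.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(out("gene_states.tsv"))
  })

  run_stage("reaction_states", function() {
    env$rstates <- lapply(env$gene_states[c(env$cond_a, env$cond_b)],
                          reaction_states, model = env$model)
    df <- do.call(rbind, lapply(env$rstates, function(rs) {
      data.frame(reaction = names(rs$state_of), condition = rs$condition,
                 state = unname(rs$state_of), stringsAsFactors = FALSE)
    }))
    utils::write.table(df, out("reaction_states.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(out("reaction_states.tsv"))
  })

  icfg <- imat_config(epsilon = cfg$epsilon,
                      default_bound = cfg$default_bound)
  env$fva <- list()
  env$samples <- list()
  for (cd in c("a", "b")) {
    local({
      cdl <- if (cd == "a") env$cond_a else env$cond_b
      idx <- if (cd == "a") 1L else 2L
      run_stage(paste0("imat_", cdl), function() {
        env[[paste0("imat_", cd)]] <-
          solve_imat(env$model, env$rstates[[cdl]], icfg)
        write_imat_solution(env[[paste0("imat_", cd)]], env$rstates[[cdl]],
                            out("imat_", cdl, ".tsv"),
                            out("imat_", cdl, ".json"))
        emit(out("imat_", cdl, ".tsv")); emit(out("imat_", cdl, ".json"))
      })
      run_stage(paste0("fva_", cdl), function() {
        env$fva[[cdl]] <- fva_at_max_agreement(
          env$model, env$rstates[[cdl]], icfg,
          imat_solution = env[[paste0("imat_", cd)]])
        write_fva(env$fva[[cdl]], out("fva_", cdl, ".tsv"))
        emit(out("fva_", cdl, ".tsv"))
      })
      run_stage(paste0("sample_", cdl), function() {
        env$samples[[cdl]] <- sample_flux_space(
          env$model, env$fva[[cdl]], n_samples = cfg$n_samples,
          seed = cfg$seed + idx, burn_in = cfg$burn_in, thin = cfg$thin)
        write_samples(env$samples[[cdl]], out("samples_", cdl, ".tsv"),
                      out("samples_", cdl, ".json"))
        emit(out("samples_", cdl, ".tsv.gz"))
      })
    })
  }

  run_stage("direction_calls", function() {
    env$dirs <- median_direction_calls(env$samples[[env$cond_a]],
                                       env$samples[[env$cond_b]],
                                       tol = cfg$tol)
    utils::write.table(env$dirs, out("directions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(out("directions.tsv"))
  })

  run_stage("pathway_enrichment", function() {
    env$enrich <- enrich_pathways(env$dirs, env$model)
    utils::write.table(env$enrich, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(out("enrichment.tsv"))
  })

  if (!is.null(cfg$gmt)) {
    run_stage("gsea", function() {
      sets <- read_gmt(cfg$gmt)
      env$gsea <- run_gsea(env$expr, sets, condition_a = env$cond_a,
                           condition_b = env$cond_b, n_perm = cfg$n_perm,
                           weight = cfg$weight, seed = cfg$seed)
      utils::write.table(env$gsea, out("gsea.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(out("gsea.tsv"))
    })
  }

  report <- finish_report()
  report$results <- list(directions = env$dirs, enrichment = env$enrich,
                         gsea = env$gsea, fva = env$fva,
                         agreement = lapply(env$fva, `[[`,
                                            "agreement_fixed"))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
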