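#' Read a metabolic model
#'
#' Supported formats: the package's JSON dialect (canonical, round-trips
#' with [write_model()]), a TSV edge list with a reaction sidecar table,
#' and SBML Level 3 with the FBC extension (read-only).
#'
#' The JSON dialect is an object with `metabolites` (id, name, compartment)
#' and `reactions` (id, stoich map, lower_bound, upper_bound, gpr, pathway,
#' is_exchange). The TSV edge list has columns `reaction_id, metabolite_id,
#' coefficient`; its sidecar (columns `reaction_id, lower_bound, upper_bound,
#' gpr, pathway, is_exchange` plus a metabolite table `metabolite_id, name,
#' compartment`) is passed as `sidecar`.
#'
#' @param path model file.
#' @param format one of `"json"`, `"tsv"`, `"sbml"`; default guessed from
#'   the file extension.
#' @param sidecar reaction sidecar TSV (required for `format = "tsv"`).
#' @return a validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("json", "tsv", "sbml"),
                       sidecar = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  if (length(format) > 1) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml"
              else if (ext == "tsv") "tsv" else "json"
  }
  format <- match.arg(format, c("json", "tsv", "sbml"))
  switch(format,
         json = read_model_json(path),
         tsv = read_model_tsv(path, sidecar),
         sbml = read_model_sbml(path))
}

read_model_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                  error = function(e) {
                    stop("model format error in '", path, "': ",
                         conditionMessage(e))
                  })
  if (is.null(obj$metabolites) || is.null(obj$reactions)) {
    stop("model format error in '", path,
         "': missing 'metabolites' or 'reactions'")
  }
  mets <- do.call(rbind, lapply(obj$metabolites, function(m) {
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "" else m$compartment,
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(obj$reactions, function(r) {
    list(id = r$id, stoich = unlist(r$stoich),
         lower_bound = as.numeric(r$lower_bound),
         upper_bound = as.numeric(r$upper_bound),
         gpr = if (is.null(r$gpr)) "" else r$gpr,
         pathway = if (is.null(r$pathway)) "" else r$pathway,
         is_exchange = isTRUE(r$is_exchange))
  })
  check_unique_ids(mets, rxns, path)
  metabolic_model(mets, rxns)
}

check_unique_ids <- function(mets, rxns, path) {
  rids <- vapply(rxns, `[[`, character(1), "id")
  if (anyDuplicated(mets$id)) {
    stop("validation error in '", path, "': duplicate metabolite id '",
         mets$id[duplicated(mets$id)][1], "'")
  }
  if (anyDuplicated(rids)) {
    stop("validation error in '", path, "': duplicate reaction id '",
         rids[duplicated(rids)][1], "'")
  }
}

#' Write a metabolic model in the JSON dialect
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      as.list(model$metabolites[i, c("id", "name", "compartment")])
    }),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, stoich = as.list(r$stoich),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gpr = r$gpr, pathway = r$pathway, is_exchange = r$is_exchange)
    })
  )
  names(obj$reactions) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_model_tsv <- function(path, sidecar) {
  if (is.null(sidecar)) {
    stop("format = 'tsv' needs a reaction `sidecar` table path")
  }
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "metabolite_id", "coefficient")
  if (!all(need %in% names(edges))) {
    stop("model format error in '", path, "': expected columns ",
         paste(need, collapse = ", "))
  }
  side <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
  need2 <- c("reaction_id", "lower_bound", "upper_bound")
  if (!all(need2 %in% names(side))) {
    stop("model format error in '", sidecar, "': expected columns ",
         paste(need2, collapse = ", "))
  }
  if (is.null(side$gpr)) side$gpr <- ""
  if (is.null(side$pathway)) side$pathway <- ""
  if (is.null(side$is_exchange)) side$is_exchange <- FALSE
  side$gpr[is.na(side$gpr)] <- ""
  side$pathway[is.na(side$pathway)] <- ""
  met_ids <- unique(edges$metabolite_id)
  mets <- data.frame(id = met_ids, name = met_ids, compartment = "",
                     stringsAsFactors = FALSE)
  rxns <- lapply(seq_len(nrow(side)), function(i) {
    rid <- side$reaction_id[i]
    e <- edges[edges$reaction_id == rid, ]
    list(id = rid, stoich = setNames(e$coefficient, e$metabolite_id),
         lower_bound = side$lower_bound[i], upper_bound = side$upper_bound[i],
         gpr = side$gpr[i], pathway = side$pathway[i],
         is_exchange = as.logical(side$is_exchange[i]))
  })
  check_unique_ids(mets, rxns, path)
  metabolic_model(mets, rxns)
}

# SBML Level 3 + FBC, read-only. Bounds come from fbc:lowerFluxBound /
# fbc:upperFluxBound parameter references; GPRs from
# fbc:geneProductAssociation trees of fbc:and / fbc:or / fbc:geneProductRef.
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("model format error in '", path, "': ", conditionMessage(e))
  })
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))
  gp <- xml2::xml_find_all(
    doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id")[!boundary],
    name = ifelse(is.na(xml2::xml_attr(sp, "name")[!boundary]),
                  xml2::xml_attr(sp, "id")[!boundary],
                  xml2::xml_attr(sp, "name")[!boundary]),
    compartment = xml2::xml_attr(sp, "compartment")[!boundary],
    stringsAsFactors = FALSE
  )

  gpa_to_rule <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lbl <- gp_label[ref]
      return(if (is.na(lbl)) ref else unname(lbl))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_rule, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx, function(node) {
    rid <- xml2::xml_attr(node, "id")
    reac <- xml2::xml_find_all(
      node, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(
      node, "./s:listOfProducts/s:speciesReference", ns)
    co <- function(refs, sign) {
      sp_id <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      setNames(sign * st, sp_id)
    }
    st <- c(co(reac, -1), co(prod, +1))
    st <- st[names(st) %in% mets$id]  # drop boundary species
    lb_id <- xml2::xml_attr(node, "lowerFluxBound")
    ub_id <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lb_id) && lb_id %in% names(pval)) pval[[lb_id]] else -Inf
    ub <- if (!is.na(ub_id) && ub_id %in% names(pval)) pval[[ub_id]] else Inf
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gpr <- ""
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids) > 0) gpr <- gpa_to_rule(kids[[1]])
    }
    list(id = rid, stoich = st, lower_bound = lb, upper_bound = ub,
         gpr = gpr, pathway = "",
         is_exchange = length(st) <= 1 || grepl("^EX_", rid))
  })
  check_unique_ids(mets, rxns, path)
  metabolic_model(mets, rxns)
}
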