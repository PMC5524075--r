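test_that("JSON toy model parses, validates and round-trips", {
  m <- chain3_model()
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path, format = "json")
  expect_equal(nrow(m2$metabolites), 2)
  expect_length(m2$reactions, 3)
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(m2$genes, m$genes)
  expect_equal(m2$pathways, m$pathways)
  for (rid in names(m$reactions)) {
    expect_equal(m2$reactions[[rid]][c("id", "stoich", "lower_bound",
                                       "upper_bound", "gpr", "pathway",
                                       "is_exchange")],
                 m$reactions[[rid]][c("id", "stoich", "lower_bound",
                                      "upper_bound", "gpr", "pathway",
                                      "is_exchange")])
  }
  # writing the re-read model reproduces the file byte for byte
  path2 <- tempfile(fileext = ".json")
  write_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("model reading rejects malformed input", {
  m <- chain3_model()
  path <- tempfile(fileext = ".json")
  obj <- jsonlite::fromJSON(readLines(path_w <- {write_model(m, path); path}),
                            simplifyDataFrame = FALSE)
  obj$reactions[[2]]$stoich <- list(A = -1, GHOST = 1)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, auto_unbox = TRUE)
  expect_error(read_model(bad), "undeclared metabolite")

  obj2 <- jsonlite::fromJSON(readLines(path), simplifyDataFrame = FALSE)
  obj2$reactions[[3]]$id <- "EX_A"
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj2, bad2, auto_unbox = TRUE)
  expect_error(read_model(bad2), "duplicate reaction id")

  notjson <- tempfile(fileext = ".json")
  writeLines("{ not json", notjson)
  expect_error(read_model(notjson), "format error")
})

test_that("TSV edge-list format reads with its sidecar", {
  edges <- tempfile(fileext = ".tsv")
  side <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tmetabolite_id\tcoefficient",
               "EX_A\tA\t1", "R1\tA\t-1", "R1\tB\t1", "EX_B\tB\t-1"),
             edges)
  writeLines(c("reaction_id\tlower_bound\tupper_bound\tgpr\tpathway\tis_exchange",
               "EX_A\t0\t10\t\t\tTRUE",
               "R1\t-5\t10\tgA or gB\tcore\tFALSE",
               "EX_B\t0\t10\t\t\tTRUE"), side)
  m <- read_model(edges, format = "tsv", sidecar = side)
  expect_equal(m$reactions$R1$lower_bound, -5)
  expect_equal(sort(m$genes), c("gA", "gB"))
  expect_equal(m$pathways$core, "R1")
  expect_equal(unname(stoichiometric_matrix(m)[, "R1"]), c(-1, 1))
})

test_that("SBML L3 FBC bounds and GPRs are honoured", {
  m <- read_model(minimal_sbml(), format = "sbml")
  expect_length(m$reactions, 3)
  expect_equal(m$reactions$EX_A$upper_bound, 12.5)
  expect_equal(m$reactions$R1$lower_bound, -12.5)
  expect_equal(m$reactions$R1$gpr_tree$op, "and")
  expect_setequal(gpr_genes(m$reactions$R1$gpr_tree), c("gA", "gB"))
  expect_equal(unname(stoichiometric_matrix(m)["A", ]), c(1, -1, 0))
})

test_that("parse_gpr honours precedence and rejects bad rules", {
  expect_equal(parse_gpr("gA"), list(op = "gene", gene = "gA"))
  t1 <- parse_gpr("gA and gB or gC")   # and binds tighter
  expect_equal(t1$op, "or")
  expect_equal(t1$children[[1]]$op, "and")
  expect_equal(t1$children[[2]]$gene, "gC")
  t2 <- parse_gpr("gA and (gB or gC)")
  expect_equal(t2$op, "and")
  expect_equal(t2$children[[2]]$op, "or")
  expect_error(parse_gpr("gA and (gB"), "unbalanced")
  expect_error(parse_gpr("gA and"), "unexpected end")
  expect_error(parse_gpr("and gA"), "unexpected token")
  expect_error(parse_gpr(""), "empty")
})

test_that("stoichiometric matrix follows model order and conventions", {
  m <- chain3_model()
  S <- stoichiometric_matrix(m)
  expect_equal(colnames(S), c("EX_A", "R1", "EX_B"))
  expect_equal(unname(S[, "R1"]), c(-1, 1))
  expect_equal(unname(S[, "EX_A"]), c(1, 0))  # exchange: 0 -> A
  # nonzero count equals the sum of stoichiometry sizes
  expect_equal(sum(S != 0),
               sum(vapply(m$reactions, function(r) length(r$stoich),
                          integer(1))))
  empty <- metabolic_model(
    data.frame(id = character(0), name = character(0),
               compartment = character(0)), list())
  expect_equal(dim(stoichiometric_matrix(empty)), c(0, 0))
})

test_that("validate_model reports issues and blocked reactions", {
  ok <- validate_model(chain3_model())
  expect_true(ok$ok)
  expect_true(ok$feasible)
  expect_length(ok$blocked, 0)

  # producer with no consumer: RD is blocked at steady state
  v <- validate_model(deadend_model())
  expect_equal(v$blocked, "RD")
  expect_true("blocked_reaction" %in% v$issues$type)

  bad <- metabolic_model(
    data.frame(id = "A", name = "A", compartment = "c"),
    list(list(id = "EX_A", stoich = c(A = 1), lower_bound = 5,
              upper_bound = 1, is_exchange = TRUE)),
    validate = FALSE)
  vb <- validate_model(bad)
  expect_true("bound_violation" %in% vb$issues$type)
})
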