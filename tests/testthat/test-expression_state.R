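test_that("per-sample discretization yields rank quartiles", {
  v <- setNames(1:8, paste0("g", 1:8))
  st <- discretize_sample(v)
  expect_setequal(names(st)[st == "HIGH"], c("g7", "g8"))
  expect_setequal(names(st)[st == "LOW"], c("g1", "g2"))
  expect_equal(sum(st == "MODERATE"), 4)

  st4 <- discretize_sample(setNames(c(10, 20, 30, 40), paste0("g", 1:4)))
  expect_equal(names(st4)[st4 == "HIGH"], "g4")
  expect_equal(names(st4)[st4 == "LOW"], "g1")

  same <- discretize_sample(setNames(rep(7, 8), paste0("g", 1:8)))
  expect_true(all(same == "MODERATE"))

  expect_error(discretize_sample(setNames(1:3, paste0("g", 1:3))),
               "quartiles undefined")
})

test_that("quartile counts are exact for distinct values (property)", {
  for (seed in 1:5) {
    for (g in c(4, 7, 10, 23, 100)) {
      v <- fluxcond:::with_seed(seed, setNames(sample(g * 10, g),
                                               paste0("g", seq_len(g))))
      st <- discretize_sample(v)
      expect_equal(sum(st == "HIGH"), floor(0.25 * g))
      expect_equal(sum(st == "LOW"), floor(0.25 * g))
    }
  }
})

test_that("two-thirds aggregation uses a ceiling threshold", {
  mk <- function(...) {
    m <- cbind(...)
    rownames(m) <- "g1"
    m
  }
  # 3 samples, HIGH in 2 -> HIGH (the paper's two-thirds rule)
  expect_equal(unname(aggregate_condition(
    mk("HIGH", "HIGH", "MODERATE"))$state_of), "HIGH")
  # conflicting calls -> MODERATE
  expect_equal(unname(aggregate_condition(
    mk("HIGH", "LOW", "MODERATE"))$state_of), "MODERATE")
  # n = 4: ceiling(8/3) = 3 agreeing samples required
  expect_equal(unname(aggregate_condition(
    mk("LOW", "LOW", "LOW", "HIGH"))$state_of), "LOW")
  expect_equal(unname(aggregate_condition(
    mk("LOW", "LOW", "MODERATE", "HIGH"))$state_of), "MODERATE")
  # single sample: aggregation is the identity
  for (s in c("LOW", "MODERATE", "HIGH")) {
    expect_equal(unname(aggregate_condition(mk(s))$state_of), s)
  }
})

test_that("GPR evaluation maps gene states to reaction states", {
  m <- metabolic_model(
    data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    list(list(id = "EX_A", stoich = c(A = 1), lower_bound = 0,
              upper_bound = 10, is_exchange = TRUE),
         list(id = "R_and", stoich = c(A = -1, B = 1), lower_bound = 0,
              upper_bound = 10, gpr = "gA and gB"),
         list(id = "R_or", stoich = c(A = -1, B = 1), lower_bound = 0,
              upper_bound = 10, gpr = "gA or gB"),
         list(id = "EX_B", stoich = c(B = -1), lower_bound = 0,
              upper_bound = 10, is_exchange = TRUE)))
  gs <- list(condition = "c1", state_of = c(gA = "HIGH", gB = "LOW"))
  rs <- reaction_states(gs, m)
  expect_equal(unname(rs$state_of["R_and"]), "LOW")    # AND -> min
  expect_equal(unname(rs$state_of["R_or"]), "HIGH")    # OR -> max
  expect_equal(unname(rs$state_of["EX_A"]), "MODERATE")  # empty GPR

  gs2 <- list(condition = "c1", state_of = c(gA = "MODERATE", gB = "HIGH"))
  expect_equal(unname(reaction_states(gs2, m)$state_of["R_or"]), "HIGH")

  # missing model gene defaults to MODERATE with a warning
  gs3 <- list(condition = "c1", state_of = c(gA = "HIGH"))
  expect_warning(rs3 <- reaction_states(gs3, m), "absent from expression")
  expect_equal(unname(rs3$state_of["R_and"]), "MODERATE")
})

test_that("reaction states are monotone in gene states (property)", {
  m <- metabolic_model(
    data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    list(list(id = "R1", stoich = c(A = -1, B = 1), lower_bound = 0,
              upper_bound = 10, gpr = "(gA and gB) or (gC and gD)"),
         list(id = "EX_A", stoich = c(A = 1), lower_bound = 0,
              upper_bound = 10, is_exchange = TRUE),
         list(id = "EX_B", stoich = c(B = -1), lower_bound = 0,
              upper_bound = 10, is_exchange = TRUE)))
  ord <- fluxcond:::.state_ord
  genes <- c("gA", "gB", "gC", "gD")
  for (seed in 1:20) {
    st <- fluxcond:::with_seed(seed, setNames(
      sample(c("LOW", "MODERATE", "HIGH"), 4, replace = TRUE), genes))
    base <- reaction_states(list(condition = "x", state_of = st), m)
    g <- fluxcond:::with_seed(seed + 100, sample(genes, 1))
    if (st[[g]] == "HIGH") next
    st2 <- st
    st2[[g]] <- if (st[[g]] == "LOW") "MODERATE" else "HIGH"
    up <- reaction_states(list(condition = "x", state_of = st2), m)
    expect_true(all(ord[up$state_of] >= ord[base$state_of]))
  }
})

test_that("expression TSV and condition map round-trip", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2,
                 dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  ep <- tempfile(fileext = ".tsv")
  cp <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = rownames(vals), vals),
                     ep, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = c("s1", "s2"),
                                condition = c("WT", "KO")),
                     cp, sep = "\t", quote = FALSE, row.names = FALSE)
  ex <- read_expression(ep, cp)
  expect_equal(unname(ex$values[, "s2"]), c(5, 6, 7, 8))
  expect_equal(unname(ex$condition_of["s2"]), "KO")
})
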