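test_that("reaction and metabolite invariants are enforced", {
  expect_error(reaction("r", c(A = 1), c(A = 1)), "both sides")
  expect_error(reaction("r", c(A = -1), c(B = 1)), "strictly positive")
  expect_error(metabolite("m", carbon = -1))
  m <- metabolite("glc", "glucose", carbon = 6)
  expect_equal(m$carbon, 6)
})

test_that("roles are derived from exchange topology and ordering is deterministic", {
  m <- chain_model()
  expect_equal(m$metabolites$role, c("input", "pivot", "output"))
  expect_equal(m$metabolites$id, c("I", "P", "O"))
  ## a metabolite never produced nor consumed has no derivable role
  expect_error(
    metabolic_model(list(metabolite("A"), metabolite("Z")),
                    list(reaction("EX_A", products = c(A = 1)),
                         reaction("S_A", c(A = 1)))),
    "Z")
})

test_that("component balance report flags exactly the unbalanced reactions", {
  ## carbon-conserving split: A(6) -> B(5) + CO2(1)
  ok <- metabolic_model(
    list(metabolite("A", carbon = 6), metabolite("B", carbon = 5),
         metabolite("CO2", carbon = 1)),
    list(reaction("EX_A", products = c(A = 1)),
         reaction("R1", c(A = 1), c(B = 1, CO2 = 1)),
         reaction("EX_B", c(B = 1)), reaction("EX_C", c(CO2 = 1))))
  rep <- validate_component_balance(ok)
  expect_true(rep$balanced)
  expect_equal(rep$report$residual[rep$report$reaction == "R1"], 0)

  bad <- metabolic_model(
    list(metabolite("A", carbon = 6), metabolite("B", carbon = 5)),
    list(reaction("EX_A", products = c(A = 1)),
         reaction("R1", c(A = 1), c(B = 1)),
         reaction("EX_B", c(B = 1))))
  repb <- validate_component_balance(bad)
  expect_false(repb$balanced)
  expect_equal(repb$report$residual[repb$report$reaction == "R1"], -1)
})

test_that("SBML round trip preserves stoichiometry, roles, ordering", {
  m <- mammary_model()
  f <- tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_equal(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$metabolites$role, m$metabolites$role)
  expect_equal(m2$metabolites$carbon, m$metabolites$carbon)
  expect_equal(m2$S, m$S)
  expect_setequal(attr(m2, "free_balance"), attr(m, "free_balance"))
})

test_that("read_sbml reads the shipped toy fixture and rejects bad input", {
  f <- system.file("extdata", "toy_chain.xml", package = "aioflux")
  m <- read_sbml(f)
  expect_equal(length(m$reactions), 3L)
  expect_equal(m$metabolites$role[m$metabolites$id == "A"], "input")
  expect_equal(m$metabolites$role[m$metabolites$id == "B"], "output")

  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model></sbml>", bad)
  expect_error(read_sbml(bad), "malformed SBML")
})

test_that("unit conversion follows mol/d/udder * 1000/48", {
  expect_equal(unit_convert(12.21, "mol/d/udder", "mmol/h/half-udder"),
               12.21 * 1000 / 48)
  expect_equal(signif(unit_convert(12.21, "mol/d/udder", "mmol/h/half-udder"), 3),
               254)
  expect_equal(unit_convert(0, "mol/d/udder", "mmol/h/half-udder"), 0)
  expect_equal(unit_convert(7.2, "mol/d/udder", "mmol/h/half-udder"), 150)
  expect_equal(unit_convert(150, "mmol/h/half-udder", "mol/d/udder"), 7.2)
  expect_error(unit_convert(1, "furlongs", "mmol/h/half-udder"), "unknown unit")
})

test_that("apply_dataset assembles steady-state rows, side constraints and fixed fluxes", {
  m <- mammary_model()
  ds <- mammary_datasets()$Ctrl
  sys <- apply_dataset(m, ds)
  rn <- rownames(sys$A_eq)
  ## the eight side constraints are present, including the acylation rule
  expect_equal(sum(grepl("^side:", rn)), 8L)
  acyl <- sys$A_eq[grepl("side:R_56", rn), ]
  expect_equal(unname(acyl[c("R_56", "R_62")]), c(1, -3))
  ## empty dataset: only stoichiometric rows
  sys0 <- apply_dataset(m)
  expect_true(all(grepl("^ss:", rownames(sys0$A_eq))))
  ## unknown reaction
  expect_error(apply_dataset(m, treatment_dataset("x", fluxes = c(R_999 = 1))),
               "unknown reaction")
  ## contradiction: nonzero fixed flux also forced to zero
  bad <- treatment_dataset("x", fluxes = c(R_2 = 237), zeroed = "R_2")
  expect_error(apply_dataset(m, bad), "contradictory")
})

test_that("apply_dataset is idempotent and order-independent", {
  m <- mammary_model()
  d <- mammary_table1_fixture()
  ds1 <- treatment_dataset("a", fluxes = d$fluxes,
                           side_constraints = mammary_side_fixture(),
                           zeroed = d$zeroed)
  perm <- sample(length(d$fluxes))
  ds2 <- treatment_dataset("a", fluxes = d$fluxes[perm],
                           side_constraints = rev(mammary_side_fixture()),
                           zeroed = rev(d$zeroed))
  s1 <- apply_dataset(m, ds1); s2 <- apply_dataset(m, ds2)
  sp1 <- flux_space(s1, prefer_free = c("R_8", "R_14", "R_15", "R_19", "R_64"))
  sp2 <- flux_space(s2, prefer_free = c("R_8", "R_14", "R_15", "R_19", "R_64"))
  expect_equal(sp1$free_ids, sp2$free_ids)
  expect_equal(sp1$dimension, sp2$dimension)
  fva1 <- flux_variability(sp1, c("R_14", "R_64"))
  fva2 <- flux_variability(sp2, c("R_14", "R_64"))
  expect_equal(fva1, fva2, tolerance = 1e-6)
})

test_that("the mammary transcription is carbon balanced with Table-1 input totals", {
  m <- mammary_model()
  expect_true(validate_component_balance(m)$balanced)
  sp <- mammary_space("Ctrl")
  a <- aio(m, sp$v0)
  ## per-input carbon totals printed in the min-max table header
  expect_equal(unname(a$input_totals["GLC"]), 1422)
  expect_equal(unname(a$input_totals["AC"]), 1020)
  expect_equal(unname(a$input_totals["BHBA"]), 336)
  expect_equal(unname(round(a$input_totals["GLYC"], 1)), 17.5)
  expect_equal(unname(round(a$input_totals["ARG"], 1)), 26.4)
})

test_that("the LCFA variant builds and rejects unsupported ratios", {
  expect_error(mammary_model(0.5), "lcfa_ratio")
  m10 <- mammary_model(0.10)
  expect_true(all(c("R_141", "R_142", "R_20", "R_21") %in% names(m10$reactions)))
  expect_true(validate_component_balance(m10)$balanced)
  sp <- mammary_space("HB", lcfa_ratio = 0.10)
  expect_equal(sp$dimension, 5L)
})
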