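test_that("ATP comparison report has the Table-2 structure", {
  rep <- report_atp_comparison()
  expect_equal(rep$treatment, c("Ctrl", "CN", "HB"))
  ## protein turnover is zero at every ATP optimum
  expect_equal(rep$peptide_hydrolysis, rep(0, 3), tolerance = 1e-6)
  ## peptide synthesis then equals the fixed peptide output
  expect_equal(rep$peptide_synthesis, c(124.5, 150, 149.17), tolerance = 1e-6)
  expect_true(all(diff(rep[rep$treatment %in% c("CN", "Ctrl", "HB"),
                           "atp_balance"]) != 0))
})

test_that("predicted CO2 equals input minus non-CO2 output carbon", {
  m <- mammary_model()
  for (tr in c("Ctrl", "CN", "HB")) {
    sp <- mammary_space(tr)
    a <- aio(m, sp$v0)
    co2 <- unname(a$output_totals["CO2"])
    expect_equal(co2, sum(a$input_totals) - sum(a$output_totals) + co2,
                 tolerance = 1e-6)
  }
})

test_that("vertex classification flags zero-turnover vertices as nonrelevant", {
  sp <- mammary_space("CN", atp = 1250)
  vs <- enumerate_vertices(sp, n_objectives = 200, seed = 3, window = 100)
  tab <- report_vertex_classification(vs)
  expect_equal(nrow(tab), length(vs$vertices))
  ## every vertex with no peptide hydrolysis is flagged
  no_turn <- tab$R_64 <= 1e-6
  expect_true(all(grepl("R_64", tab$nonrelevant[no_turn])))
  expect_true(all(tab$plausible == (tab$nonrelevant == "")))
  ## peptide synthesis = hydrolysis + fixed output at every vertex
  expect_equal(tab$R_63, tab$R_64 + 150, tolerance = 0.05)
})

test_that("peptide links carry no carbon: the peptide output row is zero", {
  m <- mammary_model()
  sp <- mammary_space("Ctrl", atp = 1250)
  a <- aio(m, sp$v0)
  expect_true("PEPT" %in% rownames(a$matrix))
  expect_equal(max(abs(a$matrix["PEPT", ])), 0)
})

test_that("percent-of-output rows sum to 100 within rounding", {
  m <- mammary_model()
  sp <- mammary_space("CN", atp = 1250)
  a <- aio(m, sp$v0)
  P <- aio_view(a, "percent-output")
  nz <- rowSums(a$matrix) > 0
  expect_true(all(abs(rowSums(P[nz, , drop = FALSE]) - 100) < 0.2))
})

test_that("the LCFA sweep reports feasibility, CO2 and ATP per scenario", {
  rep <- report_lcfa_sweep(ratios = c(0, 0.10), treatments = c("Ctrl", "HB"),
                           ranges = FALSE, seed = 2)
  expect_equal(nrow(rep), 4L)
  expect_true(all(rep$feasible))
  ## oxidizing LCFA raises both predicted CO2 and the ATP optimum
  for (tr in c("Ctrl", "HB")) {
    r0 <- rep[rep$ratio == 0 & rep$treatment == tr, ]
    r1 <- rep[rep$ratio == 0.10 & rep$treatment == tr, ]
    expect_gt(r1$predicted_co2, r0$predicted_co2)
    expect_gt(r1$atp_optimum, r0$atp_optimum)
  }
})

test_that("the fatty-acid sub-model is fully determined and fast", {
  t0 <- Sys.time()
  fs <- fa_submodel("Ctrl")
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(fs$space$dimension, 0L)
  expect_true(validate_component_balance(fs$model)$balanced)
})
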