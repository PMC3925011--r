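test_that("reaction allocation ratios follow the component masses", {
  cvec <- c(A = 6, B = 5, CO2 = 1)
  r <- reaction("r", c(A = 1), c(B = 1, CO2 = 1))
  expect_equal(reaction_allocation(r, cvec, "B"), 5 / 6)
  expect_equal(reaction_allocation(r, cvec, "CO2"), 1 / 6)
  expect_equal(reaction_allocation(r, cvec, "A"), 0)
  r2 <- reaction("r2", c(A = 2), c(B = 1), name = "2A(3)->B(6)")
  expect_equal(reaction_allocation(r2, c(A = 3, B = 6), "B"), 1)
  ## products carrying mass out of nothing is a balance error
  r3 <- reaction("r3", c(N = 1), c(B = 1))
  expect_error(reaction_allocation(r3, c(N = 0, B = 5), "B"), "component mass")
})

test_that("allocation ratios of every balanced reaction sum to one", {
  set.seed(11)
  for (k in 1:10) {
    toy <- generate_toy(toy_spec(n_pivots = sample(2:4, 1),
                                 cycle_edges = sample(0:1, 1),
                                 free_dim_target = 1, seed = 100 + k))
    cvec <- component_vector(toy$model)
    for (r in toy$model$reactions) {
      if (!length(r$substrates) || !length(r$products)) next
      s <- sum(vapply(names(r$products), function(p)
        reaction_allocation(r, cvec, p), 0))
      expect_equal(s, 1, tolerance = 1e-9)
    }
  }
})

test_that("pivot throughput equals production and detects steady-state violation", {
  m <- recycle_model()
  v <- recycle_flux(rho = 0.4)
  expect_equal(pivot_throughput(m, v, "P1"), 1 / (1 - 0.4))
  expect_equal(pivot_throughput(m, v, "I"), 1)   # exchange production
  vbad <- v; vbad["A"] <- 2 * v["A"]
  expect_error(pivot_throughput(m, vbad, "P1"), "steady-state")
  ## zero throughput everywhere
  expect_equal(pivot_throughput(m, v * 0, "P1"), 0)
})

test_that("D matrices of a linear chain have the closed form and M-matrix shape", {
  m <- chain_model()
  v <- c(EX_I = 1, U = 1, S = 1, EX_O = 1)
  d <- build_d_matrices(m, v)
  expect_equal(unname(d$D1), rbind(c(1, 0), c(-1, 1)))
  expect_equal(rownames(d$D1), c("P", "O"))
  expect_equal(unname(d$D2[, "I"]), c(-1, 0))
  ## x_O = x_I for the chain
  x <- solve(d$D1, -d$D2 %*% c(1))
  expect_equal(unname(x["O", 1]), 1)
})

test_that("the recycle network inverts to the geometric-series throughput", {
  m <- recycle_model()
  for (rho in c(0.2, 0.5, 0.8)) {
    v <- recycle_flux(rho)
    expect_equal(pivot_throughput(m, v, "P1"), 1 / (1 - rho))
    a <- aio(m, v)
    ## all input carbon exits through the single output despite the cycle
    expect_equal(unname(a$matrix["O", "I"]), 1, tolerance = 1e-12)
    d <- build_d_matrices(m, v)
    expect_true(all(diag(d$D1) == 1))
    expect_true(all(d$D1[row(d$D1) != col(d$D1)] <= 0))
    expect_true(is.finite(kappa(d$D1)))
  }
})

test_that("D1 is an M-matrix on random feasible toys", {
  for (k in 1:8) {
    toy <- generate_toy(toy_spec(n_pivots = 3, cycle_edges = 1,
                                 free_dim_target = 1, seed = 300 + k))
    d <- build_d_matrices(toy$model, toy$v$v)
    expect_true(all(diag(d$D1) == 1))
    off <- d$D1[row(d$D1) != col(d$D1)]
    expect_true(all(off <= 1e-12))
    expect_no_error(solve(d$D1))
  }
})

test_that("aio conserves carbon row- and column-wise and is scale invariant", {
  toy <- generate_toy(toy_spec(n_pivots = 4, n_inputs = 2, n_outputs = 2,
                               cycle_edges = 1, free_dim_target = 2,
                               seed = 17))
  v <- toy$v$v
  a <- aio(toy$model, v)
  expect_equal(colSums(a$matrix), a$input_totals, tolerance = 1e-8)
  expect_equal(rowSums(a$matrix), a$output_totals, tolerance = 1e-8)
  expect_true(all(a$matrix >= 0))
  ## v -> lambda v leaves the percentage views unchanged
  a2 <- aio(toy$model, 3.7 * v)
  expect_equal(aio_view(a2, "percent-output"), aio_view(a, "percent-output"),
               tolerance = 1e-9)
  expect_equal(aio_view(a2, "percent-input"), aio_view(a, "percent-input"),
               tolerance = 1e-9)
})

test_that("acyclic networks equal the topological propagation oracle", {
  m <- diamond_model()
  ## uneven split across the two parallel paths
  v <- c(EX_I = 1, U = 1, A1 = 0.3, A2 = 0.7, B1 = 0.3, B2 = 0.7, EX_O = 1)
  a <- aio(m, v)
  oracle <- dag_propagate_aio(m, v)
  expect_equal(a$matrix, oracle, tolerance = 1e-12)
  ## random acyclic toys
  for (k in 1:5) {
    toy <- generate_toy(toy_spec(n_pivots = 3, cycle_edges = 0,
                                 free_dim_target = 1, seed = 400 + k))
    a <- aio(toy$model, toy$v$v)
    oracle <- dag_propagate_aio(toy$model, toy$v$v)
    expect_equal(a$matrix, oracle, tolerance = 1e-10)
  }
  ## cyclic input is rejected by the DAG oracle
  expect_error(dag_propagate_aio(recycle_model(), recycle_flux(0.5)),
               "cycle")
})

test_that("Monte-Carlo atom tracing agrees with the exact computation", {
  m <- recycle_model()
  v <- recycle_flux(0.6)
  a <- aio(m, v)
  tr <- atom_trace_aio(m, v, n_particles = 2e4, seed = 8)
  expect_equal(tr$trapped, 0)
  expect_true(all(abs(tr$estimate - a$matrix) <=
                    3 * pmax(tr$se, 1e-9) + 1e-9))
  ## linear chain: estimate is exact
  mc <- chain_model()
  vc <- c(EX_I = 1, U = 1, S = 1, EX_O = 1)
  trc <- atom_trace_aio(mc, vc, n_particles = 1e3, seed = 8)
  expect_equal(unname(trc$estimate["O", "I"]), 1)
})

test_that("zero-throughput branches are pruned with zero allocations", {
  m <- diamond_model()
  v <- c(EX_I = 1, U = 1, A1 = 1, A2 = 0, B1 = 1, B2 = 0, EX_O = 1)
  a <- aio(m, v)
  expect_equal(unname(a$matrix["O", "I"]), 2, tolerance = 1e-12) # carbon 2/molecule
  d <- build_d_matrices(m, v)
  expect_true("P3" %in% d$pruned)
})

test_that("the mammary fatty-acid rows reproduce the primer closed forms", {
  fs <- fa_submodel("CN")
  p <- fs$precursors
  expect_equal(p$acetate, p$acetate_closed_form, tolerance = 0.005)
  expect_equal(p$bhba, p$bhba_closed_form, tolerance = 0.005)
})
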