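test_that("a dimension-0 space gives min = max = the point value", {
  m <- chain_model(c(I = 2, P = 2, O = 2))
  ds <- treatment_dataset("d", fluxes = c(EX_I = 3))
  sp <- flux_space(apply_dataset(m, ds))
  r1 <- minmax_nlp(sp, m, c("O", "I"), "min")
  r2 <- minmax_nlp(sp, m, c("O", "I"), "max")
  expect_equal(r1$value, r2$value)
  expect_equal(r1$value, 6)   # 3 molecules x 2 carbons
  g <- grid_minmax_oracle(sp, m, c("O", "I"))
  expect_equal(unname(g), c(6, 6))
})

test_that("the exact evaluator matches aio() at random feasible points", {
  sp <- mammary_space("CN", atp = 1250)
  m <- mammary_model()
  f <- aio_function(sp, m)
  cb <- chebyshev_ball(sp)
  vs <- enumerate_vertices(sp, n_objectives = 60, seed = 5, window = 40)
  set.seed(9)
  for (k in 1:5) {
    w <- rgamma(nrow(vs$lambda), 1); w <- w / sum(w)
    lam <- 0.5 * drop(w %*% vs$lambda) + 0.5 * cb$lambda
    a1 <- f(lam)
    v <- pmax(aioflux:::space_point(sp, lam), 0)
    names(v) <- rownames(sp$N)
    a2 <- aio(m, v)
    expect_equal(a1$matrix, a2$matrix, tolerance = 1e-9)
  }
})

test_that("all routes agree on a bounded one-free-variable toy", {
  ## recycle capped by a carbon-free resource: REC <= 2
  cc <- list(I1 = 1, I2 = 1, E = 0, P1 = 1, P2 = 1, O1 = 1, O2 = 1)
  m <- metabolic_model(
    lapply(names(cc), function(id) metabolite(id, carbon = cc[[id]])),
    list(reaction("EX_I1", products = c(I1 = 1)),
         reaction("EX_I2", products = c(I2 = 1)),
         reaction("EX_E", products = c(E = 1)),
         reaction("U1", c(I1 = 1), c(P1 = 1)),
         reaction("U2", c(I2 = 1), c(P2 = 1)),
         reaction("A", c(P1 = 1), c(P2 = 1)),
         reaction("REC", c(P2 = 1, E = 1), c(P1 = 1)),
         reaction("SE", c(E = 1)),
         reaction("S1", c(P1 = 1), c(O1 = 1)),
         reaction("S2", c(P2 = 1), c(O2 = 1)),
         reaction("EX_O1", c(O1 = 1)), reaction("EX_O2", c(O2 = 1))),
    name = "capped recycle")
  ds <- treatment_dataset("d", fluxes = c(EX_I1 = 1, EX_I2 = 1, EX_E = 2,
                                          EX_O1 = 1, EX_O2 = 1))
  sp <- flux_space(apply_dataset(m, ds), prefer_free = "REC")
  expect_true(sp$bounded)
  expect_equal(sp$dimension, 1L)
  ## closed form for the O1-from-I2 cell: lambda / (1 + 2 lambda)
  fva <- flux_variability(sp, "REC")
  lam_max <- fva$max
  truth <- function(l) l / (1 + 2 * l)
  expect_equal(truth(lam_max), {
    v <- pmax(aioflux:::space_point(sp, lam_max), 0)
    names(v) <- rownames(sp$N)
    aio_cell_value(m, v, "O1", "I2")
  }, tolerance = 1e-9)
  cell <- c("O1", "I2")
  g <- grid_minmax_oracle(sp, m, cell, grid_points = 200)
  nl_min <- minmax_nlp(sp, m, cell, "min", multistarts = 3, seed = 2)
  nl_max <- minmax_nlp(sp, m, cell, "max", multistarts = 3, seed = 2)
  ls_min <- minmax_localsearch(sp, m, cell, "min", seed = 2)
  ls_max <- minmax_localsearch(sp, m, cell, "max", seed = 2)
  expect_equal(nl_min$value, 0, tolerance = 1e-6)
  expect_equal(nl_max$value, truth(lam_max), tolerance = 1e-6)
  expect_equal(ls_min$value, 0, tolerance = 1e-6)
  expect_equal(ls_max$value, truth(lam_max), tolerance = 1e-6)
  ## grid gives inner bounds, refining monotonically
  g2 <- grid_minmax_oracle(sp, m, cell, grid_points = 20)
  expect_lte(g2["upper"], g["upper"] + 1e-12)
  expect_gte(g2["lower"], g["lower"] - 1e-12)
  expect_gte(g["lower"], nl_min$value - 1e-9)
  expect_lte(g["upper"], nl_max$value + 1e-9)
})

test_that("a constant cell is degenerate: lower equals upper everywhere", {
  sp <- square_space()
  m <- sp$system$model
  g <- grid_minmax_oracle(sp, m, c("OX", "X"), grid_points = 15)
  expect_equal(unname(g["lower"]), unname(g["upper"]))
  expect_equal(unname(g["lower"]), 1)  # all X carbon reaches OX
})

test_that("cell extrema can strictly beat every vertex (nonlinearity of AIO)", {
  m <- mammary_model()
  sp <- mammary_space("Ctrl", atp = 1250)
  vs <- enumerate_vertices(sp, n_objectives = 200, seed = 7, window = 100)
  vertex_vals <- vapply(vs$vertices, function(vv)
    aio_cell_value(m, vv$v, "CO2", "GLC"), 0)
  opt <- minmax_nlp(sp, m, c("CO2", "GLC"), "max", multistarts = 3, seed = 7,
                    vertices = vs)
  expect_gt(opt$value, max(vertex_vals) + 50)
  ## the argmax is feasible
  arg <- opt$argument$v
  expect_true(all(arg >= -1e-7))
  expect_lt(max(abs(sp$system$A_eq %*% arg - sp$system$b_eq)), 1e-5)
})

test_that("sandwich property: extrema bracket random feasible points", {
  m <- mammary_model()
  sp <- mammary_space("CN", atp = 1250)
  vs <- enumerate_vertices(sp, n_objectives = 150, seed = 11, window = 80)
  cell <- c("LACTOSE", "GLC")
  lo <- minmax_nlp(sp, m, cell, "min", multistarts = 3, seed = 11, vertices = vs)
  hi <- minmax_nlp(sp, m, cell, "max", multistarts = 3, seed = 11, vertices = vs)
  cb <- chebyshev_ball(sp)
  set.seed(11)
  for (k in 1:25) {
    w <- rgamma(nrow(vs$lambda) + 1, 1); w <- w / sum(w)
    lam <- drop(w[-1] %*% vs$lambda) + w[1] * cb$lambda
    v <- pmax(aioflux:::space_point(sp, lam), 0)
    names(v) <- rownames(sp$N)
    val <- aio_cell_value(m, v, cell[1], cell[2])
    expect_gte(val, lo$value - 0.5)
    expect_lte(val, hi$value + 0.5)
  }
})

test_that("aio_range emits structural zeros without optimization", {
  sp <- square_space()
  m <- sp$system$model
  rng <- aio_range(sp, m, cells = list(c("OX", "X"), c("OX", "Y")),
                   method = "nlp", seed = 3)
  cellY <- rng$cells[rng$cells$input == "Y", ]
  expect_equal(cellY$lower, 0)
  expect_equal(cellY$upper, 0)
  expect_equal(cellY$method, "structural-zero")
  cellX <- rng$cells[rng$cells$input == "X", ]
  expect_equal(cellX$lower, 1, tolerance = 1e-6)
  expect_equal(cellX$upper, 1, tolerance = 1e-6)
})
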