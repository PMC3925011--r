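test_that("a fully determined system has dimension zero and a single point", {
  m <- chain_model()
  ds <- treatment_dataset("d", fluxes = c(EX_I = 2))
  sp <- flux_space(apply_dataset(m, ds))
  expect_equal(sp$dimension, 0L)
  expect_true(sp$bounded)
  expect_equal(unname(sp$v0), rep(2, 4))
})

test_that("infeasible fixed values yield an infeasibility error", {
  m <- chain_model()
  ds <- treatment_dataset("d", fluxes = c(EX_I = 2, EX_O = 3))
  expect_error(flux_space(apply_dataset(m, ds)), "inconsistent|infeasible")
})

test_that("the recycle space has one free variable and an unbounded cone", {
  sp <- recycle_space()
  expect_equal(sp$dimension, 1L)
  expect_equal(sp$free_ids, "REC")
  expect_false(sp$bounded)   # the recycle loop can spin arbitrarily fast
  fva <- flux_variability(sp, c("REC", "A"))
  expect_equal(fva$min, c(0, 1))
  expect_true(all(is.infinite(fva$max)))
})

test_that("fba reports unbounded objectives as a status, not an error", {
  sp <- recycle_space()
  res <- fba_optimize(sp, c(REC = 1), "max")
  expect_equal(attr(res, "status"), "unbounded")
  res2 <- fba_optimize(sp, c(REC = 1), "min")
  expect_equal(attr(res2, "value"), 0)
})

test_that("ATP balance is linear in the flux vector", {
  m <- mammary_model()
  sp <- mammary_space("Ctrl", atp = 1250)
  vs <- enumerate_vertices(sp, n_objectives = 50, seed = 2, window = 30)
  v1 <- vs$vertices[[1]]$v
  v2 <- vs$vertices[[min(2, length(vs$vertices))]]$v
  set.seed(1)
  for (w in runif(5)) {
    expect_equal(atp_balance(w * v1 + (1 - w) * v2, m),
                 w * atp_balance(v1, m) + (1 - w) * atp_balance(v2, m),
                 tolerance = 1e-9)
  }
  expect_equal(atp_balance(0 * v1, m), 0)
})

test_that("vertex sampling equals exact facet enumeration on toy polytopes", {
  sp <- square_space()
  expect_true(sp$bounded)
  expect_equal(sp$dimension, 2L)
  ex <- enumerate_vertices(sp, method = "exact")
  sm <- enumerate_vertices(sp, n_objectives = 100, seed = 4, window = 50)
  expect_equal(nrow(ex$lambda), 4L)
  expect_equal(nrow(sm$lambda), 4L)
  expect_equal(sm$lambda, ex$lambda, tolerance = 1e-6)

  ## a 3-simplex style space: X split over three routes
  m <- metabolic_model(
    list(metabolite("X", carbon = 1), metabolite("O", carbon = 1)),
    list(reaction("EX_X", products = c(X = 1)),
         reaction("A", c(X = 1), c(O = 1)),
         reaction("B", c(X = 1), c(O = 1)),
         reaction("C", c(X = 1), c(O = 1)),
         reaction("EX_O", c(O = 1))), name = "threeway")
  ds <- treatment_dataset("d", fluxes = c(EX_X = 1, EX_O = 1))
  sp3 <- flux_space(apply_dataset(m, ds), prefer_free = c("A", "B"))
  ex3 <- enumerate_vertices(sp3, method = "exact")
  sm3 <- enumerate_vertices(sp3, n_objectives = 100, seed = 4, window = 50)
  expect_equal(nrow(ex3$lambda), 3L)
  expect_equal(sm3$lambda, ex3$lambda, tolerance = 1e-6)
})

test_that("every enumerated vertex is feasible with enough active constraints", {
  sp <- mammary_space("CN", atp = 1250)
  vs <- enumerate_vertices(sp, n_objectives = 200, seed = 3, window = 100)
  red <- aioflux:::space_reduced(sp)
  sys <- sp$system
  for (i in seq_along(vs$vertices)) {
    v <- vs$vertices[[i]]$v
    expect_true(all(v >= -1e-7))
    resid <- max(abs(sys$A_eq %*% v - sys$b_eq))
    expect_lt(resid, 1e-6 * max(1, max(abs(sys$b_eq))))
    lam <- vs$lambda[i, ]
    n_active <- sum(abs(red$A %*% lam - red$b) < 1e-6 * max(abs(red$b), 1))
    expect_gte(n_active, sp$dimension)
  }
  ## FVA brackets every vertex coordinate
  fva <- flux_variability(sp, c("R_14", "R_15", "R_19", "R_64"))
  for (k in seq_along(fva$reaction)) {
    vals <- vs$lambda[, fva$reaction[k]]
    expect_true(all(vals >= fva$min[k] - 1e-6 & vals <= fva$max[k] + 1e-6))
  }
})

test_that("the Chebyshev ball of the unit square is centered with radius 1/2", {
  sp <- square_space()
  cb <- chebyshev_ball(sp)
  expect_equal(unname(cb$lambda), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(cb$radius, 0.5, tolerance = 1e-6)
})

test_that("the Chebyshev ball of a triangle matches a dense grid oracle", {
  ## {x,y >= 0, x + y <= 1}: reuse the three-route simplex
  m <- metabolic_model(
    list(metabolite("X", carbon = 1), metabolite("O", carbon = 1)),
    list(reaction("EX_X", products = c(X = 1)),
         reaction("A", c(X = 1), c(O = 1)),
         reaction("B", c(X = 1), c(O = 1)),
         reaction("C", c(X = 1), c(O = 1)),
         reaction("EX_O", c(O = 1))), name = "threeway")
  ds <- treatment_dataset("d", fluxes = c(EX_X = 1, EX_O = 1))
  sp <- flux_space(apply_dataset(m, ds), prefer_free = c("A", "B"))
  cb <- chebyshev_ball(sp)
  ## oracle: maximize the minimum distance to the three facets over a grid
  g <- seq(0.01, 0.99, by = 0.002)
  best <- -Inf; arg <- NULL
  for (x in g) for (y in g) {
    if (x + y >= 1) next
    dmin <- min(x, y, (1 - x - y) / sqrt(2))
    if (dmin > best) { best <- dmin; arg <- c(x, y) }
  }
  expect_equal(cb$radius, best, tolerance = 1e-2)
  expect_equal(unname(cb$lambda), arg, tolerance = 1e-2)
  ## interior: all facet distances >= radius
  expect_true(all(c(arg, (1 - sum(arg)) / sqrt(2)) >= best - 1e-9))
})

test_that("ATP constraint: equality re-parameterizes, band relaxes", {
  sp0 <- mammary_space("Ctrl")
  expect_false(sp0$bounded)
  expect_equal(sp0$dimension, 5L)
  sp <- add_atp_constraint(sp0, 1250)
  expect_true(sp$bounded)
  expect_equal(sp$dimension, 4L)
  ## the gluconeogenic flux is no longer an independent coordinate
  expect_false("R_8" %in% sp$free_ids)
  expect_setequal(sp$free_ids, c("R_14", "R_15", "R_19", "R_64"))
  ## 10% band is a superset of the equality space
  spb <- add_atp_constraint(sp0, 1250, 0.10)
  fva_eq <- flux_variability(sp, "R_64")
  fva_band <- flux_variability(spb, "R_64")
  expect_lte(fva_eq$min, fva_band$max)
  expect_gte(fva_band$max, fva_eq$max - 1e-6)
  ## infeasible target on a toy whose ATP balance is identically zero
  m <- chain_model()
  ds <- treatment_dataset("d", fluxes = c(EX_I = 2))
  spc <- flux_space(apply_dataset(m, ds))
  expect_error(atp_balance(spc$v0, m), "no species")
})

test_that("the three treatments share the same five independent variables", {
  frees <- lapply(c("Ctrl", "CN", "HB"), function(tr)
    mammary_space(tr)$free_ids)
  expect_equal(frees[[1]], frees[[2]])
  expect_equal(frees[[1]], frees[[3]])
  expect_setequal(frees[[1]], c("R_8", "R_14", "R_15", "R_19", "R_64"))
})
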