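## Extrema of AIO coefficients over the whole polytope of plausible flux
## distributions. The AIO cells are rational (hence nonlinear) functions of
## the free flux coordinates, so vertex optima are not sufficient; the
## package offers a multistart NLP route (SLSQP over the reduced polytope)
## and a derivative-free local search on the Chebyshev-ball boundary
## parameterization with dichotomic step refinement.

## fast single-cell evaluation -------------------------------------------

## value of the AIO cell (carbon of input `in_id` recovered in the sink of
## `out_id`) at flux vector v; lean single-column version of aio()
aio_cell_value <- function(model, v, out_id, in_id, component = NULL) {
  st <- aio_structures(model, v, component, check_steady = FALSE)
  v <- st$v; cvec <- st$cvec
  if (!(in_id %in% st$active) || !(out_id %in% st$active)) return(0)
  inflow <- 0
  for (r in model$reactions)
    if (is_source(r) && names(r$products) == in_id)
      inflow <- inflow + r$products[[1]] * v[[r$id]]
  if (inflow <= 0) return(0)
  act <- st$active
  Aop <- allocation_operator(model, st)
  b <- stats::setNames(rep(0, length(act)), act)
  b[in_id] <- cvec[[in_id]] * inflow
  x <- solve(diag(length(act)) - Aop, b)
  val <- 0
  for (r in model$reactions)
    if (is_sink(r) && names(r$substrates) == out_id && v[[r$id]] > 0)
      val <- val + x[[out_id]] * r$substrates[[1]] * v[[r$id]] / st$Fv[[out_id]]
  max(val, 0)
}

#' Exact evaluator of the AIO table over the free coordinates
#'
#' Returns the allocation table as a function of the independent (free)
#' flux coordinates of a parameterized space: the analytic route of the
#' min-max computation. Each cell is a rational function of the free
#' variables; the evaluator computes it exactly through linear solves, so
#' evaluating at any feasible point reproduces [aio()] to machine
#' precision.
#'
#' @param space A [flux_space()].
#' @param model The model the space was built from.
#' @param component Optional component override.
#' @return A function `f(lambda)` returning the `"aio"` object at the flux
#'   distribution with free coordinates `lambda`; for a dimension-0 space
#'   the function is constant.
#' @export
aio_function <- function(space, model, component = NULL) {
  force(space); force(model); force(component)
  function(lambda) {
    v <- pmax(space_point(space, lambda), 0)
    names(v) <- rownames(space$N)
    aio(model, v, component)
  }
}

## strictly feasible interior starts: shrink toward the center
minmax_starts <- function(space, multistarts, seed, vertices = NULL) {
  set.seed(seed)
  cb <- chebyshev_ball(space)
  lam0 <- cb$lambda
  starts <- list(lam0)
  if (is.null(vertices))
    vertices <- tryCatch(
      enumerate_vertices(space, n_objectives = 200, seed = seed,
                         window = 100),
      error = function(e) NULL)
  V <- if (!is.null(vertices)) vertices$lambda else NULL
  if (!is.null(V)) {
    for (i in seq_len(nrow(V)))
      starts <- c(starts, list(0.99 * V[i, ] + 0.01 * lam0))
    for (j in seq_len(multistarts)) {
      w <- stats::rgamma(nrow(V) + 1, 1)
      w <- w / sum(w)
      starts <- c(starts, list(drop(w[-1] %*% V) + w[1] * lam0))
    }
  } else {
    for (j in seq_len(multistarts))
      starts <- c(starts, list(lam0 * stats::runif(1, 0.5, 1.5)))
  }
  list(starts = starts, center = lam0, radius = cb$radius, vertices = V)
}

#' Extremum of one AIO cell by multistart nonlinear programming
#'
#' Optimizes one allocation coefficient over the bounded polytope of
#' plausible flux distributions (in the reduced free coordinates, subject
#' to the nonnegativity of all fluxes) with SLSQP from multiple starts:
#' the Chebyshev center, every enumerated vertex (pulled slightly inward),
#' and random interior mixtures.
#'
#' @param space A bounded [flux_space()].
#' @param model The model.
#' @param cell Character vector `c(output, input)` of metabolite ids.
#' @param sense `"min"` or `"max"`.
#' @param multistarts Number of random interior starts.
#' @param seed Integer seed.
#' @param component Optional component override.
#' @param vertices Optional precomputed [enumerate_vertices()] result.
#' @return List: `value`, `argument` (a `"flux_distribution"`), `starts`
#'   (per-start diagnostics), `method = "nlp"`.
#' @export
minmax_nlp <- function(space, model, cell, sense = c("min", "max"),
                       multistarts = 10, seed = 1L, component = NULL,
                       vertices = NULL) {
  sense <- match.arg(sense)
  if (!isTRUE(space$bounded))
    stop("min-max optimization requires a bounded space", call. = FALSE)
  d <- length(space$free_ids)
  out_id <- cell[1]; in_id <- cell[2]
  red <- space_reduced(space)
  sgn <- if (sense == "max") -1 else 1
  fn <- function(lam) {
    v <- pmax(space_point(space, lam), 0)
    names(v) <- rownames(space$N)
    sgn * aio_cell_value(model, v, out_id, in_id, component)
  }
  if (d == 0L) {
    v <- space$v0
    val <- aio_cell_value(model, v, out_id, in_id, component)
    return(list(value = val, argument = flux_distribution(v, "optimum"),
                starts = NULL, method = "nlp"))
  }
  st <- minmax_starts(space, multistarts, seed, vertices)
  hin <- function(lam) as.numeric(red$A %*% lam) - red$b   # <= 0 feasible
  best <- NULL; diag_list <- list()
  for (i in seq_along(st$starts)) {
    x0 <- st$starts[[i]]
    res <- tryCatch(
      nloptr::slsqp(x0, fn, hin = hin,
                    control = list(xtol_rel = 1e-9, maxeval = 400),
                    deprecatedBehavior = FALSE),
      error = function(e) NULL)
    if (is.null(res)) {
      diag_list[[i]] <- list(status = "error"); next
    }
    feas <- max(hin(res$par), 0)
    diag_list[[i]] <- list(status = res$convergence, value = sgn * res$value,
                           infeasibility = feas)
    if (feas > 1e-6 * max(abs(red$b), 1)) next
    if (is.null(best) || res$value < best$value)
      best <- list(par = res$par, value = res$value)
  }
  if (is.null(best))
    stop("no NLP start converged to a feasible point", call. = FALSE)
  v <- pmax(space_point(space, best$par), 0)
  names(v) <- rownames(space$N)
  list(value = sgn * best$value,
       argument = flux_distribution(v, "optimum",
                                    paste(sense, out_id, "from", in_id)),
       starts = diag_list, method = "nlp")
}

## spherical direction from d-1 angles
angles_to_dir <- function(theta, d) {
  if (d == 1L) return(1)
  u <- numeric(d)
  s <- 1
  for (i in seq_len(d - 1L)) {
    u[i] <- s * cos(theta[i])
    s <- s * sin(theta[i])
  }
  u[d] <- s
  u
}

## distance from the center to the boundary along direction u
ray_length <- function(red, lam0, u) {
  Au <- as.numeric(red$A %*% u)
  slack <- red$b - as.numeric(red$A %*% lam0)
  pos <- Au > 1e-12
  if (!any(pos)) return(Inf)
  max(min(slack[pos] / Au[pos]), 0)
}

#' Extremum of one AIO cell by boundary local search
#'
#' Parameterizes the boundary of the polytope by angles around the
#' Chebyshev center (every boundary point is the unique intersection of a
#' half-line from the center with the boundary), scans an initial angular
#' grid of step `2*pi/grid_p`, hill-climbs over the neighborhood obtained
#' by changing one angle at a time, and halves the step (dichotomy) when no
#' neighbor improves, down to `depth` refinements. With `radial = TRUE` a
#' supplementary radial coordinate extends the search to the full space,
#' which is how the boundary/interior comparison is performed.
#'
#' @inheritParams minmax_nlp
#' @param grid_p Initial angular grid resolution.
#' @param depth Number of dichotomic refinements.
#' @param radial Explore the interior through a radial coordinate.
#' @param max_grid Cap on the number of initial grid points (sampled with
#'   `seed` beyond the cap).
#' @return As [minmax_nlp()], with `method = "local-search"`.
#' @export
minmax_localsearch <- function(space, model, cell, sense = c("min", "max"),
                               grid_p = 8, depth = 10, radial = FALSE,
                               seed = 1L, component = NULL,
                               max_grid = 4096) {
  sense <- match.arg(sense)
  if (!isTRUE(space$bounded))
    stop("local search requires a bounded space", call. = FALSE)
  d <- length(space$free_ids)
  out_id <- cell[1]; in_id <- cell[2]
  sgn <- if (sense == "max") -1 else 1
  red <- space_reduced(space)
  cb <- chebyshev_ball(space)
  if (cb$radius <= 0)
    stop("zero Chebyshev radius: reduce the space dimension first",
         call. = FALSE)
  lam0 <- cb$lambda
  point_at <- function(theta, rho) {
    u <- angles_to_dir(theta, d)
    s <- ray_length(red, lam0, u)
    lam0 + rho * s * u
  }
  fval <- function(theta, rho) {
    lam <- point_at(theta, rho)
    v <- pmax(space_point(space, lam), 0)
    names(v) <- rownames(space$N)
    sgn * aio_cell_value(model, v, out_id, in_id, component)
  }
  if (d == 1L) {
    ## the boundary of an interval is its two endpoints; the radial
    ## extension is a dichotomic scan of the interval
    s_up <- ray_length(red, lam0, 1)
    s_dn <- ray_length(red, lam0, -1)
    lo <- lam0 - s_dn; hi <- lam0 + s_up
    f1 <- function(l) {
      v <- pmax(space_point(space, l), 0)
      names(v) <- rownames(space$N)
      sgn * aio_cell_value(model, v, out_id, in_id, component)
    }
    if (!radial) {
      vals <- c(f1(lo), f1(hi))
      lam_best <- c(lo, hi)[which.min(vals)]
      val_best <- min(vals)
    } else {
      pts <- seq(lo, hi, length.out = grid_p + 1)
      vals <- vapply(pts, f1, 0)
      i <- which.min(vals)
      lam_best <- pts[i]; val_best <- vals[i]
      step1 <- (hi - lo) / grid_p
      for (lev in seq_len(depth)) {
        step1 <- step1 / 2
        for (cand in c(lam_best - step1, lam_best + step1)) {
          cand <- min(max(cand, lo), hi)
          vv <- f1(cand)
          if (vv < val_best - 1e-12) { val_best <- vv; lam_best <- cand }
        }
      }
    }
    v <- pmax(space_point(space, lam_best), 0)
    names(v) <- rownames(space$N)
    return(list(value = sgn * val_best,
                argument = flux_distribution(v, "optimum",
                                             paste(sense, out_id, "from", in_id)),
                theta = numeric(), rho = NA_real_, method = "local-search"))
  }
  na <- max(d - 1L, 0L)
  ## initial grid over angles (x radial levels when radial)
  set.seed(seed)
  rho_levels <- if (radial) c(0.25, 0.5, 0.75, 1) else 1
  if (na == 0L) {
    grid <- matrix(numeric(), 1, 0)
  } else {
    steps <- lapply(seq_len(na), function(i)
      if (i < na) 2 * pi * (0:(grid_p - 1)) / grid_p
      else pi * (0:(grid_p - 1)) / grid_p)
    grid <- as.matrix(expand.grid(steps))
    if (nrow(grid) > max_grid)
      grid <- grid[sample.int(nrow(grid), max_grid), , drop = FALSE]
  }
  best <- NULL
  for (rho in rho_levels) for (i in seq_len(nrow(grid))) {
    val <- fval(grid[i, ], rho)
    if (is.null(best) || val < best$val - 1e-12)
      best <- list(theta = grid[i, ], rho = rho, val = val)
  }
  ## hill climb with dichotomic refinement; ties resolved toward the
  ## lexicographically smallest angle vector by scan order
  step <- 2 * pi / grid_p
  rstep <- if (radial) 0.25 else 0
  for (lev in seq_len(depth)) {
    repeat {
      improved <- FALSE
      cand <- list()
      for (i in seq_len(na)) for (sg in c(-1, 1)) {
        th <- best$theta; th[i] <- th[i] + sg * step
        cand <- c(cand, list(list(theta = th, rho = best$rho)))
      }
      if (radial) for (sg in c(-1, 1)) {
        rh <- min(max(best$rho + sg * rstep, 0), 1)
        cand <- c(cand, list(list(theta = best$theta, rho = rh)))
      }
      for (cc in cand) {
        val <- fval(cc$theta, cc$rho)
        if (val < best$val - 1e-12) {
          best <- list(theta = cc$theta, rho = cc$rho, val = val)
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    step <- step / 2
    rstep <- rstep / 2
  }
  lam <- point_at(best$theta, best$rho)
  v <- pmax(space_point(space, lam), 0)
  names(v) <- rownames(space$N)
  list(value = sgn * best$val,
       argument = flux_distribution(v, "optimum",
                                    paste(sense, out_id, "from", in_id)),
       theta = best$theta, rho = best$rho, method = "local-search")
}

#' Compare boundary-restricted and full-space extrema of AIO cells
#'
#' Runs the local search once restricted to the boundary of the polytope
#' and once extended to the interior through the radial coordinate, and
#' reports per cell whether the extrema coincide — the empirical check that
#' optimized allocations are attained on the boundary.
#'
#' @param space A bounded [flux_space()].
#' @param model The model.
#' @param cells List of `c(output, input)` pairs.
#' @param tol Absolute agreement tolerance (component flux units).
#' @param ... Passed to [minmax_localsearch()].
#' @return Data frame with boundary and full-space min/max per cell and an
#'   `on_boundary` flag.
#' @export
boundary_vs_interior <- function(space, model, cells, tol = 0.5, ...) {
  rows <- lapply(cells, function(cl) {
    bmin <- minmax_localsearch(space, model, cl, "min", radial = FALSE, ...)
    bmax <- minmax_localsearch(space, model, cl, "max", radial = FALSE, ...)
    fmin <- minmax_localsearch(space, model, cl, "min", radial = TRUE, ...)
    fmax <- minmax_localsearch(space, model, cl, "max", radial = TRUE, ...)
    data.frame(output = cl[1], input = cl[2],
               boundary_min = bmin$value, full_min = fmin$value,
               boundary_max = bmax$value, full_max = fmax$value,
               on_boundary = abs(bmin$value - fmin$value) <= tol &&
                 abs(bmax$value - fmax$value) <= tol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## metabolite reachability over reactions that can carry flux
structural_cells <- function(space, model, tol = 1e-6) {
  fva <- flux_variability(space, names(model$reactions))
  can <- fva$reaction[fva$max > tol]
  cvec <- component_vector(model)
  edges <- list()
  for (rid in can) {
    r <- model$reactions[[rid]]
    subs <- names(r$substrates); subs <- subs[cvec[subs] > 0]
    prods <- names(r$products); prods <- prods[cvec[prods] > 0]
    if (length(subs) && length(prods))
      edges[[rid]] <- expand.grid(from = subs, to = prods,
                                  stringsAsFactors = FALSE)
  }
  E <- do.call(rbind, edges)
  reach <- function(from) {
    seen <- from
    frontier <- from
    while (length(frontier)) {
      nxt <- unique(E$to[E$from %in% frontier])
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    seen
  }
  list(reach = reach, active = can)
}

#' Min-max table of all allocation coefficients
#'
#' Solves the two optimization problems (minimum and maximum) for every
#' requested cell of the allocation table over the whole bounded polytope
#' of plausible flux distributions. Cells with no directed
#' component-carrying path from the input to the output anywhere in the
#' space are structurally zero and reported as `[0, 0]` without
#' optimization. The NLP route is used with the local search as fallback
#' (`method = "both"` runs both and keeps the better bound).
#'
#' @param space A bounded [flux_space()].
#' @param model The model.
#' @param cells Optional list of `c(output, input)` pairs; default all
#'   cells of the table.
#' @param method `"nlp"`, `"localsearch"` or `"both"`.
#' @param multistarts,seed,component See [minmax_nlp()].
#' @return An object of class `"aio_range"`: matrices `lower` and `upper`
#'   (outputs x inputs, absolute component units), `input_totals`, a
#'   data.frame `cells` of per-cell results, and diagnostics.
#' @export
aio_range <- function(space, model, cells = NULL,
                      method = c("nlp", "localsearch", "both"),
                      multistarts = 5, seed = 1L, component = NULL) {
  method <- match.arg(method)
  a0 <- aio(model, space$v0, component)
  outs <- rownames(a0$matrix); ins <- colnames(a0$matrix)
  if (is.null(cells))
    cells <- unlist(lapply(outs, function(o) lapply(ins, function(i) c(o, i))),
                    recursive = FALSE)
  sc <- structural_cells(space, model)
  vertices <- tryCatch(
    enumerate_vertices(space, n_objectives = 200, seed = seed, window = 100),
    error = function(e) NULL)
  lower <- a0$matrix * NA; upper <- a0$matrix * NA
  rows <- list()
  for (cl in cells) {
    o <- cl[1]; i <- cl[2]
    if (!(o %in% outs) || !(i %in% ins)) next
    reachable <- o %in% sc$reach(i)
    if (!reachable) {
      lo <- hi <- 0
      tag <- "structural-zero"
    } else {
      solve_one <- function(sense) {
        res <- NULL
        if (method %in% c("nlp", "both"))
          res <- tryCatch(minmax_nlp(space, model, cl, sense,
                                     multistarts = multistarts, seed = seed,
                                     component = component,
                                     vertices = vertices),
                          error = function(e) NULL)
        if (method %in% c("localsearch", "both") || is.null(res)) {
          res2 <- tryCatch(minmax_localsearch(space, model, cl, sense,
                                              seed = seed,
                                              component = component),
                           error = function(e) NULL)
          if (is.null(res)) res <- res2
          else if (!is.null(res2)) {
            better <- if (sense == "min") res2$value < res$value
                      else res2$value > res$value
            if (better) res <- res2
          }
        }
        res
      }
      rmin <- solve_one("min"); rmax <- solve_one("max")
      lo <- if (is.null(rmin)) NA_real_ else rmin$value
      hi <- if (is.null(rmax)) NA_real_ else rmax$value
      tag <- method
    }
    lower[o, i] <- lo; upper[o, i] <- hi
    rows[[length(rows) + 1L]] <-
      data.frame(output = o, input = i, lower = lo, upper = hi,
                 method = tag, stringsAsFactors = FALSE)
  }
  structure(list(lower = lower, upper = upper,
                 input_totals = a0$input_totals,
                 output_totals = a0$output_totals,
                 cells = do.call(rbind, rows),
                 space_name = space$system$dataset$name),
            class = "aio_range")
}

#' @export
print.aio_range <- function(x, digits = 1, ...) {
  cat(sprintf("Min-max allocation table (%s), absolute component units;\ninput totals: %s\n",
              x$space_name,
              paste(sprintf("%s=%.3g", names(x$input_totals), x$input_totals),
                    collapse = ", ")))
  done <- !is.na(x$lower)
  tab <- matrix("", nrow(x$lower), ncol(x$lower),
                dimnames = dimnames(x$lower))
  tab[done] <- sprintf("[%.*f, %.*f]", digits, x$lower[done],
                       digits, x$upper[done])
  print(tab, quote = FALSE)
  invisible(x)
}

#' @export
summary.aio_range <- function(object, ...) {
  print(object)
  cat("\nAs percentage of each input's component:\n")
  pct <- 100 * sweep(object$lower, 2, pmax(object$input_totals, 1e-12), "/")
  pcu <- 100 * sweep(object$upper, 2, pmax(object$input_totals, 1e-12), "/")
  done <- !is.na(pct)
  tab <- matrix("", nrow(pct), ncol(pct), dimnames = dimnames(pct))
  tab[done] <- sprintf("[%.1f, %.1f]", pct[done], pcu[done])
  print(tab, quote = FALSE)
  invisible(object)
}
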