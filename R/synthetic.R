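#' Specification of a synthetic carbon-balanced network
#'
#' @param n_pivots Number of intermediary metabolites in the backbone chain.
#' @param n_inputs,n_outputs Numbers of input and output metabolites.
#' @param cycle_edges Number of recycle (backward) reactions, each creating
#'   one flux cycle.
#' @param carbon_range Integer range the carbon counts are drawn from.
#' @param free_dim_target Desired dimension of the flux space
#'   (`>= cycle_edges`; the surplus is realized as parallel forward routes).
#' @param seed Integer seed.
#' @return An object of class `"toy_spec"`.
#' @export
toy_spec <- function(n_pivots = 3, n_inputs = 1, n_outputs = 1,
                     cycle_edges = 0, carbon_range = c(1, 6),
                     free_dim_target = cycle_edges, seed = 1L) {
  stopifnot(n_pivots >= 1, n_inputs >= 1, n_outputs >= 1,
            cycle_edges >= 0, free_dim_target >= cycle_edges)
  structure(list(n_pivots = n_pivots, n_inputs = n_inputs,
                 n_outputs = n_outputs, cycle_edges = cycle_edges,
                 carbon_range = carbon_range,
                 free_dim_target = free_dim_target, seed = seed),
            class = "toy_spec")
}

#' Generate a synthetic carbon-balanced network with a feasible dataset
#'
#' Builds a random irreversible network: a backbone chain
#' input(s) -> P1 -> ... -> Pn -> output(s), additional parallel forward
#' routes (one per surplus free dimension) and recycle edges (one per
#' requested cycle), with random carbon counts and stoichiometric
#' coefficients chosen so every reaction conserves carbon exactly. A
#' ground-truth feasible flux distribution is constructed alongside and the
#' exchange fluxes it implies become the dataset, so the emitted triple
#' (model, dataset, distribution) is feasible by construction; the realized
#' free dimension is verified and generation retries with a shifted seed
#' when it misses the target.
#'
#' @param spec A [toy_spec()].
#' @param max_retries Bounded number of regeneration attempts.
#' @return List `model`, `dataset`, `v` (a `"flux_distribution"`),
#'   `spec`.
#' @export
generate_toy <- function(spec, max_retries = 20) {
  for (try in seq_len(max_retries)) {
    out <- toy_attempt(spec, spec$seed + (try - 1L) * 1000L)
    if (!is.null(out)) return(out)
  }
  stop("toy generation failed after ", max_retries, " retries for spec: ",
       paste(deparse(unclass(spec)), collapse = ""), call. = FALSE)
}

toy_attempt <- function(spec, seed) {
  set.seed(seed)
  np <- spec$n_pivots
  piv <- paste0("P", seq_len(np))
  ins <- paste0("I", seq_len(spec$n_inputs))
  outs <- paste0("O", seq_len(spec$n_outputs))
  carb <- stats::setNames(
    sample(spec$carbon_range[1]:spec$carbon_range[2],
           np + length(ins) + length(outs), replace = TRUE),
    c(piv, ins, outs))
  mets <- lapply(names(carb), function(id) metabolite(id, carbon = carb[[id]]))

  ## carbon-conserving conversion a -> (c(a)/c(b)) b
  conv <- function(id, a, b)
    reaction(id, stats::setNames(1, a),
             stats::setNames(carb[[a]] / carb[[b]], b))
  rxs <- list()
  add <- function(r) rxs[[length(rxs) + 1L]] <<- r

  ## exchanges
  for (i in seq_along(ins))
    add(reaction(paste0("EX_", ins[i]), products = stats::setNames(1, ins[i])))
  for (i in seq_along(outs))
    add(reaction(paste0("EX_", outs[i]), substrates = stats::setNames(1, outs[i])))
  ## inputs feed the first pivot (extra inputs attach to random pivots)
  att_in <- c(1L, if (spec$n_inputs > 1)
    sample.int(np, spec$n_inputs - 1L, replace = TRUE))
  for (i in seq_along(ins))
    add(conv(paste0("U", i), ins[i], piv[att_in[i]]))
  ## backbone chain
  for (k in seq_len(np - 1L))
    add(conv(paste0("B", k), piv[k], piv[k + 1L]))
  ## outputs drawn from the last pivot (extras from random pivots)
  att_out <- c(np, if (spec$n_outputs > 1)
    sample.int(np, spec$n_outputs - 1L, replace = TRUE))
  for (i in seq_along(outs))
    add(conv(paste0("S", i), piv[att_out[i]], outs[i]))
  ## parallel forward routes (extra free dimensions beyond the cycles)
  extra <- spec$free_dim_target - spec$cycle_edges
  if (extra > 0 && np >= 2) for (e in seq_len(extra)) {
    k <- if (np == 2L) 1L else sample.int(np - 1L, 1L)
    add(conv(paste0("F", e), piv[k], piv[k + 1L]))
  }
  ## recycle edges (j -> k with k <= j): each closes one cycle
  if (spec$cycle_edges > 0) for (e in seq_len(spec$cycle_edges)) {
    j <- if (np == 1L) 1L else sample(seq_len(np), 1L)
    k <- if (j == 1L) 1L else sample(seq_len(j), 1L)
    if (j == k) {
      if (np < 2L) return(NULL)
      j <- 2L; k <- 1L
    }
    add(conv(paste0("C", e), piv[j], piv[k]))
  }
  model <- tryCatch(
    metabolic_model(mets, rxs, name = sprintf("toy (seed %d)", seed)),
    error = function(e) NULL)
  if (is.null(model)) return(NULL)
  if (!validate_component_balance(model)$balanced) return(NULL)

  ## ground-truth distribution: start from unit exchanges, route carbon
  ## forward, give recycle/parallel edges a modest share, then repair the
  ## pivot balances by solving the linear system with those fluxes fixed
  rids <- names(model$reactions)
  in_flux <- stats::setNames(stats::runif(length(ins), 1, 5),
                             paste0("EX_", ins))
  fixed <- in_flux
  free_ish <- grep("^(C|F)", rids, value = TRUE)
  for (id in free_ish) fixed[id] <- stats::runif(1, 0.1, 0.5)
  A <- model$S[c(piv, ins, outs), , drop = FALSE]
  b <- rep(0, nrow(A))
  add_fix <- function(id, val) {
    row <- stats::setNames(rep(0, length(rids)), rids)
    row[id] <- 1
    A <<- rbind(A, row); b <<- c(b, val)
  }
  for (id in names(fixed)) add_fix(id, fixed[[id]])
  par <- rref_param(A, b)
  if (!par$consistent) return(NULL)
  ## residual freedom (e.g. splits toward extra outputs): pin it at random
  ## small positive values and re-solve
  if (length(par$free_cols)) {
    for (j in par$free_cols) add_fix(rids[j], stats::runif(1, 0.1, 0.4))
    par <- rref_param(A, b)
    if (!par$consistent || length(par$free_cols)) return(NULL)
  }
  v <- par$x0
  names(v) <- rids
  if (any(v < 1e-9)) return(NULL)

  dataset <- treatment_dataset(
    sprintf("toy-data (seed %d)", seed),
    fluxes = v[grepl("^EX_", rids)])
  sys <- apply_dataset(model, dataset)
  sp <- tryCatch(flux_space(sys), error = function(e) NULL)
  if (is.null(sp) || sp$dimension != spec$free_dim_target) return(NULL)
  list(model = model, dataset = dataset,
       v = flux_distribution(v, "user", "ground truth"), spec = spec)
}

#' Monte-Carlo atom-tracing estimate of the allocation table
#'
#' Independent stochastic oracle for [aio()]: particles of component mass
#' enter through the inputs in proportion to their component inflow, move
#' from metabolite to metabolite by choosing a consuming reaction with
#' probability proportional to its consumption share and then a product
#' with the reaction's allocation ratio, and are absorbed at the sinks.
#' The estimate converges to the exact allocation at rate
#' `1/sqrt(n_particles)`.
#'
#' @param model A balanced [metabolic_model()].
#' @param v Feasible flux vector or `"flux_distribution"`.
#' @param n_particles Total number of particles.
#' @param seed Integer seed.
#' @param component Optional component override.
#' @param step_cap Maximum number of synchronous steps before surviving
#'   particles are declared trapped (a feasibility bug detector: at steady
#'   state a flux-carrying cycle without drain cannot exist).
#' @return List: `estimate` (outputs x inputs matrix), `se` (standard
#'   errors), `n_per_input`, `trapped`.
#' @export
atom_trace_aio <- function(model, v, n_particles = 1e5, seed = 1L,
                           component = NULL, step_cap = 1e6) {
  set.seed(seed)
  st <- aio_structures(model, v, component)
  vv <- st$v; cvec <- st$cvec
  act <- st$active
  exact <- aio(model, vv, component)
  ins <- colnames(exact$matrix); outs <- rownames(exact$matrix)
  ## transition kernel over active metabolites + absorbing sink states
  sink_ids <- vapply(Filter(is_sink, model$reactions),
                     function(r) r$id, "")
  states <- c(act, sink_ids)
  P <- matrix(0, length(act), length(states),
              dimnames = list(act, states))
  for (r in model$reactions) {
    vj <- vv[[r$id]]
    if (vj <= 0 || !length(r$substrates)) next
    subs <- names(r$substrates); subs <- intersect(subs[cvec[subs] > 0], act)
    if (!length(subs)) next
    if (is_sink(r)) {
      m <- subs[1]
      P[m, r$id] <- P[m, r$id] + r$substrates[[1]] * vj / st$Fv[[m]]
      next
    }
    prods <- names(r$products); prods <- intersect(prods[cvec[prods] > 0], act)
    sub_mass <- sum(r$substrates[subs] * cvec[subs])
    if (!length(prods) || sub_mass <= 0) next
    In_r <- r$products[prods] * cvec[prods] / sub_mass
    for (m in subs) {
      share <- r$substrates[[m]] * vj / st$Fv[[m]]
      P[m, prods] <- P[m, prods] + share * In_r
    }
  }
  ## rows may leak mass where carbon exits into zero-carbon species is
  ## impossible (balanced models do not leak); renormalize defensively
  rs <- rowSums(P)
  P <- P / pmax(rs, 1e-12)

  n_in <- stats::setNames(
    as.vector(stats::rmultinom(1, n_particles,
                               exact$input_totals / sum(exact$input_totals))),
    ins)
  est <- matrix(0, length(outs), length(ins), dimnames = list(outs, ins))
  se <- est
  trapped <- 0L
  sink_of <- vapply(Filter(is_sink, model$reactions),
                    function(r) names(r$substrates), "")
  names(sink_of) <- sink_ids
  for (m in ins) {
    counts <- stats::setNames(rep(0, length(states)), states)
    counts[m] <- n_in[[m]]
    step <- 0L
    while (sum(counts[act]) > 0 && step < step_cap) {
      step <- step + 1L
      moved <- stats::setNames(rep(0, length(states)), states)
      for (i in act) {
        ci <- counts[[i]]
        if (ci == 0) next
        moved <- moved + as.vector(stats::rmultinom(1, ci, P[i, ]))
      }
      counts[act] <- moved[act]
      counts[sink_ids] <- counts[sink_ids] + moved[sink_ids]
    }
    trapped <- trapped + sum(counts[act])
    tot <- exact$input_totals[[m]]
    for (s in sink_ids) {
      o <- sink_of[[s]]
      if (!o %in% outs) next
      p_hat <- counts[[s]] / max(n_in[[m]], 1)
      est[o, m] <- est[o, m] + tot * p_hat
      se[o, m] <- se[o, m] +
        tot * sqrt(p_hat * (1 - p_hat) / max(n_in[[m]], 1))
    }
  }
  if (trapped > 0)
    warning(trapped, " particles trapped: flux-carrying cycle without ",
            "drain — check feasibility of v")
  list(estimate = est, se = se, n_per_input = n_in, trapped = trapped)
}

#' Exact allocation by topological propagation (acyclic networks only)
#'
#' Independent oracle valid when the flux-carrying reaction graph is
#' acyclic: carbon fractions are propagated through the metabolites in
#' topological order, which reproduces [aio()] exactly. A cycle in the
#' flux-carrying graph raises an error (use [aio()], which handles
#' cycles).
#'
#' @inheritParams atom_trace_aio
#' @return An outputs x inputs matrix in absolute component units.
#' @export
dag_propagate_aio <- function(model, v, component = NULL) {
  st <- aio_structures(model, v, component)
  act <- st$active
  Aop <- allocation_operator(model, st)
  ## Kahn topological order on the active-metabolite graph
  adj <- Aop > 0
  ## indeg[k] = number of active predecessors of k (edges p -> k)
  indeg <- vapply(act, function(k) sum(adj[k, ] > 0), 0L)
  order <- character()
  queue <- act[indeg == 0]
  indeg2 <- indeg
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    order <- c(order, n)
    succ <- act[adj[, n]]
    for (s2 in succ) {
      indeg2[s2] <- indeg2[s2] - 1L
      if (indeg2[s2] == 0L) queue <- c(queue, s2)
    }
  }
  if (length(order) < length(act))
    stop("flux-carrying cycle detected: topological propagation is not ",
         "applicable, use aio()", call. = FALSE)
  exact_shape <- aio(model, st$v, component)
  ins <- colnames(exact_shape$matrix)
  X <- matrix(0, length(act), length(ins), dimnames = list(act, ins))
  for (m in intersect(ins, act)) X[m, m] <- exact_shape$input_totals[[m]]
  for (k in order) {
    pred <- act[adj[k, ]]
    for (p in pred) X[k, ] <- X[k, ] + Aop[k, p] * X[p, ]
  }
  out <- exact_shape$matrix * 0
  for (r in Filter(is_sink, model$reactions)) {
    o <- names(r$substrates)
    if (!(o %in% rownames(out)) || !(o %in% act) || st$v[[r$id]] <= 0) next
    share <- r$substrates[[1]] * st$v[[r$id]] / st$Fv[[o]]
    out[o, ] <- out[o, ] + share * X[o, ]
  }
  out
}

#' Dense-grid bracketing oracle for min-max of one allocation cell
#'
#' Brute-force twin of the optimization routes, valid for bounded spaces
#' of dimension at most 2: the free-coordinate box is gridded, infeasible
#' points discarded, and the cell evaluated everywhere, yielding inner
#' bounds that converge to the true extrema as the grid refines.
#'
#' @param space A bounded [flux_space()] of dimension <= 2.
#' @param model The model.
#' @param cell `c(output, input)` metabolite ids.
#' @param grid_points Grid resolution per dimension.
#' @param component Optional component override.
#' @return `c(lower, upper)` inner bounds.
#' @export
grid_minmax_oracle <- function(space, model, cell, grid_points = 100,
                               component = NULL) {
  d <- length(space$free_ids)
  if (d > 2) stop("grid oracle is limited to dimension <= 2", call. = FALSE)
  if (!isTRUE(space$bounded)) stop("space must be bounded", call. = FALSE)
  red <- space_reduced(space)
  if (d == 0L) {
    val <- aio_cell_value(model, space$v0, cell[1], cell[2], component)
    return(c(lower = val, upper = val))
  }
  fva <- flux_variability(space, space$free_ids)
  axes <- lapply(seq_len(d), function(k)
    seq(fva$min[k], fva$max[k], length.out = grid_points))
  pts <- as.matrix(expand.grid(axes))
  vals <- c()
  for (i in seq_len(nrow(pts))) {
    lam <- pts[i, ]
    if (any(red$A %*% lam - red$b > 1e-9)) next
    v <- pmax(space_point(space, lam), 0)
    names(v) <- rownames(space$N)
    vals <- c(vals, aio_cell_value(model, v, cell[1], cell[2], component))
  }
  c(lower = min(vals), upper = max(vals))
}
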