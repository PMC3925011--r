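#' Share of a reaction's substrate component recovered in one product
#'
#' Under proportional matter distribution, the fraction of the component
#' (carbon) mass entering a reaction as substrates that is recovered in a
#' given product equals that product's component mass divided by the total
#' substrate component mass.
#'
#' @param r A [reaction()].
#' @param component Named numeric vector of component counts.
#' @param metabolite Metabolite id.
#' @return A ratio in `[0, 1]`; 0 when the metabolite is not a product.
#' @export
reaction_allocation <- function(r, component, metabolite) {
  if (!metabolite %in% names(r$products)) return(0)
  sub_mass <- if (length(r$substrates))
    sum(r$substrates * component[names(r$substrates)]) else 0
  prod_mass <- r$products[[metabolite]] * component[[metabolite]]
  if (sub_mass <= 0) {
    if (length(r$substrates) == 0L) return(1)  # source exchange
    if (prod_mass > 0)
      stop("reaction ", r$id, ": products carry component mass but substrates do not",
           call. = FALSE)
    return(0)
  }
  prod_mass / sub_mass
}

#' Production throughput of a metabolite under a flux distribution
#'
#' Total rate at which a metabolite is produced (source exchanges
#' included); at steady state this equals its total consumption, which is
#' asserted for balanced metabolites.
#'
#' @param model A [metabolic_model()].
#' @param v A flux vector or `"flux_distribution"`.
#' @param metabolite Metabolite id.
#' @param tol Relative steady-state tolerance.
#' @return Nonnegative rate.
#' @export
pivot_throughput <- function(model, v, metabolite, tol = 1e-6) {
  if (inherits(v, "flux_distribution")) v <- v$v
  S <- model$S
  row <- S[metabolite, ]
  vv <- v[colnames(S)]
  prod <- sum(pmax(row, 0) * vv)
  cons <- sum(pmax(-row, 0) * vv)
  balanced <- !(metabolite %in% attr(model, "free_balance"))
  if (balanced && abs(prod - cons) > tol * max(prod, cons, 1))
    stop("steady-state violation at ", metabolite,
         sprintf(": production %.6g != consumption %.6g", prod, cons),
         call. = FALSE)
  prod
}

## internal: everything compute_aio needs, assembled once per (model, v)
aio_structures <- function(model, v, component = NULL, tol = 1e-6,
                           check_steady = TRUE) {
  if (inherits(v, "flux_distribution")) v <- v$v
  cvec <- component_vector(model)
  if (!is.null(component)) cvec[names(component)] <- component
  S <- model$S
  v <- v[colnames(S)]
  eps <- 1e-9 * max(v, 1)
  v[v < eps] <- 0

  ids <- rownames(S)
  carriers <- ids[cvec[ids] > 0]
  ## throughputs (production side), sources included
  Fv <- stats::setNames(as.numeric(pmax(S[carriers, , drop = FALSE], 0) %*% v),
                        carriers)
  if (check_steady) {
    free_bal <- attr(model, "free_balance")
    for (m in setdiff(carriers, free_bal)) {
      cons <- sum(pmax(-S[m, ], 0) * v)
      if (abs(Fv[[m]] - cons) > tol * max(Fv[[m]], cons, 1))
        stop("steady-state violation at ", m, call. = FALSE)
    }
  }
  active <- carriers[Fv > eps]
  list(v = v, cvec = cvec, carriers = carriers, active = active, Fv = Fv)
}

#' Assemble the allocation matrices of the component-flow linear system
#'
#' For a flux distribution `v`, the component (carbon) flow of any single
#' input through the network satisfies a linear fixpoint: the amount
#' recovered in metabolite `k` is the sum, over reactions producing `k`, of
#' the reaction's allocation ratio times the share of each substrate pool
#' the reaction consumes, times the amount in that substrate pool. Writing
#' `x` for the vector over intermediary and output metabolites, the system
#' is `D1 x = -D2 x_I` with `D1 = I - A`: unit diagonal, nonpositive
#' off-diagonal entries whose column sums exceed -1 — an M-matrix, hence
#' invertible, which is what makes the allocation well-defined in the
#' presence of cycles.
#'
#' Zero-throughput metabolites are pruned before assembly (their
#' allocations are zero in the vanishing-flux limit).
#'
#' @param model A [metabolic_model()].
#' @param v Flux vector or `"flux_distribution"`.
#' @param component Optional component override.
#' @return List with `D1` (square, rows/cols = pruned non-input component
#'   carriers), `D2` (columns = input carriers), `pruned`, `inputs`.
#' @export
build_d_matrices <- function(model, v, component = NULL) {
  st <- aio_structures(model, v, component)
  inputs <- intersect(st$active, model$metabolites$id[model$metabolites$role == "input"])
  rest <- setdiff(st$active, inputs)
  Afull <- allocation_operator(model, st)
  D1 <- diag(length(rest)) - Afull[rest, rest, drop = FALSE]
  dimnames(D1) <- list(rest, rest)
  D2 <- -Afull[rest, inputs, drop = FALSE]
  ## construction sanity: proportional distribution cannot route more than
  ## the whole pool
  colsum <- colSums(Afull[, c(rest, inputs), drop = FALSE])
  if (any(colsum > 1 + 1e-7))
    stop("allocation column sum exceeds 1: proportional distribution violated",
         call. = FALSE)
  list(D1 = D1, D2 = D2, pruned = setdiff(st$carriers, st$active),
       inputs = inputs)
}

## A[k, i] = share of metabolite i's component throughput routed to k by
## the internal reactions, summed over reactions (active carriers only)
allocation_operator <- function(model, st) {
  act <- st$active
  n <- length(act)
  A <- matrix(0, n, n, dimnames = list(act, act))
  v <- st$v; cvec <- st$cvec; Fv <- st$Fv
  for (r in model$reactions) {
    vj <- v[[r$id]]
    if (vj <= 0 || !length(r$substrates) || !length(r$products)) next
    subs <- names(r$substrates)
    subs <- subs[cvec[subs] > 0]
    subs <- intersect(subs, act)
    if (!length(subs)) next
    sub_mass <- sum(r$substrates[subs] * cvec[subs])
    if (sub_mass <= 0) next
    prods <- names(r$products)
    prods <- prods[cvec[prods] > 0]
    prods <- intersect(prods, act)
    if (!length(prods)) next
    In_r <- r$products[prods] * cvec[prods] / sub_mass
    for (i in subs) {
      share_i <- r$substrates[[i]] * vj / Fv[[i]]
      A[prods, i] <- A[prods, i] + In_r * share_i
    }
  }
  A
}

#' Allocation of inputs in outputs for one flux distribution
#'
#' Computes, for a steady-state flux distribution of a component-balanced
#' model, the absolute amount of each input's component (carbon) that is
#' recovered in each output flux. The computation solves the M-matrix
#' linear system column-wise (one solve per input), so its cost is cubic in
#' the number of component-carrying metabolites; it is exact in the
#' presence of cycles, where naive pathway tracing fails.
#'
#' @param model A [metabolic_model()] (component-balanced).
#' @param v Flux vector or `"flux_distribution"`.
#' @param component Optional named override of the component counts.
#' @return An object of class `"aio"`: `matrix` (outputs x inputs, absolute
#'   component units), `input_totals`, `output_totals`, `condition_number`
#'   of the solve.
#' @export
aio <- function(model, v, component = NULL) {
  st <- aio_structures(model, v, component)
  v <- st$v; cvec <- st$cvec
  meta <- model$metabolites

  sources <- Filter(function(r) is_source(r) && v[[r$id]] > 0, model$reactions)
  sinks <- Filter(is_sink, model$reactions)
  in_ids <- unique(vapply(sources, function(r) names(r$products), ""))
  in_ids <- in_ids[cvec[in_ids] > 0]
  in_ids <- in_ids[order(match(in_ids, meta$id))]
  out_ids <- vapply(sinks, function(r) names(r$substrates), "")
  names(out_ids) <- vapply(sinks, `[[`, "", "id")
  out_ids <- out_ids[order(match(out_ids, meta$id))]

  input_totals <- vapply(in_ids, function(m) {
    inflow <- sum(vapply(sources, function(r)
      if (names(r$products) == m) r$products[[1]] * v[[r$id]] else 0, 0))
    cvec[[m]] * inflow
  }, 0)

  act <- st$active
  Aop <- allocation_operator(model, st)
  D1 <- diag(length(act)) - Aop
  ## right-hand sides: source injections
  B <- matrix(0, length(act), length(in_ids), dimnames = list(act, in_ids))
  for (m in intersect(in_ids, act)) B[m, m] <- input_totals[[m]]
  X <- solve(D1, B)
  kappa <- kappa(D1, exact = FALSE)
  if (any(X < -1e-6 * max(abs(X), 1)))
    warning("negative allocation encountered; check steady state")
  X[X < 0] <- 0

  ## route pool contents into the sink fluxes
  M <- matrix(0, length(out_ids), length(in_ids),
              dimnames = list(unname(out_ids), in_ids))
  out_tot <- stats::setNames(rep(0, length(out_ids)), unname(out_ids))
  for (k in seq_along(out_ids)) {
    rid <- names(out_ids)[k]; m <- out_ids[[k]]
    r <- model$reactions[[rid]]
    if (cvec[[m]] <= 0 || v[[rid]] <= 0 || !(m %in% act)) next
    share <- r$substrates[[m]] * v[[rid]] / st$Fv[[m]]
    M[k, ] <- M[k, ] + share * X[m, ]
    out_tot[k] <- cvec[[m]] * r$substrates[[m]] * v[[rid]]
  }
  structure(list(matrix = M, input_totals = input_totals,
                 output_totals = out_tot, condition_number = kappa,
                 model_name = model$name),
            class = "aio")
}

#' @rdname aio
#' @export
compute_aio <- aio

#' Percentage views of an allocation table
#'
#' @param x An `"aio"` object.
#' @param view `"percent-output"` (each row sums to 100: origin of each
#'   output's component) or `"percent-input"` (each column sums to 100:
#'   fate of each input's component) or `"absolute"`.
#' @return A numeric matrix.
#' @export
aio_view <- function(x, view = c("percent-output", "percent-input",
                                 "absolute")) {
  view <- match.arg(view)
  M <- x$matrix
  switch(view,
         "absolute" = M,
         "percent-output" = {
           rs <- rowSums(M); rs[rs == 0] <- 1
           100 * M / rs
         },
         "percent-input" = {
           cs <- colSums(M); cs[cs == 0] <- 1
           100 * sweep(M, 2, cs, "/")
         })
}

#' @export
print.aio <- function(x, digits = 1, view = "percent-output", ...) {
  cat(sprintf("Allocation of inputs in outputs (%s), %s view:\n",
              x$model_name, view))
  print(round(aio_view(x, view), digits))
  invisible(x)
}

#' @export
summary.aio <- function(object, ...) {
  cat("Input component totals:\n"); print(round(object$input_totals, 1))
  cat("Output component totals:\n"); print(round(object$output_totals, 1))
  cat(sprintf("Conservation: max |col sum - input| = %.2e, max |row sum - output| = %.2e\n",
              max(abs(colSums(object$matrix) - object$input_totals)),
              max(abs(rowSums(object$matrix) - object$output_totals))))
  cat(sprintf("Condition number of the allocation system: %.3g\n",
              object$condition_number))
  invisible(object)
}

#' @export
as.matrix.aio <- function(x, ...) x$matrix

#' Precursor shares of the synthesized fatty acids
#'
#' Under the primer rules of ruminant mammary fatty-acid synthesis (the C4
#' acid is primed exclusively from beta-hydroxybutyrate; the longer even
#' acids are primed half from a 2-carbon acetate primer and half from the
#' 4-carbon BHBA primer, with all elongation 2-carbon units from acetate),
#' the acetate share of a C(2k:0) acid has the closed form
#' `(2k + (2k - 4)) / (4k)` and the BHBA share `4 / (4k)`.
#'
#' @param x An `"aio"` object from the mammary model (or compatible).
#' @param acetate,bhba Input metabolite ids.
#' @return Data frame: fatty acid, acetate and BHBA percentage of its
#'   carbon, plus the closed-form reference values.
#' @export
fatty_acid_precursors <- function(x, acetate = "AC", bhba = "BHBA") {
  P <- aio_view(x, "percent-output")
  fa <- grep("^C(4|6|8|10|12|14|16)$", rownames(P), value = TRUE)
  fa <- fa[order(as.integer(sub("C", "", fa)))]
  k <- as.integer(sub("C", "", fa)) / 2
  ## C4 is primed exclusively from BHBA; longer acids mix the two primer
  ## pools half-and-half
  ac_cf <- ifelse(k == 2, 0, 100 * (2 * k + (2 * k - 4)) / (4 * k))
  data.frame(fatty_acid = fa,
             acetate = unname(P[fa, acetate]),
             bhba = unname(P[fa, bhba]),
             acetate_closed_form = ac_cf,
             bhba_closed_form = 100 - ac_cf,
             stringsAsFactors = FALSE)
}
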