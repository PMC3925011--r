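## Reduced row echelon form with a caller-chosen column elimination order.
## Returns pivot rows/cols and the nullspace basis in "free coordinate"
## form: basis column k has 1 at its free column and 0 at the others.
rref_param <- function(A, b, col_order = seq_len(ncol(A)), tol = 1e-9) {
  A <- as.matrix(A); m <- nrow(A); n <- ncol(A)
  M <- cbind(A, b)
  piv_rows <- integer(); piv_cols <- integer()
  r <- 1L
  scale <- max(abs(A), 1)
  for (j in col_order) {
    if (r > m) break
    cand <- which.max(abs(M[r:m, j]))
    pr <- r + cand - 1L
    if (abs(M[pr, j]) <= tol * scale) next
    if (pr != r) M[c(r, pr), ] <- M[c(pr, r), ]
    M[r, ] <- M[r, ] / M[r, j]
    others <- setdiff(seq_len(m), r)
    M[others, ] <- M[others, ] - outer(M[others, j], M[r, ])
    piv_rows <- c(piv_rows, r); piv_cols <- c(piv_cols, j)
    r <- r + 1L
  }
  ## inconsistency: zero row with nonzero rhs
  if (r <= m) {
    resid <- M[r:m, n + 1]
    if (any(abs(resid) > 1e-7 * max(scale, abs(b), 1)))
      return(list(consistent = FALSE))
  }
  free_cols <- setdiff(col_order, piv_cols)
  ## particular solution: free vars 0, pivot vars = rhs
  x0 <- rep(0, n)
  x0[piv_cols] <- M[seq_along(piv_cols), n + 1]
  ## nullspace basis
  N <- matrix(0, n, length(free_cols))
  for (k in seq_along(free_cols)) {
    fc <- free_cols[k]
    N[fc, k] <- 1
    N[piv_cols, k] <- -M[seq_along(piv_cols), fc]
  }
  list(consistent = TRUE, x0 = x0, N = N,
       piv_cols = piv_cols, free_cols = free_cols, rank = length(piv_cols))
}

#' Parameterize the space of plausible flux distributions
#'
#' Computes an affine parameterization of the solution set of the equality
#' system built by [apply_dataset()] intersected with `v >= 0`: a feasible
#' particular solution, a nullspace basis whose coordinates are a set of
#' `free` reaction fluxes that determine all others, the boundedness of the
#' polyhedron and its effective dimension (free directions that are frozen
#' by nonnegativity in both senses are not counted).
#'
#' @param system A `"flux_system"` from [apply_dataset()].
#' @param prefer_free Optional character vector of reaction ids to prefer as
#'   the reported independent coordinates. Any maximal independent subset of
#'   fluxes is an equivalent coordinate system; this merely moves the named
#'   columns to the end of the elimination order so that, when they are
#'   independent, they are the ones reported.
#' @param tol Numerical tolerance for the elimination.
#' @return An object of class `"flux_space"`.
#' @export
flux_space <- function(system, prefer_free = NULL, tol = 1e-9) {
  stopifnot(inherits(system, "flux_system"))
  rids <- colnames(system$A_eq)
  ord <- seq_along(rids)
  if (!is.null(prefer_free)) {
    idx <- match(prefer_free, rids)
    idx <- idx[!is.na(idx)]
    ord <- c(setdiff(ord, idx), idx)
  }
  par <- rref_param(system$A_eq, system$b_eq, col_order = ord, tol = tol)
  if (!par$consistent)
    stop("equality system is inconsistent (contradictory constraints)",
         call. = FALSE)
  free_ids <- rids[par$free_cols]
  N <- par$N
  rownames(N) <- rids; colnames(N) <- free_ids
  d <- length(free_ids)

  ## feasible particular solution (v >= 0): LP on the full system
  v0 <- par$x0
  if (d == 0L) {
    if (any(v0 < -1e-7 * max(abs(v0), 1)))
      stop("system is infeasible: unique solution has negative fluxes",
           call. = FALSE)
    v0 <- pmax(v0, 0)
  } else if (any(v0 < -1e-9)) {
    ## feasibility restored in the reduced coordinates: find lambda with
    ## v0 + N (lambda - lam0) >= 0 (small LP, robust)
    lam0 <- v0[par$free_cols]
    bred <- as.numeric(v0 - N %*% lam0)
    keep <- rowSums(abs(N)) > 1e-12
    Ared <- -N[keep, , drop = FALSE]
    lam <- lp_feasible_point(A_ub = cbind(Ared, -Ared), b_ub = bred[keep],
                             n = 2 * d)
    if (is.null(lam))
      stop("system is infeasible: no nonnegative flux vector satisfies the constraints",
           call. = FALSE)
    lam <- lam[seq_len(d)] - lam[d + seq_len(d)]
    v0 <- pmax(as.numeric(v0 + N %*% (lam - lam0)), 0)
  }
  names(v0) <- rids

  sp <- structure(list(system = system, v0 = v0, N = N,
                       free_ids = free_ids,
                       extra_A = NULL, extra_b = NULL,
                       bounded = NA, dimension = NA_integer_),
                  class = "flux_space")
  sp <- space_finalize(sp, tol = tol)
  sp
}

## reduced inequality representation A_red lambda <= b_red
## (lambda are the free flux coordinates, absolute values)
space_reduced <- function(space) {
  v0 <- space$v0; N <- space$N
  lam0 <- v0[space$free_ids]
  ## v = v0 + N (lambda - lam0) >= 0  ->  -N lambda <= v0 - N lam0
  b <- as.numeric(v0 - N %*% lam0)
  keep <- rowSums(abs(N)) > 1e-12
  A_red <- -N[keep, , drop = FALSE]
  b_red <- b[keep]
  names(b_red) <- rownames(N)[keep]
  if (!is.null(space$extra_A)) {
    A_red <- rbind(A_red, space$extra_A)
    b_red <- c(b_red, space$extra_b)
  }
  list(A = A_red, b = b_red, lam0 = lam0)
}

## point in full flux coordinates from free coordinates
space_point <- function(space, lambda) {
  as.numeric(space$v0 + space$N %*% (lambda - space$v0[space$free_ids]))
}

## LP over the reduced space: max/min c_red' lambda (+ free-sign lambda via
## split variables). Returns status/value/lambda.
space_lp <- function(space, c_red, maximize = TRUE) {
  red <- space_reduced(space)
  d <- length(c_red)
  A2 <- cbind(red$A, -red$A)
  res <- solve_lp(c(c_red, -c_red), A_ub = A2, b_ub = red$b,
                  maximize = maximize)
  if (!identical(res$status, "optimal")) return(res)
  lam <- res$x[seq_len(d)] - res$x[d + seq_len(d)]
  list(status = "optimal", value = sum(c_red * lam), lambda = lam)
}

space_finalize <- function(space, tol = 1e-9) {
  d <- length(space$free_ids)
  if (d == 0L) {
    space$bounded <- TRUE; space$dimension <- 0L
    return(space)
  }
  red <- space_reduced(space)
  ## boundedness: a recession direction u != 0 with A u <= 0 exists iff it
  ## exists with some coordinate pushed to +-1 (test 2d small LPs)
  A2 <- cbind(red$A, -red$A)
  unbounded <- FALSE
  for (k in seq_len(d)) {
    for (s in c(1, -1)) {
      ck <- rep(0, d); ck[k] <- s
      cap <- matrix(c(ck, -ck), 1)
      res <- solve_lp(c(ck, -ck),
                      A_ub = rbind(A2, cap),
                      b_ub = c(rep(0, nrow(A2)), 1),
                      maximize = TRUE, check_unbounded = FALSE)
      if (identical(res$status, "optimal") && res$value > 1e-7) {
        unbounded <- TRUE; break
      }
    }
    if (unbounded) break
  }
  space$bounded <- !unbounded
  ## effective dimension: free directions with nonzero feasible width
  width <- vapply(seq_len(d), function(k) {
    ck <- rep(0, d); ck[k] <- 1
    up <- space_lp(space, ck, maximize = TRUE)
    dn <- space_lp(space, ck, maximize = FALSE)
    hi <- if (identical(up$status, "unbounded")) Inf else up$value
    lo <- if (identical(dn$status, "unbounded")) -Inf else dn$value
    hi - lo
  }, 0)
  space$dimension <- sum(width > 1e-7)
  space
}

#' @export
print.flux_space <- function(x, ...) {
  cat(sprintf("Flux space '%s': dimension %d (%s), free variables: %s\n",
              x$system$dataset$name, x$dimension,
              if (isTRUE(x$bounded)) "bounded" else "unbounded",
              paste(x$free_ids, collapse = ", ")))
  invisible(x)
}

#' One plausible flux distribution
#'
#' @param v Named nonnegative flux vector.
#' @param provenance How the point was obtained (`"vertex"`, `"interior"`,
#'   `"user"`, `"optimum"`).
#' @param objective Optional description of the optimized objective.
#' @return An object of class `"flux_distribution"`.
#' @export
flux_distribution <- function(v, provenance = "user", objective = NULL) {
  structure(list(v = v, provenance = provenance, objective = objective),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("Flux distribution (%s%s): %d reactions, %d active\n",
              x$provenance,
              if (!is.null(x$objective)) paste0(", ", x$objective) else "",
              length(x$v), sum(x$v > 1e-9)))
  invisible(x)
}

#' ATP (or any free-balance species) net balance of a flux distribution
#'
#' The net production minus consumption of a bookkeeping species implied by
#' a flux distribution; linear in the fluxes.
#'
#' @param v A `"flux_distribution"` or named flux vector.
#' @param model The model.
#' @param species Species id, default `"ATP"`.
#' @return A number in the flux unit of `v`.
#' @export
atp_balance <- function(v, model, species = "ATP") {
  if (inherits(v, "flux_distribution")) v <- v$v
  if (!species %in% rownames(model$S))
    stop("model has no species '", species, "'", call. = FALSE)
  as.numeric(model$S[species, , drop = FALSE] %*% v[colnames(model$S)])
}

#' Optimize a linear flux objective (flux balance analysis)
#'
#' @param space A [flux_space()].
#' @param objective Named numeric vector of coefficients over reaction ids
#'   (missing ids are zero), or a single reaction id.
#' @param sense `"max"` or `"min"`.
#' @return A `"flux_distribution"` with provenance `"optimum"` and an
#'   attribute `status`; when the objective is unbounded over the space the
#'   status is `"unbounded"` and the distribution is `NULL`-valued.
#' @export
fba_optimize <- function(space, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  rids <- rownames(space$N)
  if (is.character(objective))
    objective <- stats::setNames(rep(1, length(objective)), objective)
  cfull <- stats::setNames(rep(0, length(rids)), rids)
  cfull[names(objective)] <- objective
  c_red <- as.numeric(crossprod(space$N, cfull))
  cst <- sum(cfull * space_point(space, space$v0[space$free_ids]) * 0) +
    sum(cfull * space$v0) - sum(c_red * space$v0[space$free_ids])
  res <- space_lp(space, c_red, maximize = sense == "max")
  if (identical(res$status, "unbounded")) {
    out <- flux_distribution(NULL, provenance = "optimum",
                             objective = "unbounded")
    attr(out, "status") <- "unbounded"
    attr(out, "value") <- if (sense == "max") Inf else -Inf
    return(out)
  }
  if (!identical(res$status, "optimal"))
    stop("LP failed: ", res$status, call. = FALSE)
  v <- pmax(space_point(space, res$lambda), 0)
  names(v) <- rids
  out <- flux_distribution(v, provenance = "optimum",
                           objective = paste0(sense, " ",
                                              paste(names(objective), collapse = "+")))
  attr(out, "status") <- "optimal"
  attr(out, "value") <- cst + res$value
  out
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux over the space.
#'
#' @param space A [flux_space()].
#' @param reactions Character vector of reaction ids (default: the free
#'   variables of the space).
#' @return Data frame with columns `reaction`, `min`, `max` (`Inf` where
#'   unbounded above).
#' @export
flux_variability <- function(space, reactions = space$free_ids) {
  rids <- rownames(space$N)
  res <- lapply(reactions, function(id) {
    cfull <- stats::setNames(rep(0, length(rids)), rids)
    cfull[id] <- 1
    c_red <- as.numeric(crossprod(space$N, cfull))
    cst <- unname(space$v0[id]) - sum(c_red * space$v0[space$free_ids])
    lo <- space_lp(space, c_red, maximize = FALSE)
    hi <- space_lp(space, c_red, maximize = TRUE)
    pick <- function(r, sgn) {
      if (identical(r$status, "unbounded")) return(sgn * Inf)
      if (!identical(r$status, "optimal")) return(NA_real_)
      cst + r$value
    }
    c(min = pick(lo, -1), max = pick(hi, 1))
  })
  out <- data.frame(reaction = reactions,
                    min = vapply(res, `[[`, 0, "min"),
                    max = vapply(res, `[[`, 0, "max"),
                    stringsAsFactors = FALSE)
  out$min[abs(out$min) < 1e-9] <- 0
  rownames(out) <- NULL
  out
}

#' Constrain the ATP balance of the space
#'
#' Adds the estimated whole-organ ATP balance as a constraint: an equality
#' at `target` when `tolerance_fraction` is zero, otherwise the band
#' `target * (1 -/+ tolerance_fraction)` as two inequalities.
#'
#' @param space A [flux_space()].
#' @param target Nonnegative target balance (same unit as the fluxes).
#' @param tolerance_fraction Relative half-width of the admitted band.
#' @param species Balance species id, default `"ATP"`.
#' @return A re-parameterized [flux_space()].
#' @export
add_atp_constraint <- function(space, target, tolerance_fraction = 0,
                               species = "ATP") {
  stopifnot(target >= 0)
  system <- space$system
  model <- system$model
  atp_row <- model$S[species, colnames(system$A_eq), drop = FALSE]
  if (tolerance_fraction == 0) {
    A <- rbind(system$A_eq, atp_row)
    rownames(A)[nrow(A)] <- paste0("balance:", species)
    system2 <- system
    system2$A_eq <- A
    system2$b_eq <- c(system$b_eq, target)
    out <- tryCatch(
      flux_space(system2, prefer_free = space$free_ids),
      error = function(e)
        stop("ATP constraint makes the space empty: ", conditionMessage(e),
             call. = FALSE))
    return(out)
  }
  ## inequality band in reduced coordinates of the existing parameterization
  c_red <- as.numeric(atp_row %*% space$N)
  cst <- as.numeric(atp_row %*% space$v0) -
    sum(c_red * space$v0[space$free_ids])
  lo <- target * (1 - tolerance_fraction)
  hi <- target * (1 + tolerance_fraction)
  extra_A <- rbind(space$extra_A, c_red, -c_red)
  extra_b <- c(space$extra_b, hi - cst, cst - lo)
  out <- space
  out$extra_A <- extra_A; out$extra_b <- extra_b
  rownames(out$extra_A) <- NULL
  red <- space_reduced(out)
  feas <- lp_feasible_point(A_ub = cbind(red$A, -red$A), b_ub = red$b,
                            n = 2 * length(space$free_ids))
  if (is.null(feas))
    stop("ATP constraint makes the space empty", call. = FALSE)
  lam <- feas[seq_along(space$free_ids)] - feas[-seq_along(space$free_ids)]
  out$v0 <- stats::setNames(pmax(space_point(space, lam), 0), rownames(space$N))
  space_finalize(out)
}

#' Chebyshev ball of a bounded flux space
#'
#' Largest ball (in the metric of the free flux coordinates) inscribed in
#' the reduced-coordinate polytope; its center is a most-interior flux
#' distribution used to seed interior searches and to parameterize the
#' boundary by angles.
#'
#' @param space A bounded [flux_space()].
#' @return List with `center` (a `"flux_distribution"`), `lambda` (free
#'   coordinates of the center) and `radius`.
#' @export
chebyshev_ball <- function(space) {
  d <- length(space$free_ids)
  if (d == 0L || space$dimension == 0L) {
    warning("degenerate space: radius 0")
    return(list(center = flux_distribution(space$v0, "interior"),
                lambda = space$v0[space$free_ids], radius = 0))
  }
  if (!isTRUE(space$bounded))
    stop("Chebyshev ball requires a bounded space", call. = FALSE)
  red <- space_reduced(space)
  nrm <- sqrt(rowSums(red$A^2))
  keep <- nrm > 1e-12
  A <- red$A[keep, , drop = FALSE]; b <- red$b[keep]; nrm <- nrm[keep]
  ## vars: lambda+ (d), lambda- (d), r ; maximize r
  Aub <- cbind(A, -A, nrm)
  obj <- c(rep(0, 2 * d), 1)
  res <- solve_lp(obj, A_ub = Aub, b_ub = b, maximize = TRUE,
                  check_unbounded = FALSE)
  if (!identical(res$status, "optimal"))
    stop("Chebyshev LP failed: ", res$status, call. = FALSE)
  lam <- res$x[seq_len(d)] - res$x[d + seq_len(d)]
  names(lam) <- space$free_ids
  v <- pmax(space_point(space, lam), 0)
  names(v) <- rownames(space$N)
  list(center = flux_distribution(v, "interior", "Chebyshev center"),
       lambda = lam, radius = res$value)
}
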