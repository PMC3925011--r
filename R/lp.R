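## Internal linear-programming layer.
##
## All polyhedra handled by the package are of the form
##   { x >= 0 : A_eq x = b_eq, A_ub x <= b_ub }.
## boot::simplex() is the engine; it requires nonnegative right-hand sides
## (rows are flipped as needed) and it does not return gracefully on
## unbounded problems, so unboundedness is detected first with a
## recession-cone auxiliary LP (max c'd s.t. A_eq d = 0, A_ub d <= 0,
## d >= 0, c'd <= 1), which is bounded by construction.

lp_canonical <- function(obj, A_eq = NULL, b_eq = NULL,
                         A_ub = NULL, b_ub = NULL) {
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL; A3 <- NULL; b3 <- NULL
  if (!is.null(A_ub) && nrow(A_ub)) {
    neg <- b_ub < 0
    if (any(!neg)) { A1 <- A_ub[!neg, , drop = FALSE]; b1 <- b_ub[!neg] }
    if (any(neg))  { A2 <- -A_ub[neg, , drop = FALSE]; b2 <- -b_ub[neg] }
  }
  if (!is.null(A_eq) && nrow(A_eq)) {
    neg <- b_eq < 0
    A3 <- A_eq; b3 <- b_eq
    if (any(neg)) { A3[neg, ] <- -A3[neg, , drop = FALSE]; b3[neg] <- -b3[neg] }
  }
  list(A1 = A1, b1 = b1, A2 = A2, b2 = b2, A3 = A3, b3 = b3)
}

simplex_call <- function(obj, cn, maxi, eps = 1e-9, n.iter = NULL) {
  n <- length(obj)
  if (is.null(n.iter))
    n.iter <- 50 * (n + length(cn$b1) + length(cn$b2) + length(cn$b3))
  res <- tryCatch(
    boot::simplex(a = obj, A1 = cn$A1, b1 = cn$b1, A2 = cn$A2, b2 = cn$b2,
                  A3 = cn$A3, b3 = cn$b3, maxi = maxi,
                  n.iter = n.iter, eps = eps),
    error = function(e) NULL)
  if (is.null(res)) return(list(status = "error", x = NULL, value = NA_real_))
  status <- switch(as.character(res$solved),
                   "1" = "optimal", "0" = "iteration-limit", "infeasible")
  list(status = status, x = as.numeric(res$soln), value = res$value)
}

## Solve max/min obj'x over {x >= 0, A_eq x = b_eq, A_ub x <= b_ub}.
## Returns list(status, x, value); status one of
## optimal / unbounded / infeasible / error.
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     maximize = TRUE, check_unbounded = TRUE) {
  obj <- as.numeric(obj)
  cn <- lp_canonical(obj, A_eq, b_eq, A_ub, b_ub)
  if (check_unbounded && any(obj != 0)) {
    sgn <- if (maximize) 1 else -1
    rays_eq <- A_eq
    ray_ub <- rbind(A_ub, matrix(sgn * obj, 1))
    bray_ub <- c(if (is.null(A_ub)) NULL else rep(0, nrow(A_ub)), 1)
    cnr <- lp_canonical(sgn * obj,
                        A_eq = rays_eq,
                        b_eq = if (is.null(rays_eq)) NULL else rep(0, nrow(rays_eq)),
                        A_ub = ray_ub, b_ub = bray_ub)
    aux <- simplex_call(sgn * obj, cnr, maxi = TRUE)
    if (identical(aux$status, "optimal") && aux$value > 1e-7) {
      ## feasibility still needs confirming before declaring unbounded
      feas <- simplex_call(rep(0, length(obj)), cn, maxi = TRUE)
      if (identical(feas$status, "infeasible"))
        return(list(status = "infeasible", x = NULL, value = NA_real_))
      return(list(status = "unbounded", x = NULL,
                  value = if (maximize) Inf else -Inf, ray = aux$x))
    }
  }
  res <- simplex_call(obj, cn, maxi = maximize)
  res
}

## Feasible point of {x >= 0, A_eq x = b_eq, A_ub x <= b_ub}, or NULL.
lp_feasible_point <- function(A_eq = NULL, b_eq = NULL,
                              A_ub = NULL, b_ub = NULL, n = NULL) {
  if (is.null(n)) n <- if (!is.null(A_eq)) ncol(A_eq) else ncol(A_ub)
  cn <- lp_canonical(rep(0, n), A_eq, b_eq, A_ub, b_ub)
  res <- simplex_call(rep(0, n), cn, maxi = TRUE)
  if (!identical(res$status, "optimal")) return(NULL)
  res$x
}
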