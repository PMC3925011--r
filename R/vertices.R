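#' Enumerate the vertices of a bounded flux space
#'
#' Two routes are provided. `"sampling"` optimizes many linear objectives
#' over the polytope — the canonical coordinate directions of the free
#' variables, all pairwise sum/difference combinations of them, and random
#' unit-sphere objectives — collecting the distinct optimal basic solutions;
#' sampling stops early when a window of consecutive draws yields nothing
#' new. `"exact"` intersects all subsets of `d` facets of the reduced
#' polytope (practical for dimension <= 4) and keeps the feasible
#' intersections; it is the brute-force oracle the sampler is verified
#' against.
#'
#' For an unbounded space, set `rays = TRUE` to enumerate the extreme rays
#' of the recession cone instead (facet brute force on the cone section).
#'
#' @param space A [flux_space()].
#' @param n_objectives Number of random objectives for the sampler.
#' @param seed Integer seed (mandatory for reproducibility of the sampler).
#' @param method `"sampling"` or `"exact"`.
#' @param window Early-stopping window of consecutive non-novel draws.
#' @param tol Relative deduplication tolerance on the flux vectors.
#' @param rays Enumerate extreme rays of an unbounded cone instead.
#' @return An object of class `"vertex_set"`: list of `"flux_distribution"`
#'   vertices with per-vertex `objective` records, plus the free-coordinate
#'   matrix `lambda` (vertices in rows).
#' @export
enumerate_vertices <- function(space, n_objectives = 2000, seed = 1L,
                               method = c("sampling", "exact"),
                               window = 500, tol = 1e-6, rays = FALSE) {
  method <- match.arg(method)
  d <- length(space$free_ids)
  if (rays) return(enumerate_rays(space, tol = tol))
  if (!isTRUE(space$bounded))
    stop("space is unbounded: enumerate extreme rays instead (rays = TRUE)",
         call. = FALSE)
  if (d == 0L) {
    vs <- list(flux_distribution(space$v0, "vertex", "point space"))
    return(structure(list(vertices = vs,
                          lambda = matrix(numeric(), 1, 0)),
                     class = "vertex_set"))
  }
  if (method == "exact") return(vertices_exact(space, tol = tol))

  set.seed(seed)
  objs <- list()
  for (k in seq_len(d)) {
    ek <- rep(0, d); ek[k] <- 1
    objs <- c(objs, list(ek, -ek))
  }
  if (d >= 2) for (i in seq_len(d - 1)) for (j in (i + 1):d)
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      e <- rep(0, d); e[i] <- s1; e[j] <- s2
      objs <- c(objs, list(e))
    }
  lam_mat <- NULL
  found_by <- character()
  scale_ref <- max(abs(space$v0), 1)
  add_vertex <- function(lam, label) {
    if (is.null(lam_mat)) {
      lam_mat <<- matrix(lam, 1); found_by <<- label; return(TRUE)
    }
    dd <- sqrt(rowSums((lam_mat - matrix(lam, nrow(lam_mat), d,
                                         byrow = TRUE))^2))
    if (all(dd > tol * scale_ref)) {
      lam_mat <<- rbind(lam_mat, lam); found_by <<- c(found_by, label)
      return(TRUE)
    }
    FALSE
  }
  miss <- 0L
  n_drawn <- 0L
  obj_label <- function(e) {
    nz <- which(e != 0)
    if (length(nz) > 3) return("random")
    paste(sprintf("%+g*%s", e[nz], space$free_ids[nz]), collapse = " ")
  }
  repeat {
    if (length(objs)) {
      e <- objs[[1]]; objs <- objs[-1]; lab <- obj_label(e)
    } else {
      if (n_drawn >= n_objectives || miss >= window) break
      e <- stats::rnorm(d); e <- e / sqrt(sum(e^2))
      n_drawn <- n_drawn + 1L; lab <- "random"
    }
    res <- space_lp(space, e, maximize = TRUE)
    if (!identical(res$status, "optimal")) next
    new <- add_vertex(res$lambda, lab)
    miss <- if (new) 0L else miss + 1L
  }
  vertex_set_from_lambda(space, lam_mat, found_by)
}

vertex_set_from_lambda <- function(space, lam_mat, found_by = NULL) {
  ord <- do.call(order, as.data.frame(round(lam_mat, 6)))
  lam_mat <- lam_mat[ord, , drop = FALSE]
  if (!is.null(found_by)) found_by <- found_by[ord]
  vs <- lapply(seq_len(nrow(lam_mat)), function(i) {
    v <- pmax(space_point(space, lam_mat[i, ]), 0)
    names(v) <- rownames(space$N)
    flux_distribution(v, "vertex",
                      if (!is.null(found_by)) found_by[i] else NULL)
  })
  colnames(lam_mat) <- space$free_ids
  rownames(lam_mat) <- NULL
  structure(list(vertices = vs, lambda = lam_mat), class = "vertex_set")
}

vertices_exact <- function(space, tol = 1e-6) {
  d <- length(space$free_ids)
  red <- space_reduced(space)
  A <- red$A; b <- red$b
  ## deduplicate facet rows (normalize)
  nrm <- sqrt(rowSums(A^2))
  keep <- nrm > 1e-12
  A <- A[keep, , drop = FALSE] / nrm[keep]; b <- b[keep] / nrm[keep]
  key <- apply(round(cbind(A, b), 9), 1, paste, collapse = "|")
  uni <- !duplicated(key)
  A <- A[uni, , drop = FALSE]; b <- b[uni]
  m <- nrow(A)
  if (m < d) stop("polytope has too few facets; is the space bounded?")
  combos <- utils::combn(m, d)
  lam_mat <- NULL
  scale_ref <- max(abs(space$v0), 1)
  for (ci in seq_len(ncol(combos))) {
    idx <- combos[, ci]
    Ai <- A[idx, , drop = FALSE]
    if (abs(det(Ai)) < 1e-10) next
    lam <- try(solve(Ai, b[idx]), silent = TRUE)
    if (inherits(lam, "try-error")) next
    if (any(A %*% lam - b > 1e-7 * scale_ref)) next
    if (is.null(lam_mat)) lam_mat <- matrix(lam, 1)
    else {
      dd <- sqrt(rowSums((lam_mat - matrix(lam, nrow(lam_mat), d,
                                           byrow = TRUE))^2))
      if (all(dd > tol * scale_ref)) lam_mat <- rbind(lam_mat, lam)
    }
  }
  if (is.null(lam_mat)) stop("no vertex found; space may be empty")
  vertex_set_from_lambda(space, lam_mat)
}

enumerate_rays <- function(space, tol = 1e-6) {
  d <- length(space$free_ids)
  red <- space_reduced(space)
  A <- red$A
  nrm <- sqrt(rowSums(A^2))
  keep <- nrm > 1e-12
  A <- A[keep, , drop = FALSE] / nrm[keep]
  key <- apply(round(A, 9), 1, paste, collapse = "|")
  A <- A[!duplicated(key), , drop = FALSE]
  m <- nrow(A)
  rays <- NULL
  if (d == 1L) {
    for (s in c(1, -1)) if (all(A %*% s <= 1e-9)) rays <- rbind(rays, s)
  } else {
    combos <- utils::combn(m, d - 1L)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      ns <- nullspace_basis(A[idx, , drop = FALSE])
      if (is.null(ns) || ncol(ns) != 1L) next
      for (s in c(1, -1)) {
        u <- s * ns[, 1]
        if (all(A %*% u <= 1e-9)) {
          u <- u / sqrt(sum(u^2))
          if (is.null(rays)) rays <- matrix(u, 1)
          else {
            dd <- sqrt(rowSums((rays - matrix(u, nrow(rays), d,
                                              byrow = TRUE))^2))
            if (all(dd > tol)) rays <- rbind(rays, u)
          }
        }
      }
    }
  }
  if (is.null(rays)) rays <- matrix(numeric(), 0, d)
  colnames(rays) <- space$free_ids
  structure(list(rays = rays, unbounded = TRUE), class = "ray_set")
}

nullspace_basis <- function(M, tol = 1e-9) {
  s <- svd(M, nv = ncol(M))
  r <- sum(s$d > tol * max(s$d, 1))
  if (r == ncol(M)) return(NULL)
  s$v[, (r + 1):ncol(M), drop = FALSE]
}

#' @export
print.vertex_set <- function(x, ...) {
  cat(sprintf("Vertex set: %d extreme flux distributions over (%s)\n",
              length(x$vertices), paste(colnames(x$lambda), collapse = ", ")))
  print(round(x$lambda, 3))
  invisible(x)
}
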