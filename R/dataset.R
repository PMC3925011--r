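#' Create a treatment dataset
#'
#' A treatment dataset pins the measured exchange fluxes of a model (net
#' uptakes and secretions), forces a set of reactions to zero and adds
#' homogeneous linear side constraints expressing biological knowledge
#' (e.g. a fixed ratio between two pathway fluxes).
#'
#' @param name Dataset name (e.g. `"Ctrl"`).
#' @param fluxes Named numeric vector: reaction id -> fixed rate
#'   (mmol/h/half-udder by convention). All values must be nonnegative.
#' @param side_constraints List of named numeric vectors; each vector `w`
#'   encodes the homogeneous equation `sum(w * v[names(w)]) = 0`.
#' @param zeroed Character vector of reaction ids forced to zero.
#' @param unit Unit the rates are expressed in.
#' @return An object of class `"treatment_dataset"`.
#' @export
treatment_dataset <- function(name, fluxes = numeric(),
                              side_constraints = list(),
                              zeroed = character(),
                              unit = "mmol/h/half-udder") {
  if (length(fluxes)) {
    stopifnot(!is.null(names(fluxes)), all(nzchar(names(fluxes))))
    if (any(fluxes < 0)) stop("fixed rates must be nonnegative", call. = FALSE)
  }
  for (w in side_constraints)
    stopifnot(is.numeric(w), !is.null(names(w)))
  structure(list(name = name, fluxes = fluxes,
                 side_constraints = side_constraints,
                 zeroed = zeroed, unit = unit),
            class = "treatment_dataset")
}

#' @export
print.treatment_dataset <- function(x, ...) {
  cat(sprintf("Treatment dataset '%s': %d fixed fluxes, %d side constraints, %d zeroed reactions [%s]\n",
              x$name, length(x$fluxes), length(x$side_constraints),
              length(x$zeroed), x$unit))
  invisible(x)
}

#' Convert between the flux units of the lactation datasets
#'
#' Whole-udder daily moles and half-udder hourly millimoles are the two
#' units in which mammary net-uptake data are commonly reported;
#' `mol/d/udder * 1000 / 48 = mmol/h/half-udder` (24 h, two udder halves).
#'
#' @param rate Numeric rate(s).
#' @param from,to Units, each one of `"mol/d/udder"`,
#'   `"mmol/h/half-udder"`.
#' @return Converted numeric rate(s) (unrounded; display rounding is the
#'   caller's concern).
#' @export
unit_convert <- function(rate, from, to) {
  norm <- function(u) {
    u <- gsub("\\s+", "", tolower(u))
    u <- gsub("halfudder", "half-udder", u)
    if (u %in% c("mol/d/udder", "mol/day/udder")) return("mol/d/udder")
    if (u %in% c("mmol/h/half-udder", "mmol/hour/half-udder"))
      return("mmol/h/half-udder")
    stop("unknown unit: ", u, call. = FALSE)
  }
  from <- norm(from); to <- norm(to)
  if (from == to) return(rate)
  if (from == "mol/d/udder") rate * 1000 / 48 else rate * 48 / 1000
}

#' Apply a treatment dataset to a model
#'
#' Builds the full equality system of plausible flux distributions: the
#' steady-state rows of the stoichiometric matrix for every balanced
#' metabolite, the homogeneous side constraints, and one row per fixed or
#' zeroed reaction flux; together with nonnegativity `v >= 0` this is the
#' polyhedron explored by [flux_space()].
#'
#' @param model A [metabolic_model()].
#' @param dataset A [treatment_dataset()]; an empty dataset yields the
#'   stoichiometric rows only.
#' @return An object of class `"flux_system"` with fields `A_eq`, `b_eq`
#'   (labelled rows), `model`, `dataset`.
#' @export
apply_dataset <- function(model, dataset = treatment_dataset("empty")) {
  rids <- names(model$reactions)
  bad <- setdiff(c(names(dataset$fluxes), dataset$zeroed,
                   unlist(lapply(dataset$side_constraints, names))), rids)
  if (length(bad))
    stop("dataset references unknown reaction(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)

  free_bal <- attr(model, "free_balance")
  balanced <- setdiff(model$metabolites$id, free_bal)
  A <- model$S[balanced, , drop = FALSE]
  b <- rep(0, nrow(A))
  rn <- paste0("ss:", balanced)

  for (k in seq_along(dataset$side_constraints)) {
    w <- dataset$side_constraints[[k]]
    row <- stats::setNames(rep(0, length(rids)), rids)
    row[names(w)] <- w
    A <- rbind(A, row); b <- c(b, 0)
    rn <- c(rn, paste0("side:", paste(names(w), collapse = ",")))
  }

  fixed <- dataset$fluxes
  zero_add <- setdiff(dataset$zeroed, names(fixed))
  fixed <- c(fixed, stats::setNames(rep(0, length(zero_add)), zero_add))
  contradict <- intersect(dataset$zeroed, names(dataset$fluxes))
  contradict <- contradict[dataset$fluxes[contradict] != 0]
  if (length(contradict))
    stop("contradictory fixed values for reaction(s): ",
         paste(contradict, collapse = ", "), call. = FALSE)
  for (id in names(fixed)) {
    row <- stats::setNames(rep(0, length(rids)), rids)
    row[id] <- 1
    A <- rbind(A, row); b <- c(b, fixed[[id]])
    rn <- c(rn, paste0("fix:", id))
  }
  rownames(A) <- rn; colnames(A) <- rids
  structure(list(A_eq = A, b_eq = unname(b), model = model,
                 dataset = dataset, fixed = fixed),
            class = "flux_system")
}

#' @export
print.flux_system <- function(x, ...) {
  cat(sprintf("Constrained flux system '%s' on model '%s': %d reactions, %d equality rows (+ v >= 0)\n",
              x$dataset$name, x$model$name, ncol(x$A_eq), nrow(x$A_eq)))
  invisible(x)
}
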