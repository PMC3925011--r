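#' Create a metabolite
#'
#' A metabolite is identified by an id, carries a human-readable name, a role
#' within the network boundary and the number of atoms of the matter
#' component under study (carbon by default) per molecule.
#'
#' @param id Character scalar, unique identifier.
#' @param name Character scalar, display name (defaults to `id`).
#' @param role One of `"input"`, `"pivot"`, `"output"`. Inputs are taken up
#'   by the system, outputs are secreted, pivots are intermediary metabolites
#'   that must not accumulate (production = consumption at steady state).
#' @param carbon Nonnegative number: component atoms per molecule (0 for
#'   bookkeeping species such as cofactors, ATP or peptide links).
#' @return An object of class `"metabolite"`.
#' @export
metabolite <- function(id, name = id, role = c("pivot", "input", "output"),
                       carbon = 0) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(carbon), length(carbon) == 1L, carbon >= 0)
  structure(list(id = id, name = name, role = role, carbon = carbon),
            class = "metabolite")
}

#' Create an irreversible reaction
#'
#' Reactions are irreversible by construction; a reversible biochemical step
#' is represented by two reactions. A metabolite may not appear on both
#' sides of one reaction and every stoichiometric coefficient is strictly
#' positive.
#'
#' @param id Character scalar, unique identifier.
#' @param substrates Named numeric vector of substrate coefficients (may be
#'   empty for a pure source exchange).
#' @param products Named numeric vector of product coefficients (may be
#'   empty for a pure sink exchange or a dissipative step).
#' @param name Character scalar, display name.
#' @return An object of class `"reaction"`.
#' @export
reaction <- function(id, substrates = numeric(), products = numeric(),
                     name = id) {
  stopifnot(is.character(id), length(id) == 1L)
  substrates <- unlist(substrates); products <- unlist(products)
  if (length(substrates) && (is.null(names(substrates)) || any(!nzchar(names(substrates)))))
    stop("substrates must be a named vector", call. = FALSE)
  if (length(products) && (is.null(names(products)) || any(!nzchar(names(products)))))
    stop("products must be a named vector", call. = FALSE)
  if (any(substrates <= 0) || any(products <= 0))
    stop("stoichiometric coefficients must be strictly positive", call. = FALSE)
  both <- intersect(names(substrates), names(products))
  if (length(both))
    stop("reaction ", id, ": metabolite on both sides: ",
         paste(both, collapse = ", "), call. = FALSE)
  structure(list(id = id, name = name,
                 substrates = substrates, products = products),
            class = "reaction")
}

is_exchange <- function(r) length(r$substrates) == 0L || length(r$products) == 0L
is_source   <- function(r) length(r$substrates) == 0L && length(r$products) == 1L
is_sink     <- function(r) length(r$products) == 0L && length(r$substrates) == 1L

#' Assemble a metabolic model
#'
#' Metabolites are ordered deterministically: inputs first, then pivots,
#' then outputs, each block alphabetical by id. Roles, when not supplied on
#' the metabolites, are derived from exchange-reaction topology: a
#' metabolite produced by a source exchange (a reaction with no substrates)
#' is an input, one consumed by a sink exchange (no products) is an output,
#' and one with internal producers and consumers (or both kinds of
#' exchange) is a pivot.
#'
#' @param metabolites List of [metabolite()] objects, or a character vector
#'   of ids (roles then derived from topology).
#' @param reactions List of [reaction()] objects.
#' @param carbon Optional named numeric vector overriding the component
#'   counts of the metabolites.
#' @param name Model name.
#' @param free_balance Character vector of metabolite ids whose balance is
#'   left free (not constrained to zero at steady state): bookkeeping
#'   species such as ATP, O2 or NH3 whose net production is deduced from a
#'   flux distribution rather than imposed.
#' @return An object of class `"metabolic_model"` with fields
#'   `metabolites` (data.frame id/name/role/carbon), `reactions`,
#'   and the cached stoichiometric matrix `S` (metabolites x reactions).
#' @export
metabolic_model <- function(metabolites, reactions, carbon = NULL,
                            name = "model", free_balance = character()) {
  if (is.character(metabolites))
    metabolites <- lapply(metabolites, metabolite)
  ids <- vapply(metabolites, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate metabolite ids", call. = FALSE)
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids", call. = FALSE)

  used <- unique(unlist(lapply(reactions, function(r)
    c(names(r$substrates), names(r$products)))))
  unknown <- setdiff(used, ids)
  if (length(unknown))
    stop("reactions reference unknown metabolites: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  ## role derivation from exchange topology
  src <- unique(unlist(lapply(Filter(is_source, reactions),
                              function(r) names(r$products))))
  snk <- unique(unlist(lapply(Filter(is_sink, reactions),
                              function(r) names(r$substrates))))
  int_prod <- unique(unlist(lapply(Filter(Negate(is_exchange), reactions),
                                   function(r) names(r$products))))
  int_cons <- unique(unlist(lapply(Filter(Negate(is_exchange), reactions),
                                   function(r) names(r$substrates))))
  derive_role <- function(id) {
    in_src <- id %in% src; in_snk <- id %in% snk
    produced <- id %in% int_prod; consumed <- id %in% int_cons
    if (in_src && !in_snk && !produced) return("input")
    if (in_snk && !in_src && !produced && !consumed) return("output")
    if (in_snk && !in_src && !consumed) return("output")
    if (!in_src && !in_snk && !produced && !consumed)
      stop("metabolite ", id, " is never produced nor consumed: ",
           "no role can be derived", call. = FALSE)
    "pivot"
  }
  roles <- vapply(metabolites, function(m) {
    if (!is.null(m$role) && m$role != "pivot") m$role else derive_role(m$id)
  }, "")
  carb <- vapply(metabolites, `[[`, 0, "carbon")
  names(carb) <- ids
  if (!is.null(carbon)) carb[names(carbon)] <- carbon

  ord <- order(match(roles, c("input", "pivot", "output")), ids)
  meta <- data.frame(id = ids[ord],
                     name = vapply(metabolites, `[[`, "", "name")[ord],
                     role = roles[ord], carbon = unname(carb[ids[ord]]),
                     stringsAsFactors = FALSE)
  S <- matrix(0, nrow(meta), length(reactions),
              dimnames = list(meta$id, rids))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    if (length(r$substrates)) S[names(r$substrates), j] <-
        S[names(r$substrates), j] - r$substrates
    if (length(r$products)) S[names(r$products), j] <-
        S[names(r$products), j] + r$products
  }
  out <- structure(list(name = name, metabolites = meta,
                        reactions = stats::setNames(reactions, rids),
                        S = S),
                   class = "metabolic_model")
  attr(out, "free_balance") <- intersect(free_balance, meta$id)
  out
}

#' @export
print.metabolic_model <- function(x, ...) {
  tab <- table(x$metabolites$role)
  cat("Metabolic model:", x$name, "\n")
  cat(sprintf("  %d metabolites (%d inputs, %d pivots, %d outputs), %d reactions\n",
              nrow(x$metabolites),
              sum(x$metabolites$role == "input"),
              sum(x$metabolites$role == "pivot"),
              sum(x$metabolites$role == "output"),
              length(x$reactions)))
  nex <- sum(vapply(x$reactions, is_exchange, TRUE))
  cat(sprintf("  %d exchange reactions (sources/sinks)\n", nex))
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  print(object)
  rep <- validate_component_balance(object)
  print(rep)
  invisible(object)
}

#' Stoichiometric matrix of a model
#'
#' @param model A [metabolic_model()].
#' @return Numeric matrix (metabolites x reactions), entries
#'   product-coefficient minus substrate-coefficient.
#' @export
stoichiometry <- function(model) model$S

#' Component (carbon) composition vector of a model
#'
#' @param model A [metabolic_model()].
#' @return Named numeric vector of component atoms per molecule.
#' @export
component_vector <- function(model)
  stats::setNames(model$metabolites$carbon, model$metabolites$id)

#' Check the per-reaction matter-invariance of a model
#'
#' Every reaction of a well-formed model conserves the matter component:
#' the signed sum of stoichiometric coefficients weighted by the component
#' counts is zero. Reactions violating this (beyond `tol`, relative to the
#' substrate component mass) are listed.
#'
#' @param model A [metabolic_model()].
#' @param component Optional named vector of component counts (defaults to
#'   the model's carbon vector). Must cover every metabolite.
#' @param tol Relative tolerance, default `1e-9`.
#' @return An object of class `"balance_report"`: data.frame of reaction id,
#'   residual, substrate component mass, and a `balanced` flag for the model.
#' @export
validate_component_balance <- function(model, component = NULL, tol = 1e-9) {
  cvec <- component_vector(model)
  if (!is.null(component)) {
    missing <- setdiff(model$metabolites$id, names(component))
    ## only species carrying the component need an entry; treat absent as 0
    ## unless the model says they carry some
    cvec[names(component)] <- component
    if (length(missing) && any(cvec[missing] > 0))
      stop("no component entry for metabolite(s): ",
           paste(missing[cvec[missing] > 0], collapse = ", "), call. = FALSE)
  }
  S <- model$S
  resid <- as.numeric(crossprod(S, cvec[rownames(S)]))
  submass <- vapply(model$reactions, function(r) {
    if (!length(r$substrates)) return(0)
    sum(r$substrates * cvec[names(r$substrates)])
  }, 0)
  ## exchange reactions move matter across the boundary on purpose
  exch <- vapply(model$reactions, is_exchange, TRUE)
  scale <- pmax(submass, 1)
  flag <- !exch & abs(resid) > tol * scale
  rep <- data.frame(reaction = colnames(S), residual = resid,
                    substrate_mass = unname(submass),
                    exchange = unname(exch), violated = unname(flag),
                    stringsAsFactors = FALSE)
  structure(list(report = rep, balanced = !any(flag), tol = tol),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  n <- sum(x$report$violated)
  if (x$balanced) {
    cat(sprintf("Component balance: OK (%d internal reactions, tol %.1e)\n",
                sum(!x$report$exchange), x$tol))
  } else {
    cat(sprintf("Component balance: %d reaction(s) violated (tol %.1e)\n",
                n, x$tol))
    print(x$report[x$report$violated, c("reaction", "residual")],
          row.names = FALSE)
  }
  invisible(x)
}
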