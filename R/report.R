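#' ATP-optimization comparison across the treatments
#'
#' For each treatment dataset, maximizes the ATP balance over the
#' unconstrained flux space and reports the optimum together with the
#' protein-turnover (peptide hydrolysis) flux at the optimum.
#'
#' @param treatments Treatments to include.
#' @param lcfa_ratio LCFA oxidation ratio of the model variant.
#' @return Data frame: treatment, ATP balance at the optimum, peptide
#'   hydrolysis and synthesis fluxes, predicted CO2.
#' @export
report_atp_comparison <- function(treatments = c("Ctrl", "CN", "HB"),
                                  lcfa_ratio = 0) {
  st <- mammary_study(lcfa_ratio)
  obj <- atp_objective(st$model)
  rows <- lapply(treatments, function(tr) {
    sp <- flux_space(apply_dataset(st$model, st$datasets[[tr]]),
                     prefer_free = mammary_free_ids())
    opt <- fba_optimize(sp, obj, "max")
    data.frame(treatment = tr,
               atp_balance = attr(opt, "value"),
               peptide_hydrolysis = unname(opt$v["R_64"]),
               peptide_synthesis = unname(opt$v["R_63"]),
               predicted_co2 = unname(opt$v["R_139"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

atp_objective <- function(model) {
  w <- stats::setNames(as.numeric(model$S["ATP", ]), colnames(model$S))
  w[w != 0]
}

#' Classification of the simplex vertices
#'
#' Tabulates, for every vertex of an ATP-constrained space, the activation
#' pattern over the marker fluxes (NADPH oxidation, OAA->G3P, OAA->PYR,
#' G3P->G6P, peptide hydrolysis/synthesis, PYR->OAA) and flags vertices
#' that violate literature bounds: G3P->G6P at most 591, PYR->OAA at most
#' 266 mmol/h/half-udder, and a nonzero protein turnover.
#'
#' @param vertexset An [enumerate_vertices()] result on the mammary model.
#' @param r8_max,r13_max,turnover_required Plausibility thresholds.
#' @return Data frame, one row per vertex.
#' @export
report_vertex_classification <- function(vertexset, r8_max = 591,
                                         r13_max = 266,
                                         turnover_required = TRUE) {
  cols <- c("R_19", "R_15", "R_14", "R_8", "R_64", "R_63", "R_13")
  rows <- lapply(seq_along(vertexset$vertices), function(i) {
    v <- vertexset$vertices[[i]]$v
    flags <- character()
    if (v["R_8"] > r8_max) flags <- c(flags, "R_8")
    if (v["R_13"] > r13_max) flags <- c(flags, "R_13")
    if (turnover_required && v["R_64"] <= 1e-6) flags <- c(flags, "R_64")
    data.frame(vertex = i,
               objective = vertexset$vertices[[i]]$objective %||% "",
               as.list(round(v[cols], 1)),
               plausible = length(flags) == 0L,
               nonrelevant = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long-chain fatty-acid oxidation sweep
#'
#' For each combination of LCFA oxidation ratio and treatment, reports the
#' predicted CO2, the ATP optimum, the vertex count of the ATP-constrained
#' space and the glucose-to-lactose / glucose-to-CO2 allocation ranges
#' (optional, as they dominate the run time).
#'
#' @param ratios LCFA ratios to sweep.
#' @param treatments Treatments.
#' @param atp ATP-balance target for the constrained analyses.
#' @param ranges Also compute the two glucose allocation ranges.
#' @param seed Seed for vertex enumeration / optimization.
#' @return Data frame, one row per (ratio, treatment); infeasible
#'   combinations carry `feasible = FALSE` and NA entries.
#' @export
report_lcfa_sweep <- function(ratios = c(0, 0.10),
                              treatments = c("Ctrl", "CN", "HB"),
                              atp = 1250, ranges = FALSE, seed = 1L) {
  rows <- list()
  for (rho in ratios) {
    st <- mammary_study(rho)
    obj <- atp_objective(st$model)
    for (tr in treatments) {
      row <- data.frame(ratio = rho, treatment = tr, feasible = TRUE,
                        predicted_co2 = NA_real_, atp_optimum = NA_real_,
                        n_vertices = NA_integer_,
                        glc_lactose_min = NA_real_, glc_lactose_max = NA_real_,
                        glc_co2_min = NA_real_, glc_co2_max = NA_real_,
                        stringsAsFactors = FALSE)
      sp0 <- tryCatch(
        flux_space(apply_dataset(st$model, st$datasets[[tr]]),
                   prefer_free = mammary_free_ids()),
        error = function(e) NULL)
      if (is.null(sp0)) {
        row$feasible <- FALSE
        rows[[length(rows) + 1L]] <- row
        next
      }
      opt <- fba_optimize(sp0, obj, "max")
      row$atp_optimum <- attr(opt, "value")
      row$predicted_co2 <- unname(opt$v["R_139"])
      spc <- tryCatch(add_atp_constraint(sp0, atp), error = function(e) NULL)
      if (!is.null(spc)) {
        vs <- tryCatch(enumerate_vertices(spc, n_objectives = 300,
                                          seed = seed, window = 150),
                       error = function(e) NULL)
        if (!is.null(vs)) row$n_vertices <- length(vs$vertices)
        if (ranges && !is.null(vs)) {
          tot <- aio(st$model, spc$v0)$input_totals[["GLC"]]
          for (cl in list(c("LACTOSE", "glc_lactose"), c("CO2", "glc_co2"))) {
            lo <- minmax_nlp(spc, st$model, c(cl[1], "GLC"), "min",
                             multistarts = 3, seed = seed, vertices = vs)
            hi <- minmax_nlp(spc, st$model, c(cl[1], "GLC"), "max",
                             multistarts = 3, seed = seed, vertices = vs)
            row[[paste0(cl[2], "_min")]] <- 100 * lo$value / tot
            row[[paste0(cl[2], "_max")]] <- 100 * hi$value / tot
          }
        }
      } else row$n_vertices <- NA_integer_
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
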