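## Fixtures built in code: tiny networks with known behaviour.

## linear chain: EX_I -> I -> P -> O -> EX_O, unit carbons
chain_model <- function(carbons = c(I = 1, P = 1, O = 1)) {
  mets <- lapply(names(carbons), function(id)
    metabolite(id, carbon = carbons[[id]]))
  metabolic_model(mets, list(
    reaction("EX_I", products = c(I = 1)),
    reaction("U", c(I = 1), c(P = carbons[["I"]] / carbons[["P"]])),
    reaction("S", c(P = 1), c(O = carbons[["P"]] / carbons[["O"]])),
    reaction("EX_O", c(O = 1))
  ), name = "chain")
}

## single-recycle network: P2 -> P1 returns a fraction of the flow.
## At input 1 and recycle flux rho/(1-rho), the throughput of P1 is the
## geometric series 1/(1-rho).
recycle_model <- function() {
  metabolic_model(
    list(metabolite("I", carbon = 1), metabolite("P1", carbon = 1),
         metabolite("P2", carbon = 1), metabolite("O", carbon = 1)),
    list(
      reaction("EX_I", products = c(I = 1)),
      reaction("U", c(I = 1), c(P1 = 1)),
      reaction("A", c(P1 = 1), c(P2 = 1)),
      reaction("REC", c(P2 = 1), c(P1 = 1)),
      reaction("S", c(P2 = 1), c(O = 1)),
      reaction("EX_O", c(O = 1))
    ), name = "recycle")
}

## flux vector of the recycle network for a given recycle fraction rho
recycle_flux <- function(rho, input = 1) {
  t <- input / (1 - rho)
  c(EX_I = input, U = input, A = t, REC = rho * t, S = input, EX_O = input)
}

recycle_space <- function(input = 1) {
  m <- recycle_model()
  ds <- treatment_dataset("rec", fluxes = c(EX_I = input, EX_O = input))
  flux_space(apply_dataset(m, ds), prefer_free = "REC")
}

## diamond: one input, two parallel paths, one output
diamond_model <- function() {
  metabolic_model(
    list(metabolite("I", carbon = 2), metabolite("P1", carbon = 2),
         metabolite("P2", carbon = 2), metabolite("P3", carbon = 2),
         metabolite("O", carbon = 2)),
    list(
      reaction("EX_I", products = c(I = 1)),
      reaction("U", c(I = 1), c(P1 = 1)),
      reaction("A1", c(P1 = 1), c(P2 = 1)),
      reaction("A2", c(P1 = 1), c(P3 = 1)),
      reaction("B1", c(P2 = 1), c(O = 1)),
      reaction("B2", c(P3 = 1), c(O = 1)),
      reaction("EX_O", c(O = 1))
    ), name = "diamond")
}

## two independent unit intervals: reduced space is the unit square
square_space <- function(side = 1) {
  m <- metabolic_model(
    list(metabolite("X", carbon = 1), metabolite("Y", carbon = 1),
         metabolite("OX", carbon = 1), metabolite("OY", carbon = 1)),
    list(
      reaction("EX_X", products = c(X = 1)),
      reaction("XA", c(X = 1), c(OX = 1)),
      reaction("XB", c(X = 1), c(OX = 1)),
      reaction("EX_Y", products = c(Y = 1)),
      reaction("YA", c(Y = 1), c(OY = 1)),
      reaction("YB", c(Y = 1), c(OY = 1)),
      reaction("EX_OX", c(OX = 1)),
      reaction("EX_OY", c(OY = 1))
    ), name = "square")
  ds <- treatment_dataset("sq", fluxes = c(EX_X = side, EX_Y = side,
                                           EX_OX = side, EX_OY = side))
  flux_space(apply_dataset(m, ds), prefer_free = c("XA", "YA"))
}

## two-input recycle network whose output-share cell is a nonlinear
## function of the free variables; 1 free dim version for closed forms
mix_recycle_model <- function() {
  metabolic_model(
    list(metabolite("I1", carbon = 1), metabolite("I2", carbon = 1),
         metabolite("P1", carbon = 1), metabolite("P2", carbon = 1),
         metabolite("O1", carbon = 1), metabolite("O2", carbon = 1)),
    list(
      reaction("EX_I1", products = c(I1 = 1)),
      reaction("EX_I2", products = c(I2 = 1)),
      reaction("U1", c(I1 = 1), c(P1 = 1)),
      reaction("U2", c(I2 = 1), c(P2 = 1)),
      reaction("A", c(P1 = 1), c(P2 = 1)),
      reaction("REC", c(P2 = 1), c(P1 = 1)),
      reaction("S1", c(P1 = 1), c(O1 = 1)),
      reaction("S2", c(P2 = 1), c(O2 = 1)),
      reaction("EX_O1", c(O1 = 1)),
      reaction("EX_O2", c(O2 = 1))
    ), name = "mix-recycle")
}

mix_recycle_space <- function(in1 = 1, in2 = 1, out1 = 1, out2 = 1) {
  m <- mix_recycle_model()
  ds <- treatment_dataset("mix", fluxes = c(EX_I1 = in1, EX_I2 = in2,
                                            EX_O1 = out1, EX_O2 = out2))
  flux_space(apply_dataset(m, ds), prefer_free = "REC")
}

mammary_atp_objective <- function(model)
  aioflux:::atp_objective(model)

mammary_table1_fixture <- function() aioflux:::mammary_table1()$Ctrl
mammary_side_fixture <- function() aioflux:::mammary_side_constraints()
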