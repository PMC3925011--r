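## Transcription of the ruminant mammary-gland stoichiometric model and its
## three lactation datasets (control diet Ctrl, duodenal casein infusion CN,
## and the reference dataset HB), reconstructed from the printed tables of
## the source study: all exchange fluxes, the fixed fatty-acid primer
## routes, the eight homogeneous side constraints, the peptide ATP costs
## (5 per link synthesized, 1 per link hydrolyzed) and the 70/30
## NADPH-origin rule are data; the internal cofactor stoichiometry uses
## classic textbook yields (P/O 3 for NADH, 2 for FADH2, 2 ATP for acetate
## activation). Reaction ids printed in the source tables are kept;
## ids of lumped internal steps are transcription-assigned.
##
## Conventions:
##  * irreversible reactions only; a cycle is two opposed reactions;
##  * ATP, O2 and NH3 are free balances (net production is deduced from a
##    flux distribution, not constrained); all other species are balanced;
##  * CO2 is a balanced pivot with a free nonnegative sink (R_139), the
##    "predicted CO2" of the model;
##  * the preformed long-chain fatty acid esterified into milk
##    triglyceride beyond the synthesized C4..C16 is the passthrough input
##    FAnm (palmitate-equivalent, 16 carbons).

mammary_metabolites <- function() {
  m <- function(id, carbon, name = id) metabolite(id, name, carbon = carbon)
  list(
    m("GLC", 6, "glucose"), m("GLYC", 3, "glycerol"), m("AC", 2, "acetate"),
    m("BHBA", 4, "beta-hydroxybutyrate"), m("LAC", 3, "lactate"),
    m("FAnm", 16, "preformed long-chain fatty acid"),
    m("ARG", 6, "arginine"), m("GLN", 5, "glutamine"), m("HIS", 6, "histidine"),
    m("ILE", 6, "isoleucine"), m("LEU", 6, "leucine"), m("LYS", 6, "lysine"),
    m("THR", 4, "threonine"), m("VAL", 5, "valine"),
    ## pivots
    m("ALA", 3, "alanine"), m("G6P", 6, "glucose-6-phosphate"),
    m("G3P", 3, "triose-phosphate"), m("GLY3P", 3, "glycerol-3-phosphate"),
    m("PYR", 3, "pyruvate"), m("OAA", 4, "oxaloacetate"),
    m("AKG", 5, "alpha-ketoglutarate"),
    m("MACOA", 2, "mitochondrial acetyl-CoA"),
    m("CACOA", 2, "cytosolic acetyl-CoA"),
    m("PC2", 2, "primer C(2:0)-CoA"), m("PC4", 4, "primer C(4:0)-CoA"),
    m("SER", 3, "serine"), m("GLU", 5, "glutamate"), m("ASP", 4, "aspartate"),
    m("FACOA", 16, "long-chain acyl-CoA"), m("CH2THF", 1, "methylene-THF"),
    m("CO2", 1), m("PEPT", 0, "peptide links"),
    m("NADHC", 0, "cytosolic NADH"), m("NADHM", 0, "mitochondrial NADH"),
    m("NADPH", 0), m("FADH2", 0), m("ATP", 0), m("O2", 0), m("NH3", 0),
    ## outputs
    m("LACTOSE", 12), m("C4", 4), m("C6", 6), m("C8", 8), m("C10", 10),
    m("C12", 12), m("C14", 14), m("C16", 16),
    m("GLY_AA", 2, "glycine"), m("PRO", 5, "proline"), m("ASN", 4, "asparagine")
  )
}

mammary_reactions <- function(lcfa = FALSE) {
  rx <- function(id, s, p, name = id) reaction(id, s, p, name)
  src <- function(id, m) reaction(id, products = stats::setNames(1, m),
                                  name = paste0(m, " input"))
  snk <- function(id, m) reaction(id, substrates = stats::setNames(1, m),
                                  name = paste0(m, " output"))
  ## C2-primer (acetate) and C4-primer (BHBA) fatty-acid synthesis routes:
  ## one elongation unit = 1 cytosolic acetyl-CoA + 1 ATP + 2 NADPH
  fa_c2 <- function(id, n_c, elong)
    rx(id, c(PC2 = 1, CACOA = elong, ATP = elong, NADPH = 2 * elong),
       stats::setNames(1, paste0("C", n_c)),
       paste0("C", n_c, " synthesis (acetate primer)"))
  fa_c4 <- function(id, n_c, elong) {
    s <- c(PC4 = 1)
    if (elong > 0) s <- c(s, CACOA = elong, ATP = elong, NADPH = 2 * elong)
    rx(id, s, stats::setNames(1, paste0("C", n_c)),
       paste0("C", n_c, " synthesis (BHBA primer)"))
  }
  out <- list(
    ## exchanges: net uptakes
    src("R_2", "GLC"), src("R_95", "GLYC"), src("R_96", "AC"),
    src("R_97", "BHBA"), src("R_98", "LAC"), src("R_109", "FAnm"),
    src("R_128", "ALA"), src("R_119", "ARG"), src("R_131", "GLN"),
    src("R_118", "HIS"), src("R_113", "ILE"), src("R_114", "LEU"),
    src("R_108", "LYS"), src("R_111", "THR"), src("R_115", "VAL"),
    ## exchanges: milk components and secreted amino acids
    snk("R_99", "LACTOSE"), snk("R_100", "C4"), snk("R_101", "C6"),
    snk("R_102", "C8"), snk("R_103", "C10"), snk("R_104", "C12"),
    snk("R_105", "C14"), snk("R_106", "C16"),
    snk("R_62", "GLY3P"), snk("R_57", "FACOA"), snk("R_107", "PEPT"),
    snk("R_121", "ALA"), snk("R_134", "ASN"), snk("R_125", "ASP"),
    snk("R_122", "GLU"), snk("R_120", "GLY_AA"), snk("R_124", "PRO"),
    snk("R_136", "SER"), snk("R_139", "CO2"),
    ## glycolysis / gluconeogenesis / lactose
    rx("R_3", c(GLC = 1, ATP = 1), c(G6P = 1), "hexokinase"),
    rx("R_5", c(G6P = 1, ATP = 1), c(G3P = 2), "glycolysis upper"),
    rx("R_6", c(G3P = 1), c(PYR = 1, ATP = 2, NADHC = 1), "glycolysis lower"),
    rx("R_8", c(G3P = 1), c(G6P = 0.5), "gluconeogenesis G3P->G6P"),
    rx("R_9", c(G6P = 2, ATP = 1), c(LACTOSE = 1), "lactose synthesis"),
    ## NADPH supply: pentose-phosphate pathway (scaled per NADPH) and the
    ## isocitrate-dehydrogenase route of the TCA cycle
    rx("R_58", c(G6P = 1 / 12), c(CO2 = 0.5, NADPH = 1), "pentose phosphate"),
    rx("R_82", c(OAA = 1, MACOA = 1), c(AKG = 1, CO2 = 1, NADPH = 1),
       "citrate synthase + ICDH (NADPH)"),
    rx("R_81", c(OAA = 1, MACOA = 1), c(AKG = 1, CO2 = 1, NADHM = 1),
       "citrate synthase + IDH (NADH)"),
    rx("R_16", c(AKG = 1), c(OAA = 1, CO2 = 1, NADHM = 2, FADH2 = 1, ATP = 1),
       "TCA alpha-KG -> OAA"),
    rx("R_19", c(NADPH = 1, O2 = 0.5), c(ATP = 3),
       "NADPH oxidation (respiratory chain, NADH-equivalent P/O)"),
    ## pyruvate node
    rx("R_12", c(PYR = 1), c(MACOA = 1, CO2 = 1, NADHM = 1),
       "pyruvate dehydrogenase"),
    rx("R_13", c(PYR = 1, CO2 = 1, ATP = 1), c(OAA = 1), "pyruvate carboxylase"),
    rx("R_14", c(OAA = 1), c(PYR = 1, CO2 = 1), "OAA -> PYR"),
    rx("R_15", c(OAA = 1, ATP = 2, NADHC = 1), c(G3P = 1, CO2 = 1),
       "OAA -> G3P (PEPCK + reverse glycolysis)"),
    ## oxidative phosphorylation and shuttle
    rx("R_30", c(NADHM = 1, O2 = 0.5), c(ATP = 3), "ETC NADH"),
    rx("R_31", c(FADH2 = 1, O2 = 0.5), c(ATP = 2), "ETC FADH2"),
    rx("R_32", c(NADHC = 1), c(NADHM = 1), "malate-aspartate shuttle"),
    ## glycerol and triglyceride glycerol-3P
    rx("R_60", c(GLYC = 1, ATP = 1), c(G3P = 1, NADHC = 1),
       "glycerol entry (kinase + G3P dehydrogenase)"),
    rx("R_61", c(G3P = 1, NADHM = 1), c(GLY3P = 1),
       "glycerol-3P synthesis (redox via the glycerol-phosphate shuttle)"),
    rx("R_24", c(LAC = 1), c(PYR = 1, NADHC = 1), "lactate -> pyruvate"),
    ## serine / glycine (half via SHMT, half via the glycine-synthase route)
    rx("R_17", c(G3P = 1, NH3 = 1), c(SER = 1, NADHC = 1), "serine synthesis"),
    rx("R_18", c(SER = 1), c(GLY_AA = 1, CH2THF = 1, NADHM = 1), "SHMT"),
    rx("R_23", c(CH2THF = 1, CO2 = 1, NH3 = 1, NADHM = 1), c(GLY_AA = 1),
       "glycine synthase"),
    ## nonessential amino-acid synthesis
    rx("R_77", c(AKG = 1, NH3 = 1), c(GLU = 1),
       "glutamate synthesis (transamination)"),
    rx("R_78", c(GLU = 1, ATP = 1, NADPH = 2), c(PRO = 1), "proline synthesis"),
    rx("R_79", c(OAA = 1, NH3 = 1), c(ASP = 1), "aspartate synthesis"),
    rx("R_83", c(ASP = 1, ATP = 2, NH3 = 1), c(ASN = 1), "asparagine synthesis"),
    rx("R_76", c(PYR = 1, NH3 = 1), c(ALA = 1), "alanine synthesis"),
    rx("R_44", c(ALA = 1), c(PYR = 1, NH3 = 1), "alanine catabolism"),
    ## acetate and BHBA activation
    rx("R_47", c(AC = 1, ATP = 2), c(CACOA = 1), "acetate -> cytosolic AcCoA"),
    rx("R_48", c(AC = 1, ATP = 2), c(MACOA = 1), "acetate -> mitochondrial AcCoA"),
    rx("R_46", c(BHBA = 1, ATP = 1), c(MACOA = 2, NADHM = 1), "BHBA -> 2 AcCoA"),
    rx("R_29", c(BHBA = 1, ATP = 2), c(PC4 = 1), "BHBA -> C4 primer"),
    ## protein turnover (peptide links; carbon-free bookkeeping)
    rx("R_63", c(ATP = 5), c(PEPT = 1), "peptide synthesis"),
    rx("R_64", c(PEPT = 1, ATP = 1), c(), "peptide hydrolysis"),
    ## preformed fatty-acid esterification (milk triglyceride acyl part)
    rx("R_56", c(FAnm = 1, ATP = 2), c(FACOA = 1), "fatty-acid acylation"),
    ## acetate primer production, one dedicated reaction per fatty acid
    rx("R_54", c(AC = 1, ATP = 2), c(PC2 = 1), "C2 primer (for C6)"),
    rx("R_55", c(AC = 1, ATP = 2), c(PC2 = 1), "C2 primer (for C8)"),
    rx("R_51", c(AC = 1, ATP = 2), c(PC2 = 1), "C2 primer (for C10)"),
    rx("R_86", c(AC = 1, ATP = 2), c(PC2 = 1), "C2 primer (for C12)"),
    rx("R_87", c(AC = 1, ATP = 2), c(PC2 = 1), "C2 primer (for C14)"),
    rx("R_88", c(AC = 1, ATP = 2), c(PC2 = 1), "C2 primer (for C16)"),
    ## fatty-acid synthesis, acetate-primer routes
    fa_c2("R_53", 4, 1), fa_c2("R_90", 6, 2), fa_c2("R_91", 8, 3),
    fa_c2("R_52", 10, 4), fa_c2("R_92", 12, 5), fa_c2("R_93", 14, 6),
    fa_c2("R_94", 16, 7),
    ## fatty-acid synthesis, BHBA-primer routes
    fa_c4("R_34", 4, 0), fa_c4("R_35", 6, 1), fa_c4("R_37", 8, 2),
    fa_c4("R_38", 10, 3), fa_c4("R_26", 12, 4), fa_c4("R_27", 14, 5),
    fa_c4("R_49", 16, 6),
    ## amino-acid catabolism, lumped to the pivots
    rx("R_45", c(ARG = 1), c(AKG = 1, CO2 = 1, NH3 = 3, NADHM = 1),
       "arginine catabolism"),
    rx("R_41", c(GLN = 1), c(AKG = 1, NH3 = 2, NADHM = 1),
       "glutamine catabolism"),
    rx("R_40", c(HIS = 1), c(AKG = 1, CO2 = 1, NH3 = 2, NADHM = 1),
       "histidine catabolism"),
    rx("R_42", c(ILE = 1), c(MACOA = 1, OAA = 1, NH3 = 1, NADHM = 3, FADH2 = 1),
       "isoleucine catabolism"),
    rx("R_36", c(LEU = 1, ATP = 1), c(MACOA = 3, NH3 = 1, NADHM = 1, FADH2 = 1),
       "leucine catabolism"),
    rx("R_43", c(LYS = 1), c(MACOA = 2, CO2 = 2, NH3 = 2, NADHM = 4, FADH2 = 1),
       "lysine catabolism"),
    rx("R_33", c(THR = 1), c(PYR = 1, CO2 = 1, NH3 = 1, NADHM = 2),
       "threonine catabolism"),
    rx("R_39", c(VAL = 1), c(OAA = 1, CO2 = 1, NH3 = 1, NADHM = 3, FADH2 = 1),
       "valine catabolism")
  )
  if (lcfa) {
    out <- c(out, list(
      src("R_141", "C16IN"), src("R_142", "C18IN"),
      rx("R_20", c(C16IN = 1, ATP = 2), c(MACOA = 8, NADHM = 7, FADH2 = 7),
         "C16 oxidation"),
      rx("R_21", c(C18IN = 1, ATP = 2), c(MACOA = 9, NADHM = 8, FADH2 = 8),
         "C18 oxidation")
    ))
  }
  out
}

#' The mammary-gland stoichiometric model (transcription)
#'
#' Builds the carbon-balanced stoichiometric model of ruminant mammary
#' metabolism used throughout the package: glucose, glycerol, acetate,
#' beta-hydroxybutyrate, lactate and amino-acid net uptakes; lactose,
#' glycerol-3P, synthesized C4..C16 fatty acids, secreted amino acids,
#' peptide links and CO2 as outputs; eleven carbon pivots; explicit
#' NADH/NADPH/FADH2/ATP bookkeeping. This is a transcription reconstructed
#' from the printed description of the published mammary model (the ids of
#' reactions named there are preserved; lumped internal steps carry
#' transcription-assigned ids), not the original supplementary file.
#'
#' @param lcfa_ratio Fraction of the TCA acetyl-CoA supplied by long-chain
#'   fatty-acid (C16/C18) oxidation: one of 0, 0.10, 0.20, 0.25. At 0 the
#'   base model is returned; otherwise C16/C18 uptake and oxidation
#'   reactions are added (the datasets then carry the coupling constraint).
#' @return A [metabolic_model()].
#' @export
mammary_model <- function(lcfa_ratio = 0) {
  check_lcfa_ratio(lcfa_ratio)
  mets <- mammary_metabolites()
  if (lcfa_ratio > 0)
    mets <- c(mets, list(metabolite("C16IN", "C16 uptake", carbon = 16),
                         metabolite("C18IN", "C18 uptake", carbon = 18)))
  metabolic_model(mets, mammary_reactions(lcfa = lcfa_ratio > 0),
                  name = if (lcfa_ratio > 0)
                    sprintf("mammary gland (LCFA %d%%)", round(100 * lcfa_ratio))
                  else "mammary gland",
                  free_balance = c("ATP", "O2", "NH3"))
}

check_lcfa_ratio <- function(r) {
  if (!isTRUE(r %in% c(0, 0.10, 0.20, 0.25)))
    stop("lcfa_ratio must be one of 0, 0.10, 0.20, 0.25", call. = FALSE)
}

## Net uptake and milk output of the mammary gland in the three
## treatments, mmol/h/half udder. Positive amino-acid balances are inputs,
## negative balances outputs, hence the separate in/out exchange fluxes.
mammary_table1 <- function() {
  list(
    Ctrl = list(
      fluxes = c(R_2 = 237, R_95 = 5.84, R_96 = 510, R_97 = 84, R_98 = 0,
                 R_62 = 32.96,
                 R_100 = 10.08, R_101 = 4.51, R_102 = 2.23, R_103 = 4.66,
                 R_104 = 4.23, R_105 = 13.90, R_106 = 18.82, R_99 = 73.80,
                 R_128 = 3.11, R_121 = 0, R_119 = 4.40, R_134 = 0,
                 R_125 = 3.43, R_122 = 0.54, R_131 = 1.22, R_120 = 4.98,
                 R_124 = 10.65, R_136 = 7.21, R_118 = 0.23, R_113 = 2.19,
                 R_114 = 2.02, R_108 = 2.68, R_111 = 0.35, R_115 = 2.54,
                 R_107 = 124.5,
                 R_53 = 0, R_54 = 2.256, R_55 = 1.113, R_51 = 2.331,
                 R_86 = 2.116, R_87 = 6.951, R_88 = 9.410),
      zeroed = c("R_24", "R_76", "R_83")),
    CN = list(
      fluxes = c(R_2 = 232, R_95 = 5.74, R_96 = 462, R_97 = 167, R_98 = 0,
                 R_62 = 39.11,
                 R_100 = 11.59, R_101 = 5.58, R_102 = 2.87, R_103 = 6.46,
                 R_104 = 6.12, R_105 = 17.89, R_106 = 21.44, R_99 = 83.52,
                 R_128 = 0, R_121 = 3.26, R_119 = 4.48, R_134 = 0,
                 R_125 = 4.13, R_122 = 6.33, R_131 = 1.79, R_120 = 3.44,
                 R_124 = 10.99, R_136 = 7.50, R_118 = 0, R_113 = 3.57,
                 R_114 = 3.76, R_108 = 3.58, R_111 = 0, R_115 = 3.86,
                 R_107 = 150.0,
                 R_53 = 0, R_54 = 2.790, R_55 = 1.437, R_51 = 3.230,
                 R_86 = 3.061, R_87 = 8.946, R_88 = 10.719),
      zeroed = c("R_24", "R_44", "R_83", "R_40", "R_33")),
    HB = list(
      fluxes = c(R_2 = 254, R_95 = 0.69, R_96 = 384, R_97 = 151, R_98 = 0.48,
                 R_62 = 31.67,
                 R_100 = 9.48, R_101 = 3.79, R_102 = 2.06, R_103 = 3.96,
                 R_104 = 3.56, R_105 = 9.31, R_106 = 13.40, R_99 = 79.28,
                 R_128 = 2.19, R_121 = 0, R_119 = 10.96, R_134 = 0.48,
                 R_125 = 5.15, R_122 = 4.79, R_131 = 1.50, R_120 = 5.17,
                 R_124 = 13.96, R_136 = 1.88, R_118 = 0, R_113 = 31.63,
                 R_114 = 0, R_108 = 3.98, R_111 = 0, R_115 = 9.13,
                 R_107 = 149.17,
                 R_53 = 0, R_54 = 1.896, R_55 = 1.031, R_51 = 1.979,
                 R_86 = 1.781, R_87 = 4.655, R_88 = 6.698),
      zeroed = c("R_76", "R_40", "R_36", "R_33"))
  )
}

## The eight homogeneous side constraints (NADPH 70/30 split, the five
## acetate-primer route couplings, the triglyceride acylation rule).
mammary_side_constraints <- function() {
  list(c(R_82 = 0.7, R_58 = -0.3),
       c(R_51 = 1, R_52 = -1),
       c(R_54 = 1, R_90 = -1),
       c(R_55 = 1, R_91 = -1),
       c(R_86 = 1, R_92 = -1),
       c(R_87 = 1, R_93 = -1),
       c(R_88 = 1, R_94 = -1),
       c(R_56 = 1, R_62 = -3))
}

#' The three lactation treatment datasets
#'
#' @param lcfa_ratio See [mammary_model()]; at a positive ratio each
#'   dataset gains the constraint coupling C16/C18 oxidation to the TCA
#'   acetyl-CoA flux.
#' @param treatments Which datasets to build.
#' @return Named list of [treatment_dataset()] objects.
#' @export
mammary_datasets <- function(lcfa_ratio = 0,
                             treatments = c("Ctrl", "CN", "HB")) {
  check_lcfa_ratio(lcfa_ratio)
  t1 <- mammary_table1()
  side <- mammary_side_constraints()
  if (lcfa_ratio > 0)
    side <- c(side,
              list(c(R_20 = 8, R_21 = 9,
                     R_81 = -lcfa_ratio, R_82 = -lcfa_ratio),
                   c(R_20 = 1, R_21 = -1)))
  out <- lapply(treatments, function(nm) {
    d <- t1[[nm]]
    treatment_dataset(nm, fluxes = d$fluxes, side_constraints = side,
                      zeroed = d$zeroed)
  })
  stats::setNames(out, treatments)
}

#' Model plus datasets for one long-chain fatty-acid oxidation scenario
#'
#' Convenience fixture builder: the mammary model and its three treatment
#' datasets for a given LCFA oxidation ratio.
#'
#' @inheritParams mammary_model
#' @return List with elements `model` and `datasets`.
#' @export
mammary_study <- function(lcfa_ratio = 0) {
  list(model = mammary_model(lcfa_ratio),
       datasets = mammary_datasets(lcfa_ratio))
}

## the five cycle fluxes reported as the independent coordinates
mammary_free_ids <- function() c("R_8", "R_14", "R_15", "R_19", "R_64")

#' Fatty-acid synthesis sub-model with its allocation table
#'
#' Builds the primer/elongation sub-network of milk fatty-acid synthesis
#' (acetate and beta-hydroxybutyrate inputs, the two primer pools, the
#' C4..C16 synthesis routes) under the primer rules of a treatment: the C4
#' acid primed exclusively from BHBA, the longer acids half from the
#' acetate C2 primer and half from the BHBA C4 primer, all elongation
#' units from acetate. The resulting flux system is fully determined
#' (dimension 0), and its allocation table gives the precursor shares of
#' each synthesized fatty acid.
#'
#' @param treatment `"Ctrl"`, `"CN"` or `"HB"` (the shares are identical
#'   across treatments; the fluxes differ).
#' @return List: `model`, `space` (dimension-0 [flux_space()]), `aio` and
#'   the [fatty_acid_precursors()] table `precursors`.
#' @export
fa_submodel <- function(treatment = "Ctrl") {
  t1 <- mammary_table1()[[treatment]]
  keep_rx <- c("R_96", "R_97", "R_47", "R_29",
               "R_54", "R_55", "R_51", "R_86", "R_87", "R_88",
               "R_53", "R_90", "R_91", "R_52", "R_92", "R_93", "R_94",
               "R_34", "R_35", "R_37", "R_38", "R_26", "R_27", "R_49",
               "R_100", "R_101", "R_102", "R_103", "R_104", "R_105", "R_106")
  rxs <- Filter(function(r) r$id %in% keep_rx, mammary_reactions())
  ## strip the bookkeeping species the sub-model does not balance
  rxs <- lapply(rxs, function(r) {
    drop <- c("ATP", "NADPH")
    reaction(r$id, r$substrates[setdiff(names(r$substrates), drop)],
             r$products[setdiff(names(r$products), drop)], r$name)
  })
  keep_met <- c("AC", "BHBA", "PC2", "PC4", "CACOA",
                paste0("C", c(4, 6, 8, 10, 12, 14, 16)))
  mets <- Filter(function(m) m$id %in% keep_met, mammary_metabolites())
  model <- metabolic_model(mets, rxs,
                           name = sprintf("fatty-acid sub-model (%s)", treatment))
  ## the sub-model's acetate/BHBA uptakes are those of fatty-acid
  ## synthesis alone (pinned by balance), not the whole-gland uptakes
  fx <- t1$fluxes[setdiff(intersect(names(t1$fluxes), names(model$reactions)),
                          c("R_96", "R_97"))]
  side <- Filter(function(w) all(names(w) %in% names(model$reactions)),
                 mammary_side_constraints())
  ds <- treatment_dataset(treatment, fluxes = fx, side_constraints = side)
  sp <- flux_space(apply_dataset(model, ds))
  a <- aio(model, sp$v0)
  list(model = model, space = sp, aio = a,
       precursors = fatty_acid_precursors(a))
}

#' Parameterized flux space for one mammary treatment
#'
#' @param treatment `"Ctrl"`, `"CN"` or `"HB"`.
#' @param lcfa_ratio LCFA oxidation ratio.
#' @param atp Optional ATP-balance target; when given the space is
#'   constrained (see [add_atp_constraint()]).
#' @param atp_tolerance Relative tolerance on the ATP target.
#' @return A [flux_space()].
#' @export
mammary_space <- function(treatment = "Ctrl", lcfa_ratio = 0, atp = NULL,
                          atp_tolerance = 0) {
  st <- mammary_study(lcfa_ratio)
  sys <- apply_dataset(st$model, st$datasets[[treatment]])
  sp <- flux_space(sys, prefer_free = mammary_free_ids())
  if (!is.null(atp))
    sp <- add_atp_constraint(sp, atp, atp_tolerance)
  sp
}
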