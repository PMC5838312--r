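# The packaged reduced central-carbon network of O. oeni PSU-1.
#
# Scope: heterolactic phosphoketolase pathway (glucose/fructose -> GAP +
# acetyl-P; D-lactate, acetate, ethanol, erythritol, mannitol products),
# malolactic reaction, citrate degradation to oxaloacetate/pyruvate (with
# acetate, diacetyl products), the malate -> oxaloacetate -> pyruvate route,
# F0F1-ATPase, an NGAM ATP hydrolysis reaction, serine/threonine/cysteine
# degradation, and exchanges for all measured substrates and products.
#
# Protons and water are explicit in both compartments; charge is not balanced.
# Malate and citrate each have two carrier paralogs with identical (uniport)
# stoichiometry: this reproduces the elementary-mode counts of the malate and
# citrate rows of the substrate-product table without creating an
# energetically free choice between uptake mechanisms. Mannitol arises only
# by direct fructose reduction (mannitol dehydrogenase); a mannitol-1P shunt
# from F6P is deliberately absent because it is an ATP-dissipating bypass
# that would make maintenance (NGAM) unidentifiable from exchange data.

#' Load the packaged reduced O. oeni central-carbon network
#'
#' Builds the network programmatically (the copy under
#' `inst/extdata/oeni_reduced.json` is written from this constructor and kept
#' in sync by a test). The biomass reaction is a lumped precursor drain
#' (~33 mmol C per gDCW) with a growth-associated maintenance of 23 mmol ATP
#' per gDCW; biomass flux is in 1/h.
#'
#' @param h_per_atp protons translocated inward per ATP by the F0F1-ATPase
#'   (integer >= 2; the chemical reaction itself consumes one of them).
#'   This number is not settled for O. oeni; 3 is the packaged default and
#'   all proton fractions are reported per chosen value.
#' @return a `metabolic_network`.
#' @export
load_reduced_oeni_model <- function(h_per_atp = 3) {
  stopifnot(h_per_atp >= 2)
  m <- list(
    # extracellular
    metabolite("glc_e", "D-glucose", "e", "C6H12O6"),
    metabolite("fru_e", "D-fructose", "e", "C6H12O6"),
    metabolite("cit_e", "citrate", "e", "C6H8O7"),
    metabolite("mal_e", "L-malate", "e", "C4H6O5"),
    metabolite("cys_e", "L-cysteine", "e", "C3H7NO2S"),
    metabolite("ser_e", "L-serine", "e", "C3H7NO3"),
    metabolite("thr_e", "L-threonine", "e", "C4H9NO3"),
    metabolite("val_e", "L-valine", "e", "C5H11NO2"),
    metabolite("phe_e", "L-phenylalanine", "e", "C9H11NO2"),
    metabolite("mnl_e", "D-mannitol", "e", "C6H14O6"),
    metabolite("eol_e", "erythritol", "e", "C4H10O4"),
    metabolite("llac_e", "L-lactate", "e", "C3H6O3"),
    metabolite("dlac_e", "D-lactate", "e", "C3H6O3"),
    metabolite("ac_e", "acetate", "e", "C2H4O2"),
    metabolite("etoh_e", "ethanol", "e", "C2H6O"),
    metabolite("diact_e", "diacetyl", "e", "C4H6O2"),
    metabolite("co2_e", "CO2", "e", "CO2"),
    metabolite("nh4_e", "ammonium", "e", "H4N"),
    metabolite("h2s_e", "hydrogen sulfide", "e", "H2S"),
    metabolite("h_e", "proton", "e", "H"),
    metabolite("h2o_e", "water", "e", "H2O"),
    metabolite("pi_e", "phosphate", "e", "HO4P"),
    # cytosol
    metabolite("glc_c", "D-glucose", "c", "C6H12O6"),
    metabolite("fru_c", "D-fructose", "c", "C6H12O6"),
    metabolite("g6p", "D-glucose 6-phosphate", "c", "C6H13O9P"),
    metabolite("f6p", "D-fructose 6-phosphate", "c", "C6H13O9P"),
    metabolite("pg6", "6-phospho-D-gluconate", "c", "C6H13O10P"),
    metabolite("ru5p", "D-ribulose 5-phosphate", "c", "C5H11O8P"),
    metabolite("x5p", "D-xylulose 5-phosphate", "c", "C5H11O8P"),
    metabolite("e4p", "D-erythrose 4-phosphate", "c", "C4H9O7P"),
    metabolite("ery4p", "erythritol 4-phosphate", "c", "C4H11O7P"),
    metabolite("gap", "glyceraldehyde 3-phosphate", "c", "C3H7O6P"),
    metabolite("bpg13", "1,3-bisphospho-D-glycerate", "c", "C3H8O10P2"),
    metabolite("pg3", "3-phospho-D-glycerate", "c", "C3H7O7P"),
    metabolite("pep", "phosphoenolpyruvate", "c", "C3H5O6P"),
    metabolite("pyr", "pyruvate", "c", "C3H4O3"),
    metabolite("oaa", "oxaloacetate", "c", "C4H4O5"),
    metabolite("cit_c", "citrate", "c", "C6H8O7"),
    metabolite("mal_c", "L-malate", "c", "C4H6O5"),
    metabolite("llac_c", "L-lactate", "c", "C3H6O3"),
    metabolite("dlac_c", "D-lactate", "c", "C3H6O3"),
    metabolite("ac_c", "acetate", "c", "C2H4O2"),
    metabolite("actp", "acetyl phosphate", "c", "C2H5O5P"),
    metabolite("accoa", "acetyl-CoA", "c", "C23H38N7O17P3S"),
    metabolite("coa", "coenzyme A", "c", "C21H36N7O16P3S"),
    metabolite("acald", "acetaldehyde", "c", "C2H4O"),
    metabolite("etoh_c", "ethanol", "c", "C2H6O"),
    metabolite("mnl_c", "D-mannitol", "c", "C6H14O6"),
    metabolite("eol_c", "erythritol", "c", "C4H10O4"),
    metabolite("alac", "(S)-2-acetolactate", "c", "C5H8O4"),
    metabolite("diact_c", "diacetyl", "c", "C4H6O2"),
    metabolite("cys_c", "L-cysteine", "c", "C3H7NO2S"),
    metabolite("ser_c", "L-serine", "c", "C3H7NO3"),
    metabolite("thr_c", "L-threonine", "c", "C4H9NO3"),
    metabolite("val_c", "L-valine", "c", "C5H11NO2"),
    metabolite("phe_c", "L-phenylalanine", "c", "C9H11NO2"),
    metabolite("gly", "glycine", "c", "C2H5NO2"),
    metabolite("nad", "NAD+", "c", "C21H27N7O14P2"),
    metabolite("nadh", "NADH", "c", "C21H28N7O14P2"),
    metabolite("nadp", "NADP+", "c", "C21H28N7O17P3"),
    metabolite("nadph", "NADPH", "c", "C21H29N7O17P3"),
    metabolite("atp", "ATP", "c", "C10H16N5O13P3"),
    metabolite("adp", "ADP", "c", "C10H15N5O10P2"),
    metabolite("pi_c", "phosphate", "c", "HO4P"),
    metabolite("h_c", "proton", "c", "H"),
    metabolite("h2o_c", "water", "c", "H2O"),
    metabolite("co2_c", "CO2", "c", "CO2"),
    metabolite("nh4_c", "ammonium", "c", "H4N"),
    metabolite("h2s_c", "hydrogen sulfide", "c", "H2S"))
  mets <- do.call(rbind, m)

  ex <- function(met, lb) reaction(paste0("EX_", sub("_e$", "", met)),
                                   setNames(-1, met), lower_bound = lb,
                                   upper_bound = DEFAULT_BOUND,
                                   subsystem = "exchange",
                                   name = paste0("exchange of ", met))
  sym <- function(id, met, tags = "proton_importer", subsystem = "transport")
    reaction(id, setNames(c(-1, -1, 1, 1),
                          c(paste0(met, "_e"), "h_e", paste0(met, "_c"), "h_c")),
             subsystem = subsystem, role_tags = tags,
             name = paste0(met, " proton symport uptake"))

  r <- list(
    # exchanges: substrates open for uptake, products export-only,
    # small freely exchanged species open both ways
    ex("glc_e", -DEFAULT_BOUND), ex("fru_e", -DEFAULT_BOUND),
    ex("cit_e", -DEFAULT_BOUND), ex("mal_e", -DEFAULT_BOUND),
    ex("cys_e", -DEFAULT_BOUND), ex("ser_e", -DEFAULT_BOUND),
    ex("thr_e", -DEFAULT_BOUND), ex("val_e", -DEFAULT_BOUND),
    ex("phe_e", -DEFAULT_BOUND),
    ex("mnl_e", 0), ex("eol_e", 0), ex("llac_e", 0), ex("dlac_e", 0),
    ex("ac_e", 0), ex("etoh_e", 0), ex("diact_e", 0),
    ex("co2_e", -DEFAULT_BOUND), ex("nh4_e", 0), ex("h2s_e", 0),
    ex("h_e", -DEFAULT_BOUND), ex("h2o_e", -DEFAULT_BOUND),
    ex("pi_e", -DEFAULT_BOUND),

    # transport
    reaction("GLCt", c(glc_e = -1, glc_c = 1), subsystem = "transport",
             name = "D-glucose facilitated uptake"),
    reaction("FRUt", c(fru_e = -1, fru_c = 1), subsystem = "transport",
             name = "D-fructose facilitated uptake"),
    # two carrier paralogs each for citrate and malate (electrogenic uniport
    # of the mono-anion); identical stoichiometry, so they differ only as
    # routes, not energetically
    reaction("CITt1", c(cit_e = -1, cit_c = 1), subsystem = "transport",
             name = "citrate uniport (carrier 1)"),
    reaction("CITt2", c(cit_e = -1, cit_c = 1), subsystem = "transport",
             name = "citrate uniport (carrier 2)"),
    reaction("MALt1", c(mal_e = -1, mal_c = 1), subsystem = "transport",
             name = "L-malate uniport (carrier 1)"),
    reaction("MALt2", c(mal_e = -1, mal_c = 1), subsystem = "transport",
             name = "L-malate uniport (carrier 2)"),
    sym("CYSt", "cys"), sym("SERt", "ser"), sym("THRt", "thr"),
    sym("VALt", "val"), sym("PHEt", "phe"), sym("PIt", "pi"),
    reaction("LLACt", c(llac_c = -1, h_c = -1, llac_e = 1, h_e = 1),
             subsystem = "transport", role_tags = "proton_extruder",
             name = "L-lactate/H+ symport efflux"),
    reaction("DLACt", c(dlac_c = -1, h_c = -1, dlac_e = 1, h_e = 1),
             subsystem = "transport", role_tags = "proton_extruder",
             name = "D-lactate/H+ symport efflux"),
    reaction("ACt", c(ac_c = -1, h_c = -1, ac_e = 1, h_e = 1),
             subsystem = "transport", role_tags = "proton_extruder",
             name = "acetate/H+ symport efflux"),
    reaction("ETOHt", c(etoh_c = -1, etoh_e = 1), reversible = TRUE,
             subsystem = "transport", name = "ethanol diffusion"),
    reaction("MNLt", c(mnl_c = -1, mnl_e = 1), subsystem = "transport",
             name = "D-mannitol efflux"),
    reaction("EOLt", c(eol_c = -1, eol_e = 1), subsystem = "transport",
             name = "erythritol efflux"),
    reaction("DIACt", c(diact_c = -1, diact_e = 1), subsystem = "transport",
             name = "diacetyl efflux"),
    reaction("CO2t", c(co2_c = -1, co2_e = 1), reversible = TRUE,
             subsystem = "transport", name = "CO2 diffusion"),
    reaction("H2Ot", c(h2o_c = -1, h2o_e = 1), reversible = TRUE,
             subsystem = "transport", name = "water diffusion"),
    reaction("NH4t", c(nh4_c = -1, nh4_e = 1), subsystem = "transport",
             name = "ammonium efflux"),
    reaction("H2St", c(h2s_c = -1, h2s_e = 1), subsystem = "transport",
             name = "hydrogen sulfide efflux"),

    # phosphoketolase pathway (heterolactic backbone)
    reaction("HEX1", c(glc_c = -1, atp = -1, g6p = 1, adp = 1, h_c = 1),
             subsystem = "phosphoketolase", name = "hexokinase"),
    reaction("FRUK", c(fru_c = -1, atp = -1, f6p = 1, adp = 1, h_c = 1),
             subsystem = "phosphoketolase", name = "fructokinase"),
    reaction("PGI", c(g6p = -1, f6p = 1), reversible = TRUE,
             subsystem = "phosphoketolase", name = "glucose-6P isomerase"),
    reaction("G6PDH", c(g6p = -1, nadp = -1, pg6 = 1, nadph = 1, h_c = 1),
             subsystem = "phosphoketolase", role_tags = "nadph_producer",
             name = "glucose-6P dehydrogenase (+ lactonase, lumped)"),
    reaction("GND", c(pg6 = -1, nadp = -1, ru5p = 1, co2_c = 1, nadph = 1),
             subsystem = "phosphoketolase", role_tags = "nadph_producer",
             name = "phosphogluconate dehydrogenase (decarboxylating)"),
    reaction("RPE", c(ru5p = -1, x5p = 1), reversible = TRUE,
             subsystem = "phosphoketolase", name = "ribulose-5P 3-epimerase"),
    reaction("XPK", c(x5p = -1, pi_c = -1, gap = 1, actp = 1, h2o_c = 1),
             subsystem = "phosphoketolase", name = "xylulose-5P phosphoketolase"),
    reaction("FPK", c(f6p = -1, pi_c = -1, e4p = 1, actp = 1, h2o_c = 1),
             subsystem = "phosphoketolase", name = "fructose-6P phosphoketolase"),
    reaction("GAPD", c(gap = -1, nad = -1, pi_c = -1, bpg13 = 1, nadh = 1, h_c = 1),
             subsystem = "phosphoketolase", role_tags = "nadh_producer",
             name = "glyceraldehyde-3P dehydrogenase"),
    reaction("PGK", c(bpg13 = -1, adp = -1, pg3 = 1, atp = 1),
             subsystem = "phosphoketolase", role_tags = "atp_producer_pkp",
             name = "3-phosphoglycerate kinase"),
    reaction("ENO", c(pg3 = -1, pep = 1, h2o_c = 1),
             subsystem = "phosphoketolase",
             name = "phosphoglycerate mutase + enolase (lumped)"),
    reaction("PYK", c(pep = -1, adp = -1, h_c = -1, pyr = 1, atp = 1),
             subsystem = "phosphoketolase", role_tags = "atp_producer_pkp",
             name = "pyruvate kinase"),
    reaction("ACK", c(actp = -1, adp = -1, ac_c = 1, atp = 1),
             subsystem = "phosphoketolase", role_tags = "atp_producer_pkp",
             name = "acetate kinase"),
    reaction("PTA", c(actp = -1, coa = -1, accoa = 1, pi_c = 1),
             reversible = TRUE, subsystem = "phosphoketolase",
             name = "phosphotransacetylase"),
    reaction("ACALDDH", c(accoa = -1, nadh = -1, h_c = -1,
                          acald = 1, coa = 1, nad = 1),
             subsystem = "phosphoketolase",
             name = "acetaldehyde dehydrogenase (acylating)"),
    reaction("ADH", c(acald = -1, nadh = -1, h_c = -1, etoh_c = 1, nad = 1),
             subsystem = "phosphoketolase", name = "alcohol dehydrogenase"),
    reaction("DLDH", c(pyr = -1, nadh = -1, h_c = -1, dlac_c = 1, nad = 1),
             subsystem = "phosphoketolase", name = "D-lactate dehydrogenase"),

    # fructose reduction / polyol formation
    reaction("MNLDH", c(fru_c = -1, nadh = -1, h_c = -1, mnl_c = 1, nad = 1),
             subsystem = "fructose_reduction",
             name = "mannitol dehydrogenase (NADH)"),
    reaction("MNLDH2", c(fru_c = -1, nadph = -1, h_c = -1, mnl_c = 1, nadp = 1),
             subsystem = "fructose_reduction",
             name = "mannitol dehydrogenase (NADPH)"),
    reaction("E4PR", c(e4p = -1, nadph = -1, h_c = -1, ery4p = 1, nadp = 1),
             subsystem = "fructose_reduction",
             name = "erythrose-4P reductase"),
    reaction("ERY4PP", c(ery4p = -1, h2o_c = -1, eol_c = 1, pi_c = 1),
             subsystem = "fructose_reduction", name = "erythritol-4P phosphatase"),

    # citrate degradation
    reaction("CITL", c(cit_c = -1, oaa = 1, ac_c = 1),
             subsystem = "citrate_degradation", name = "citrate lyase"),
    reaction("OAADC", c(oaa = -1, h_c = -1, pyr = 1, co2_c = 1),
             subsystem = "citrate_degradation", name = "oxaloacetate decarboxylase"),
    reaction("ALS", c(pyr = -2, h_c = -1, alac = 1, co2_c = 1),
             subsystem = "citrate_degradation", name = "acetolactate synthase"),
    reaction("DIACS", c(alac = -1, h_c = -1, diact_c = 1, co2_c = 1),
             subsystem = "citrate_degradation",
             name = "diacetyl formation from acetolactate (lumped)"),

    # malolactic fermentation and the malate -> oxaloacetate route
    reaction("MLE", c(mal_c = -1, h_c = -1, llac_c = 1, co2_c = 1),
             subsystem = "MLF", name = "malolactic enzyme"),
    reaction("MDH", c(mal_c = -1, nad = -1, oaa = 1, nadh = 1, h_c = 1),
             subsystem = "malic_enzyme", role_tags = "nadh_producer",
             name = "malate dehydrogenase"),

    # redox housekeeping: NADPH -> NADH (energy-independent direction)
    reaction("THD", c(nadph = -1, nad = -1, nadp = 1, nadh = 1),
             subsystem = "redox", role_tags = "nadh_producer",
             name = "NAD(P)+ transhydrogenase"),

    # amino acid degradation
    reaction("SERD", c(ser_c = -1, pyr = 1, nh4_c = 1),
             subsystem = "aa_degradation", name = "serine dehydratase"),
    reaction("CYSDS", c(cys_c = -1, h2o_c = -1, pyr = 1, nh4_c = 1, h2s_c = 1),
             subsystem = "aa_degradation", name = "cysteine desulfhydrase"),
    reaction("THRDEG", c(thr_c = -1, h2o_c = -1, pyr = 1, co2_c = 1, nh4_c = 1),
             subsystem = "aa_degradation",
             name = "threonine degradation to pyruvate (lumped)"),
    reaction("THRD", c(thr_c = -1, coa = -1, nad = -1,
                       gly = 1, accoa = 1, nadh = 1, h_c = 1),
             subsystem = "aa_degradation", role_tags = "nadh_producer",
             name = "threonine dehydrogenase + KBL (lumped)"),
    # turnover drains so measured uptake can exceed the lumped biomass demand
    reaction("VALDM", c(val_c = -1), subsystem = "aa_degradation",
             role_tags = "demand", name = "valine turnover demand"),
    reaction("PHEDM", c(phe_c = -1), subsystem = "aa_degradation",
             role_tags = "demand", name = "phenylalanine turnover demand"),

    # energy
    # reversible: synthesis along the proton gradient, or ATP-driven proton
    # export (pH homeostasis) when the cytosol runs a proton surplus
    reaction("ATPS", setNames(c(-1, -1, -h_per_atp, 1, 1, h_per_atp - 1),
                              c("adp", "pi_c", "h_e", "atp", "h2o_c", "h_c")),
             reversible = TRUE, subsystem = "ATPase",
             role_tags = c("atp_producer_f0f1", "proton_importer"),
             name = "F0F1-ATPase"),
    reaction("ATPM", c(atp = -1, h2o_c = -1, adp = 1, pi_c = 1, h_c = 1),
             subsystem = "NGAM", name = "non-growth-associated maintenance"),

    # lumped biomass: ~33 mmol C/gDCW, GAM 23 mmol ATP/gDCW
    reaction("BIOMASS",
             c(g6p = -1.0, pg3 = -0.75, pep = -0.26, pyr = -1.4, oaa = -0.66,
               accoa = -0.9, coa = 0.9, e4p = -0.16, ru5p = -0.45, gap = -0.05,
               ser_c = -0.6, thr_c = -0.5, cys_c = -0.18, val_c = -0.8,
               phe_c = -0.35, gly = -0.45, nadph = -2.0, nadp = 2.0,
               atp = -23, h2o_c = -23, adp = 23, pi_c = 23, h_c = 23),
             subsystem = "biomass", name = "biomass (lumped, flux in 1/h)"))

  metabolic_network(mets, r, objective_id = "BIOMASS",
                    name = "oeni_reduced_central_carbon")
}
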