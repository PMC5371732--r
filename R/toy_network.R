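#' Curated reduced hepatocyte network
#'
#' Builds the packaged ~55-reaction fasting-state hepatocyte network used
#' throughout the cohort analysis. It is a deliberate reduction of liver
#' central metabolism that preserves every pathway the flux-phenotype
#' analysis interrogates:
#' \itemize{
#'   \item fatty-acid transport and beta-oxidation (per C16 FA: 7 NADH,
#'     7 FADH2, 8 acetyl-CoA) with a stoichiometrically coupled
#'     H2O2-producing side flux (\code{ros_yield_per_fa}, a free parameter);
#'   \item mitochondrial NNT (NADH + NADP+ -> NAD+ + NADPH), cytosolic GSR
#'     (GSSG + NADPH -> 2 GSH), GPX/PRDX peroxide detoxification
#'     (H2O2 + 2 GSH -> GSSG), de novo GSH synthesis from glutamate,
#'     cysteine and glycine, and a biliary GSH efflux;
#'   \item serine-glycine interconversion through SHMT with the THF /
#'     5,10-methylene-THF one-carbon couple, glycine cleavage, and
#'     one-carbon oxidation;
#'   \item gluconeogenesis from lactate, alanine, glutamine (via glutamate)
#'     and glycerol; a glycogenolysis source; the oxidative pentose
#'     phosphate shunt as the alternative cytosolic NADPH source;
#'   \item ketogenesis (acetoacetate, beta-hydroxybutyrate) and TCA +
#'     oxidative phosphorylation with oxygen uptake;
#'   \item VLDL assembly consuming a triglyceride pseudo-metabolite
#'     (glycerol + 3 FA) and an apoB protein-synthesis pseudo-reaction
#'     consuming amino acids in liver molar ratios;
#'   \item urea synthesis as the nitrogen sink, and boundary reactions for
#'     every metabolite of [assemble_subject_bounds()].
#' }
#' Carbon atoms are tracked per metabolite (cofactor couples carry zero) so
#' that carbon conservation of every internal reaction is testable.
#'
#' @param profiles amino-acid profile table; the liver molar ratios define
#'   the apoB pseudo-protein composition.
#' @param const physiology constants; \code{ros_yield_per_fa} and
#'   \code{ros_yield_per_aax} set the H2O2 coupling, \code{default_flux_ub}
#'   the generic finite flux cap.
#' @return a \code{metabolic_network} with objective \code{EX_vldltg_sec}.
#' @export
build_toy_hepatocyte_network <- function(profiles = aa_profiles(),
                                         const = physiology_constants()) {
  big <- const$default_flux_ub
  ros_fa <- const$ros_yield_per_fa
  ros_aax <- const$ros_yield_per_aax

  lr <- stats::setNames(profiles$liver_molar_ratio, profiles$aa)
  apob_in <- paste(sprintf("%s %s[c]", format(lr, digits = 6), names(lr)),
                   collapse = " + ")
  apob_carbons <- sum(lr * profiles$carbons)

  rx <- function(id, eq, subsystem, lower = 0, upper = big)
    data.frame(id = id, equation = eq, lower = lower, upper = upper,
               subsystem = subsystem, stringsAsFactors = FALSE)

  reactions <- rbind(
    ## exchanges (bounds are placeholders until apply_bounds)
    rx("EX_fa_up",        "-> fa[c]",        "exchange"),
    rx("EX_glycerol_up",  "-> glycerol[c]",  "exchange"),
    rx("EX_lac_up",       "-> lac[c]",       "exchange"),
    rx("EX_glycogen_up",  "-> glycogen[c]",  "exchange"),
    rx("EX_ala_up",       "-> ala[c]",       "exchange"),
    rx("EX_gln_up",       "-> gln[c]",       "exchange"),
    rx("EX_glu_up",       "-> glu[c]",       "exchange"),
    rx("EX_gly_up",       "-> gly[c]",       "exchange"),
    rx("EX_ser_up",       "-> ser[c]",       "exchange"),
    rx("EX_cys_up",       "-> cys[c]",       "exchange"),
    rx("EX_aax_up",       "-> aax[c]",       "exchange"),
    rx("EX_o2_up",        "-> o2[c]",        "exchange"),
    rx("EX_glc_sec",      "glc[c] ->",       "exchange"),
    rx("EX_acac_sec",     "acac[c] ->",      "exchange"),
    rx("EX_bhb_sec",      "bhb[c] ->",       "exchange"),
    rx("EX_vldltg_sec",   "vldl_tg[c] ->",   "exchange"),
    rx("EX_apob_sec",     "apob[c] ->",      "exchange"),
    rx("EX_gsh_sec",      "gsh[c] ->",       "exchange"),
    rx("EX_urea_sec",     "urea[c] ->",      "exchange"),
    rx("EX_co2_sec",      "co2[c] ->",       "exchange"),
    rx("EX_h2o_sec",      "h2o[c] ->",       "exchange"),

    ## glucose production
    rx("GLYCOGENOLYSIS", "glycogen[c] -> g6p[c]", "glycogenolysis"),
    rx("LDH",     "lac[c] + nad[c] -> pyr[c] + nadh[c]", "gluconeogenesis"),
    rx("ALATA",   "ala[c] -> pyr[c] + nh3[c]", "gluconeogenesis"),
    rx("GLNASE",  "gln[c] -> glu[c] + nh3[c]", "gluconeogenesis"),
    rx("GLUDH",   "glu[c] + 2 nad[c] -> pep[c] + 2 co2[c] + nh3[c] + 2 nadh[c]",
       "gluconeogenesis"),
    rx("AAXDEG",  sprintf(paste0("aax[c] + 2 nad[c] -> pyr[c] + 2 co2[c] + ",
                                 "1.45 nh3[c] + 2 nadh[c] + %s h2o2[c]"),
                          format(ros_aax, digits = 6)),
       "gluconeogenesis"),
    rx("CYSDEG",  "cys[c] -> pyr[c] + nh3[c]", "gluconeogenesis"),
    rx("PCPEPCK", "pyr[c] + atp[c] -> pep[c]", "gluconeogenesis"),
    rx("GNG",     "2 pep[c] + 2 nadh[c] + 2 atp[c] -> g6p[c] + 2 nad[c]",
       "gluconeogenesis"),
    rx("GLYCGNG", "2 glycerol[c] + 2 nad[c] -> g6p[c] + 2 nadh[c]",
       "gluconeogenesis"),
    rx("G6PASE",  "g6p[c] -> glc[c]", "gluconeogenesis"),
    rx("PPP",     "g6p[c] + 12 nadp[c] -> 12 nadph[c] + 6 co2[c]",
       "pentose phosphate pathway"),

    ## serine-glycine / one-carbon
    rx("SHMT",   "ser[c] + thf[c] <-> gly[c] + mlthf[c]",
       "serine-glycine/one-carbon", lower = -big),
    rx("SDS",    "ser[c] -> pyr[c] + nh3[c]", "serine-glycine/one-carbon"),
    rx("GCS",    "gly[c] + thf[c] + nad[c] -> co2[c] + mlthf[c] + nh3[c] + nadh[c]",
       "serine-glycine/one-carbon"),
    rx("MTHFOX", "mlthf[c] + nad[c] -> thf[c] + co2[c] + nadh[c]",
       "serine-glycine/one-carbon"),

    ## mitochondrial oxidation
    rx("PYRT",   "pyr[c] -> pyr[m]", "transport"),
    rx("PDH",    "pyr[m] + nad[m] -> accoa[m] + co2[c] + nadh[m]", "TCA cycle"),
    rx("TCA",    "accoa[m] + 3 nad[m] + fad[m] -> 2 co2[c] + 3 nadh[m] + fadh2[m]",
       "TCA cycle"),
    rx("FAT",    "fa[c] -> fa[m]", "fatty-acid oxidation"),
    rx("BETAOX", sprintf(paste0("fa[m] + 7 nad[m] + 7 fad[m] -> 8 accoa[m] + ",
                                "7 nadh[m] + 7 fadh2[m] + %s h2o2[c]"),
                         format(ros_fa, digits = 6)),
       "fatty-acid oxidation"),
    rx("KETO",   "2 accoa[m] -> acac[m]", "ketogenesis"),
    rx("BDH",    "acac[m] + nadh[m] -> bhb[m] + nad[m]", "ketogenesis"),
    rx("ACACT",  "acac[m] -> acac[c]", "transport"),
    rx("BHBT",   "bhb[m] -> bhb[c]", "transport"),
    rx("OXPHOSN", "nadh[m] + 0.5 o2[c] -> nad[m] + h2o[c] + 2.5 atp[c]",
       "oxidative phosphorylation"),
    rx("OXPHOSF", "fadh2[m] + 0.5 o2[c] -> fad[m] + h2o[c] + 1.5 atp[c]",
       "oxidative phosphorylation"),
    rx("ATPM",   "atp[c] ->", "ATP maintenance"),
    rx("NADHSH", "nadh[c] + nad[m] <-> nad[c] + nadh[m]", "transport",
       lower = -big),

    ## redox detoxification
    rx("NNT",    "nadh[m] + nadp[m] -> nad[m] + nadph[m]", "NNT"),
    rx("NADPHT", "nadph[m] + nadp[c] -> nadp[m] + nadph[c]", "transport"),
    rx("GSHSYN", "glu[c] + cys[c] + gly[c] + 2 atp[c] -> gsh[c]",
       "GSH de novo synthesis"),
    rx("GPX",    "h2o2[c] + 2 gsh[c] -> gssg[c] + 2 h2o[c]", "GPX/PRDX"),
    rx("GSR",    "gssg[c] + nadph[c] -> 2 gsh[c] + nadp[c]", "GSR"),

    ## export products
    rx("TGSYN",   "3 fa[c] + glycerol[c] + 2 atp[c] -> tg[c]", "VLDL assembly"),
    rx("VLDLASM", "tg[c] -> vldl_tg[c]", "VLDL assembly"),
    rx("APOBSYN", paste(apob_in, "+ 4 atp[c] -> apob[c]"), "protein synthesis"),
    rx("UREASYN", "2 nh3[c] + co2[c] + 2 atp[c] -> urea[c]", "urea output")
  )

  carbons <- c(fa = 16, glycerol = 3, lac = 3, glycogen = 6, glc = 6, g6p = 6,
               pep = 3, pyr = 3, accoa = 2, acac = 4, bhb = 4, co2 = 1,
               urea = 1, tg = 51, vldl_tg = 51, gsh = 10, gssg = 20,
               mlthf = 1, thf = 0, h2o = 0, h2o2 = 0, o2 = 0, nh3 = 0,
               nad = 0, nadh = 0, nadp = 0, nadph = 0, fad = 0, fadh2 = 0,
               atp = 0,
               stats::setNames(profiles$carbons, profiles$aa),
               apob = apob_carbons)

  network_from_reactions(reactions, carbons = carbons,
                         objective = "EX_vldltg_sec")
}
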