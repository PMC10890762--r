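## Deterministic synthetic mini-model generator and the packaged
## stress-response gene registry, so every stress mechanism is exercisable
## without any external reconstruction.

#' Build the packaged toy ME model
#'
#' Emits a small but mechanistically complete stress-coupled ME model:
#' glucose uptake through a periplasmic transporter, lumped glycolysis, a
#' lumped TCA cycle carried by an Fe(II) enzyme (with a mismetallated Mn
#' variant), electron transport with a high-yield Fe-S NADH dehydrogenase and
#' a lower-yield Fe-S-free alternative, an acetate overflow branch whose
#' kinase step has two interchangeable catalysts, amino-acid synthesis split
#' into four supplementable pools, a terpenoid-precursor step carried by an
#' essential heat-labile enzyme whose keff differs 0.01 vs 88.72 1/s between
#' the wild-type and heat-evolved kinetomes, a redundant homocysteine pathway
#' pair (a forced low-keff recycling step bypassed by a cheap main route),
#' pH-dependent membrane lipid synthesis, the cytoplasmic folding network
#' (DnaK, GroEL, Lon), HdeB protection of the periplasmic transporter, and
#' the ROS damage/repair cycle (YtfE repair, Fenton chemistry, Dps
#' sequestration, AhpC detoxification).
#'
#' Randomness only perturbs non-critical parameters (the heat-evolved jitter
#' on a few keffs and any extra enzymes); mechanism-critical constants (the
#' 0.01/88.72 keff pair, the unmodeled protein fraction) are fixed. The same
#' seed always yields an identical model.
#'
#' @param seed integer seed for the non-critical perturbations.
#' @param unmodeled_protein_fraction fraction of proteome mass outside the
#'   model scope (default 0.10).
#' @param total_proteome_mass grams protein per gDW (default 0.55).
#' @param n_extra_enzymes number of additional never-preferred amino-acid
#'   synthesis enzymes, for scaling exercises.
#' @param include_thermal,include_acid,include_oxidative switch the stress
#'   decorations on or off.
#' @return an \code{me_model} with keff vectors "wild_type" (active) and
#'   "heat_evolved".
#' @export
build_toy_model <- function(seed = 7, unmodeled_protein_fraction = 0.10,
                            total_proteome_mass = 0.55,
                            n_extra_enzymes = 0,
                            include_thermal = TRUE, include_acid = TRUE,
                            include_oxidative = TRUE) {
  rng <- local_rng(seed)

  m <- me_model(unmodeled_protein_fraction, total_proteome_mass)
  m$params$keff_ea_kj <- 25

  ## small molecules
  comp <- c(glc_e = "extracellular", ac_e = "extracellular",
            o2_e = "extracellular", lipid_c = "membrane")
  for (met in c("glc_e", "glc_c", "pyr_c", "accoa_c", "ac_c", "ac_e",
                "co2_c", "o2_e", "o2_c", "atp_c", "nadh_c", "aa_gen_c",
                "aa_ilv_c", "aa_metcys_c", "aa_aro_c", "rhcys_c", "cyst_c",
                "hcys_c", "q8_c", "fa_sat_c", "fa_unsat_c", "lipid_c",
                "dead_c")) {
    m <- add_metabolite(m, met, if (met %in% names(comp)) comp[[met]]
                        else "cytoplasm")
  }

  ## proteins: id, gene, mw, compartment, dHm, cp, tm, kf_ref, agg, metal,
  ## fe_s, category
  prot <- list(
    list("glcP", 45, "periplasm", 350, 6, 322, 3.0, 0.8, "none", 0, "transport"),
    list("glyK", 120, "cytoplasm", 600, 7, 317, 6.0, 0.4, "none", 0, "metabolism"),
    list("pdhA", 200, "cytoplasm", 600, 8, 335, 5.0, 0.3, "none", 0, "metabolism"),
    list("tcaA", 180, "cytoplasm", 600, 8, 316, 5.0, 0.6, "Fe2", 0, "metabolism"),
    list("nuoX", 520, "membrane", 600, 8, 330, 5.0, 0.3, "none", 2, "energy"),
    list("ndhX", 100, "membrane", 600, 8, 330, 5.0, 0.3, "none", 0, "energy"),
    list("ackA", 43, "cytoplasm", 600, 8, 328, 5.0, 0.3, "none", 0, "overflow"),
    list("purT", 43, "cytoplasm", 600, 8, 328, 5.0, 0.3, "none", 0, "overflow"),
    list("luxS", 19, "cytoplasm", 600, 7, 314, 4.0, 0.9, "none", 0, "metabolism"),
    list("metC", 43, "cytoplasm", 600, 8, 330, 5.0, 0.3, "none", 0, "metabolism"),
    list("aaS", 160, "cytoplasm", 600, 8, 318, 6.0, 0.3, "none", 0, "metabolism"),
    list("ilvD", 66, "cytoplasm", 600, 8, 330, 5.0, 0.3, "none", 1, "metabolism"),
    list("fabA", 80, "cytoplasm", 600, 8, 330, 5.0, 0.3, "none", 0, "metabolism"),
    list("dxr", 60, "cytoplasm", 600, 8, 312, 2.0, 2.5, "Mg2", 0, "metabolism"),
    list("dnaK", 69, "cytoplasm", 600, 8, 335, 5.0, 0.2, "none", 0, "chaperone"),
    list("groL", 400, "cytoplasm", 600, 8, 335, 5.0, 0.2, "none", 0, "chaperone"),
    list("lon", 87, "cytoplasm", 600, 8, 335, 5.0, 0.2, "none", 0, "protein_turnover"),
    list("hdeB", 12, "periplasm", 600, 8, 335, 5.0, 0.2, "none", 0, "chaperone"),
    list("dps", 19, "cytoplasm", 600, 8, 335, 5.0, 0.2, "none", 0, "oxidative_response"),
    list("ytfE", 25, "cytoplasm", 600, 8, 335, 5.0, 0.2, "none", 0, "oxidative_response"),
    list("ahpC", 21, "cytoplasm", 600, 8, 335, 5.0, 0.2, "none", 0, "oxidative_response"))
  for (p in prot) {
    m <- add_protein(m, p[[1]], gene = p[[1]], mw_kda = p[[2]],
                     compartment = p[[3]], dHm_kj_mol = p[[4]],
                     cp_kj_mol_k = p[[5]], tm_k = p[[6]], kf_ref = p[[7]],
                     agg = p[[8]], metal = p[[9]], fe_s = p[[10]],
                     category = p[[11]])
  }

  ## translation: amino acids (pool split) + ATP -> protein
  for (p in prot) {
    id <- p[[1]]; n_aa <- p[[2]] / m$params$aa_mw_kda
    st <- stats::setNames(-n_aa * m$params$aa_fractions,
                          m$params$aa_pools[names(m$params$aa_fractions)])
    st["atp_c"] <- -m$params$atp_per_aa * n_aa
    st[paste0("protein_", id)] <- 1
    m <- add_reaction(m, paste0("TR_", id), "translation", stoich = st)
  }

  ## exchanges (secretion positive, uptake negative)
  m <- add_reaction(m, "EX_glc", "exchange", stoich = c(glc_e = -1),
                    lb = -6, ub = 0)
  m <- add_reaction(m, "EX_o2", "exchange", stoich = c(o2_e = -1),
                    lb = -30, ub = 0)
  m <- add_reaction(m, "EX_ac", "exchange", stoich = c(ac_e = -1),
                    lb = 0, ub = 100)
  m <- add_reaction(m, "EX_co2", "exchange", stoich = c(co2_c = -1),
                    lb = 0, ub = 100)
  for (g in names(m$params$aa_pools)) {
    ex <- paste0("EX_aa_", g)
    m <- add_reaction(m, ex, "exchange",
                      stoich = stats::setNames(-1, m$params$aa_pools[[g]]),
                      lb = 0, ub = 0)
    m$params$aa_exchange[g] <- ex
  }

  ## central metabolism (lumped)
  mk <- function(id, st, cats, lb = 0, ub = 1000)
    add_reaction(m, id, "metabolic", stoich = st, catalysts = cats,
                 lb = lb, ub = ub)
  m <- mk("GLCt", c(glc_e = -1, glc_c = 1), "glcP")
  m <- mk("O2t", c(o2_e = -1, o2_c = 1), character())
  m <- mk("GLYC", c(glc_c = -1, pyr_c = 2, atp_c = 2, nadh_c = 2), "glyK")
  m <- mk("PDH", c(pyr_c = -1, accoa_c = 1, co2_c = 1, nadh_c = 1), "pdhA")
  m <- mk("TCA", c(accoa_c = -1, co2_c = 2, nadh_c = 3, atp_c = 1), "tcaA")
  m <- mk("NUO", c(nadh_c = -1, o2_c = -0.5, atp_c = 2.5), "nuoX")
  m <- mk("NDH", c(nadh_c = -1, o2_c = -0.5, atp_c = 1.2), "ndhX")
  m <- mk("ACK", c(accoa_c = -1, ac_c = 1, atp_c = 1), c("ackA", "purT"))
  m <- mk("ACt", c(ac_c = -1, ac_e = 1), character())
  ## amino-acid synthesis; the general route excretes a ribosylhomocysteine
  ## byproduct that must be recycled through the low-keff RHCC step
  m <- mk("AASYN", c(pyr_c = -1, atp_c = -2, aa_gen_c = 1, rhcys_c = 0.002),
          "aaS")
  m <- mk("ILVSYN", c(pyr_c = -1, atp_c = -2.5, aa_ilv_c = 1), "ilvD")
  m <- mk("AROSYN", c(pyr_c = -1.5, atp_c = -3, aa_aro_c = 1), "aaS")
  m <- mk("METSYN", c(hcys_c = -1, atp_c = -2, aa_metcys_c = 1), "metC")
  m <- mk("CYSTS", c(pyr_c = -1, atp_c = -2, cyst_c = 1), "aaS")
  m <- mk("RHCC", c(rhcys_c = -1, hcys_c = 1), "luxS")
  m <- mk("CYSTL", c(cyst_c = -1, hcys_c = 1, pyr_c = 1), "metC")
  ## essential terpenoid-precursor step: the thermo-sensitive bottleneck
  m <- mk("DXPR", c(pyr_c = -1, atp_c = -1, nadh_c = -1, q8_c = 1), "dxr")
  ## membrane lipids; composition of MEMSYN set per condition
  m <- mk("FASAT", c(accoa_c = -8, atp_c = -7, nadh_c = -14, fa_sat_c = 1),
          "fabA")
  m <- mk("FAUNSAT", c(accoa_c = -8, atp_c = -7, nadh_c = -15,
                       fa_unsat_c = 1), "fabA")
  m <- add_reaction(m, "MEMSYN", "metabolic", stoich = c(lipid_c = 1),
                    lipid_pseudo = TRUE)
  ## a permanently blocked reaction pair (dead-end bounds)
  m <- add_reaction(m, "DEADSRC", "metabolic",
                    stoich = c(pyr_c = -1, dead_c = 1), lb = 0, ub = 0)
  m <- mk("DEADRX", c(dead_c = -1, pyr_c = 1), "glyK")

  ## biomass: flux pinned to mu
  m <- add_reaction(m, "GROWTH", "biomass",
                    stoich = c(atp_c = -35, q8_c = -0.02, lipid_c = -0.02,
                               pyr_c = -1),
                    flux_fixed_mu = 1)
  ## unmodeled protein sink: one gram of generic protein per unit flux
  n_aa_g <- 1 / m$params$aa_mw_kda
  st_u <- stats::setNames(-n_aa_g * m$params$aa_fractions,
                          m$params$aa_pools[names(m$params$aa_fractions)])
  st_u["atp_c"] <- -m$params$atp_per_aa * n_aa_g
  m <- add_reaction(m, "UNMODELED_PROTEIN", "sink", stoich = st_u,
                    unmodeled = TRUE)

  ## optional extra enzymes: redundant, costly amino-acid synthesis routes
  extra_keffs <- numeric()
  if (n_extra_enzymes > 0) {
    for (i in seq_len(n_extra_enzymes)) {
      pid <- sprintf("extE%02d", i)
      m <- add_protein(m, pid, gene = pid,
                       mw_kda = round(30 + 30 * rng(), 1),
                       compartment = "cytoplasm", category = "metabolism")
      n_aa <- protein_spec(m, pid)$mw_kda / m$params$aa_mw_kda
      st <- stats::setNames(-n_aa * m$params$aa_fractions,
                            m$params$aa_pools[names(m$params$aa_fractions)])
      st["atp_c"] <- -m$params$atp_per_aa * n_aa
      st[paste0("protein_", pid)] <- 1
      m <- add_reaction(m, paste0("TR_", pid), "translation", stoich = st)
      rid <- sprintf("EXTRA%02d", i)
      m <- add_reaction(m, rid, "metabolic",
                        stoich = c(pyr_c = -1, atp_c = -2, aa_gen_c = 1),
                        catalysts = pid)
      extra_keffs[rid] <- round(0.5 + 1.5 * rng(), 3)
    }
  }

  ## stress decorations
  if (include_thermal) {
    for (pid in c("dxr", "glyK", "tcaA", "aaS", "luxS")) {
      m <- build_folding_network(m, pid)
      m <- lon_degradation(m, pid)
    }
  }
  if (include_acid) {
    m <- build_folding_network(m, "glcP")
    m <- lon_degradation(m, "glcP")
    m <- add_hdeb_protection(m, "glcP")
  }
  if (include_oxidative) {
    m <- add_fenton_and_dps(m)
    m <- add_fe_s_cycle(m, "nuoX", rate_per_nm_h = 6)
    m <- add_fe_s_cycle(m, "ilvD", rate_per_nm_h = 40)
    m <- add_demetallation(m, "tcaA", rate_per_nm_h = 60)
    m <- mismetallation_variant(m, "tcaA", "Mn2", keff_penalty = 0.5)
  }

  ## kinetomes (s^-1); the wild-type/heat-evolved pair differs at the
  ## terpenoid bottleneck (0.01 vs 88.72), the recycling step (0.01 vs
  ## 28.8), the blocked reaction, and small jitter on central enzymes
  wild <- c(GLCt = 40, GLYC = 4, PDH = 10, TCA = 3, NUO = 12, NDH = 6,
            ACK = 50, AASYN = 3, ILVSYN = 8, AROSYN = 8, METSYN = 15,
            CYSTS = 15, RHCC = 0.01, CYSTL = 12, DXPR = 0.01, FASAT = 10,
            FAUNSAT = 10, DEADRX = 5, extra_keffs)
  if (include_oxidative) {
    ## repair runs through scarce YtfE capacity (effective events per hour)
    wild <- c(wild, AHPX = 50, DPSSEQ = 0.5, FESREP_nuoX = 1e-4,
              FESREP_ilvD = 3e-5, REMETAL_tcaA = 1e-4)
  }
  evolved <- wild
  evolved["DXPR"] <- 88.72
  evolved["RHCC"] <- 28.8
  evolved["DEADRX"] <- 10
  for (rid in c("GLYC", "PDH", "NUO", "TCA"))
    evolved[rid] <- round(wild[rid] * (0.95 + 0.1 * rng()), 4)
  m <- set_keff_vector(m, "wild_type", wild, activate = TRUE)
  m <- set_keff_vector(m, "heat_evolved", evolved)
  m
}

## Deterministic uniform(0,1) stream independent of the global RNG state
## (Lehmer / Park-Miller).
local_rng <- function(seed) {
  state <- (as.integer(seed) %% 2147483646L) + 1L
  function() {
    state <<- as.integer((as.double(state) * 16807) %% 2147483647)
    state / 2147483647
  }
}

#' Load the packaged stress-response gene registry
#'
#' Eleven stress-response genes (nine oxidative, one thermal, one acid) that
#' single-stress models contribute beyond the base reconstruction, packaged
#' as a TSV fixture. Parsing validates row count and stress classes.
#'
#' @param path TSV path; defaults to the packaged copy.
#' @return data.frame with columns gene, symbol, function., stress.
#' @export
load_stress_gene_registry <- function(path = system.file(
  "extdata", "stress_gene_registry.tsv", package = "mestress")) {
  if (!nzchar(path) || !file.exists(path)) stop("registry TSV not found")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) != 11)
    stop("registry corrupt: expected 11 genes, found ", nrow(tab))
  if (!all(tab$stress %in% c("Oxidative", "Thermal", "Acid")))
    stop("registry corrupt: unknown stress class")
  tab
}
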