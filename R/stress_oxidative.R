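## Oxidative stress: ROS-dependent damage and repair of metalloproteins --
## demetallation, mismetallation with alternative metals, Fe-S cluster
## oxidation and YtfE-mediated repair, the Fenton reaction of free Fe(II)
## with hydrogen peroxide, and Dps iron sequestration.

#' ROS environment
#'
#' Basal intracellular superoxide and hydrogen peroxide concentrations plus a
#' common multiplier (the "0.01x to 10x basal level" axis). Effective levels
#' are basal times multiplier.
#'
#' @param basal_superoxide_nm basal superoxide concentration (nM).
#' @param basal_h2o2_nm basal hydrogen peroxide concentration (nM).
#' @param multiplier common fold-change on both species (>= 0).
#' @return an object of class \code{ros_environment}.
#' @export
ros_environment <- function(basal_superoxide_nm = 0.02, basal_h2o2_nm = 50,
                            multiplier = 1) {
  stopifnot(basal_superoxide_nm >= 0, basal_h2o2_nm >= 0, multiplier >= 0)
  structure(list(basal_superoxide_nm = basal_superoxide_nm,
                 basal_h2o2_nm = basal_h2o2_nm, multiplier = multiplier,
                 superoxide_nm = basal_superoxide_nm * multiplier,
                 h2o2_nm = basal_h2o2_nm * multiplier),
            class = "ros_environment")
}

#' Damage flux on a target enzyme
#'
#' First-order in the effective superoxide level and in the target enzyme
#' amount: \code{rate_per_nm_h * superoxide_nm * amount}. Inside the LP the
#' same kinetics appear as a forced consumption of native enzyme per unit of
#' catalyzed flux, which must be compensated by extra synthesis or repair.
#'
#' @param rule one damage rule (list/row with \code{rate_per_nm_h}).
#' @param enzyme_amount enzyme amount proxy, e.g. its synthesis flux (>= 0).
#' @param ros a \code{ros_environment}.
#' @return damage flux in the units of \code{enzyme_amount}.
#' @export
damage_flux <- function(rule, enzyme_amount, ros) {
  stopifnot(all(enzyme_amount >= 0), rule$rate_per_nm_h >= 0)
  rule$rate_per_nm_h * ros$superoxide_nm * enzyme_amount
}

ensure_metabolite <- function(model, id, compartment = "cytoplasm",
                              is_macromolecule = FALSE) {
  if (id %in% model$metabolites$id) return(model)
  add_metabolite(model, id, compartment, is_macromolecule)
}

#' Add an iron-sulfur damage/repair cycle for a protein
#'
#' ROS oxidizes the protein's Fe-S cluster: per unit of catalyzed flux a
#' superoxide-proportional share of the native enzyme is converted to a
#' damaged species, releasing Fe(II). The damaged form is either discarded
#' (free sink, forcing resynthesis) or repaired by the YtfE machinery, which
#' re-inserts Fe(II) at an ATP cost and is itself coupled through its keff.
#'
#' @param model an \code{me_model}; protein must have \code{fe_s >= 1} and a
#'   protein "ytfE" must be registered.
#' @param protein_id damage target.
#' @param rate_per_nm_h damage rate constant (per nM superoxide per hour).
#' @return the modified model.
#' @export
add_fe_s_cycle <- function(model, protein_id, rate_per_nm_h) {
  p <- protein_spec(model, protein_id)
  if (p$fe_s < 1) stop(protein_id, " has no Fe-S cluster")
  if (!"ytfE" %in% model$proteins$id) stop("repair protein ytfE not registered")
  dmg <- paste0("damaged_", protein_id)
  model <- ensure_metabolite(model, dmg, p$compartment, TRUE)
  model <- ensure_metabolite(model, "fe2_c")
  model <- add_reaction(model, paste0("FESREP_", protein_id), "repair",
                        stoich = stats::setNames(
                          c(-1, -1, -10, 1),
                          c(dmg, "fe2_c", "atp_c",
                            paste0("protein_", protein_id))),
                        catalysts = "ytfE")
  model <- add_reaction(model, paste0("SINK_damaged_", protein_id), "sink",
                        stoich = stats::setNames(-1, dmg))
  model$damage_rules <- rbind(model$damage_rules, data.frame(
    target = protein_id, mechanism = "fe_s_oxidation",
    rate_per_nm_h = rate_per_nm_h,
    repair_id = paste0("FESREP_", protein_id), alt_metal = NA_character_,
    keff_penalty = NA_real_, stringsAsFactors = FALSE))
  model
}

#' Add ROS demetallation of an Fe(II) protein
#'
#' Superoxide strips the Fe(II) cofactor: per unit flux a ROS-proportional
#' share of the holo enzyme becomes the apo form, releasing free Fe(II).
#' Re-metallation (apo + Fe2+ -> holo) runs spontaneously at a small ATP
#' cost; the apo form can also be discarded.
#'
#' @param model an \code{me_model}; protein must carry \code{metal == "Fe2"}.
#' @param protein_id damage target.
#' @param rate_per_nm_h damage rate constant (per nM superoxide per hour).
#' @return the modified model.
#' @export
add_demetallation <- function(model, protein_id, rate_per_nm_h) {
  p <- protein_spec(model, protein_id)
  if (!identical(p$metal, "Fe2")) stop(protein_id, " is not an Fe(II) protein")
  apo <- paste0("apo_", protein_id)
  model <- ensure_metabolite(model, apo, p$compartment, TRUE)
  model <- ensure_metabolite(model, "fe2_c")
  if (!"ytfE" %in% model$proteins$id) stop("repair protein ytfE not registered")
  model <- add_reaction(model, paste0("REMETAL_", protein_id), "repair",
                        stoich = stats::setNames(
                          c(-1, -1, -1, 1),
                          c(apo, "fe2_c", "atp_c",
                            paste0("protein_", protein_id))),
                        catalysts = "ytfE")
  model <- add_reaction(model, paste0("SINK_apo_", protein_id), "sink",
                        stoich = stats::setNames(-1, apo))
  model$damage_rules <- rbind(model$damage_rules, data.frame(
    target = protein_id, mechanism = "demetallation",
    rate_per_nm_h = rate_per_nm_h,
    repair_id = paste0("REMETAL_", protein_id), alt_metal = NA_character_,
    keff_penalty = NA_real_, stringsAsFactors = FALSE))
  model
}

#' Add the Fenton reaction, DNA repair cost, and Dps iron sequestration
#'
#' A forced hydrogen peroxide influx scales with the ROS environment. Free
#' Fe(II) reacts with it to hydroxyl radicals, booked as DNA damage that must
#' be repaired at an ATP cost; alternatively AhpC reduces the peroxide (NADH
#' cost) and Dps sequesters free Fe(II) at a protein-capacity-coupled rate,
#' cutting the Fenton flux off at its substrate.
#'
#' @param model an \code{me_model}; proteins "dps" and "ahpC" must be
#'   registered.
#' @return the modified model.
#' @export
add_fenton_and_dps <- function(model) {
  for (pr in c("dps", "ahpC"))
    if (!pr %in% model$proteins$id) stop("protein ", pr, " not registered")
  model <- ensure_metabolite(model, "fe2_c")
  model <- ensure_metabolite(model, "h2o2_c")
  model <- ensure_metabolite(model, "dna_dmg_c")
  model <- add_reaction(model, "H2O2GEN", "damage",
                        stoich = c(h2o2_c = 1), ros_forced = TRUE)
  model <- add_reaction(model, "FENTON", "damage",
                        stoich = c(fe2_c = -1, h2o2_c = -1, dna_dmg_c = 1))
  model <- add_reaction(model, "DNAREP", "repair",
                        stoich = c(dna_dmg_c = -1, atp_c = -12))
  model <- add_reaction(model, "DPSSEQ", "repair",
                        stoich = c(fe2_c = -1), catalysts = "dps")
  model <- add_reaction(model, "AHPX", "metabolic",
                        stoich = c(h2o2_c = -1, nadh_c = -0.3),
                        catalysts = "ahpC")
  ## trace iron uptake so repair can run even when no damage releases Fe(II)
  add_reaction(model, "EX_fe2", "exchange", stoich = c(fe2_c = -1),
               lb = -0.01, ub = 0)
}

#' Add a mismetallated variant of an Fe(II) enzyme
#'
#' Clones the protein with an alternative metal cofactor and a keff penalty
#' (< 1): the variant catalyzes the same reactions less efficiently but is
#' not a ROS target, so under oxidative stress the LP can trade catalytic
#' efficiency for damage immunity. The variant inherits the folding behavior
#' of its parent.
#'
#' @param model an \code{me_model}.
#' @param protein_id Fe(II) protein to clone.
#' @param alt_metal alternative metal, e.g. "Mn2".
#' @param keff_penalty multiplicative keff factor in (0, 1).
#' @return the modified model.
#' @export
mismetallation_variant <- function(model, protein_id, alt_metal = "Mn2",
                                   keff_penalty = 0.35) {
  p <- protein_spec(model, protein_id)
  if (!identical(p$metal, "Fe2")) stop(protein_id, " is not an Fe(II) protein")
  if (keff_penalty >= 1 || keff_penalty <= 0)
    stop("keff_penalty must lie in (0, 1)")
  vid <- paste0(protein_id, "_", tolower(sub("2$", "", alt_metal)))
  was_folding <- p$folding
  model <- add_protein(model, vid, gene = paste0(p$gene, "::", alt_metal),
                       mw_kda = p$mw_kda, compartment = p$compartment,
                       dHm_kj_mol = p$dHm_kj_mol, cp_kj_mol_k = p$cp_kj_mol_k,
                       tm_k = p$tm_k, kf_ref = p$kf_ref, agg = p$agg,
                       metal = alt_metal, fe_s = p$fe_s,
                       category = p$category, folding = FALSE)
  ## clone the translation reaction
  tr <- model$reactions[[paste0("TR_", protein_id)]]
  st <- tr$stoich
  names(st)[names(st) %in% paste0(c("protein_", "unfolded_"), protein_id)] <-
    paste0("protein_", vid)
  model <- add_reaction(model, paste0("TR_", vid), "translation",
                        stoich = st, lb = tr$lb, ub = tr$ub)
  if (was_folding) model <- build_folding_network(model, vid)
  ## register as alternative catalyst wherever the parent catalyzes
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    if (protein_id %in% r$catalysts && r$kind != "folding" &&
        is.na(r$pathway)) {
      model$reactions[[rid]]$catalysts <- c(r$catalysts, vid)
    }
  }
  model$keff_penalty[[vid]] <- keff_penalty
  ## record the alternative on the parent's demetallation rule, if present
  hit <- model$damage_rules$target == protein_id &
    model$damage_rules$mechanism == "demetallation"
  if (any(hit)) {
    model$damage_rules$alt_metal[hit] <- alt_metal
    model$damage_rules$keff_penalty[hit] <- keff_penalty
  }
  model
}

#' Write the damage-rule table to TSV
#' @param model an \code{me_model}.
#' @param path output file; columns target_id, mechanism, rate_per_nm_h,
#'   repair_id, alt_metal, keff_penalty.
#' @return invisibly, the path.
#' @export
write_damage_rules <- function(model, path) {
  tab <- model$damage_rules
  names(tab)[names(tab) == "target"] <- "target_id"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a damage-rule table from TSV
#' @param path TSV written by \code{\link{write_damage_rules}}.
#' @return data.frame in the model's internal damage-rule layout.
#' @export
read_damage_rules <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "target_id"] <- "target"
  tab
}
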