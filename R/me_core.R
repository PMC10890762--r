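## Core of the growth-coupled metabolism-and-expression (ME) model:
## model container, mu-parameterized LP assembly, bisection on growth rate,
## fixed-growth optimization, knockouts.

R_GAS <- 8.314e-3   # kJ mol^-1 K^-1

#' Create an empty ME model
#'
#' An ME model couples a metabolic network to the synthesis cost of its own
#' enzymes: a reaction carrying flux v and catalyzed by an enzyme with
#' effective turnover rate keff forces enzyme synthesis at rate mu*v/keff.
#' The container holds metabolites (small molecules and macromolecule
#' species), reactions with optionally growth-rate-dependent stoichiometry,
#' protein specifications, named keff vectors, and the stress-response
#' parameter blocks consumed at LP assembly time.
#'
#' @param unmodeled_protein_fraction fraction of total proteome mass reserved
#'   for proteins outside the model scope (default 0.10).
#' @param total_proteome_mass grams of protein per gram dry weight
#'   (default 0.55).
#' @return an object of class \code{me_model}.
#' @export
me_model <- function(unmodeled_protein_fraction = 0.10,
                     total_proteome_mass = 0.55) {
  stopifnot(unmodeled_protein_fraction >= 0, unmodeled_protein_fraction < 1,
            total_proteome_mass > 0)
  structure(list(
    metabolites = data.frame(id = character(), compartment = character(),
                             is_macromolecule = logical(),
                             stringsAsFactors = FALSE),
    reactions = list(),
    proteins = empty_protein_table(),
    keff_vectors = list(),
    active_keff = NA_character_,
    keff_penalty = list(),     # catalyst id -> multiplicative keff penalty
    damage_rules = empty_damage_table(),
    params = list(
      unmodeled_protein_fraction = unmodeled_protein_fraction,
      total_proteome_mass = total_proteome_mass,
      aa_mw_kda = 0.109,
      atp_per_aa = 4.3,
      keff_ea_kj = 40,          # Arrhenius slope of metabolic keffs
      t_ref_k = 310.15,
      mu_max_scan = 3,
      growth_reaction = "GROWTH",
      aa_exchange = character(),  # named: group -> exchange reaction id
      aa_uptake_cap = 3,
      aa_fractions = c(gen = 0.80, ilv = 0.10, metcys = 0.05, aro = 0.05),
      aa_pools = c(gen = "aa_gen_c", ilv = "aa_ilv_c",
                   metcys = "aa_metcys_c", aro = "aa_aro_c"),
      ## pathway coupling rates are effective clients-per-chaperone-hour
      ## scales, not single-molecule turnover numbers
      folding = list(kd_base = 2e-4, kg_base = 5e-4, hb_base = 2e-4,
                     kf_scale = 2e-4, kf_ea_kj = -250, lon_keff = 2,
                     atp_dnak = 5, atp_groel = 14, keq_cap = 1e6)
    ),
    acid = list(slope_kj_per_ph = 6, hdeb_gate_ph = 6.0,
                lipid_table = data.frame(ph = c(5, 7),
                                         sat = c(0.45, 0.70),
                                         unsat = c(0.55, 0.30)),
                activity_table = data.frame(ph = c(4.5, 5, 6, 7, 7.5),
                                            factor = c(0.70, 0.76, 0.88, 1, 1))),
    ros = list(basal_superoxide_nm = 0.02, basal_h2o2_nm = 50,
               h2o2_influx_per_nm = 1e-4)
  ), class = "me_model")
}

empty_protein_table <- function() {
  data.frame(id = character(), gene = character(), mw_kda = numeric(),
             compartment = character(), dHm_kj_mol = numeric(),
             cp_kj_mol_k = numeric(), tm_k = numeric(), kf_ref = numeric(),
             agg = numeric(), metal = character(), fe_s = integer(),
             category = character(), folding = logical(),
             stringsAsFactors = FALSE)
}

empty_damage_table <- function() {
  data.frame(target = character(), mechanism = character(),
             rate_per_nm_h = numeric(), repair_id = character(),
             alt_metal = character(), keff_penalty = numeric(),
             stringsAsFactors = FALSE)
}

#' Add a metabolite to an ME model
#' @param model an \code{me_model}.
#' @param id metabolite id (unique).
#' @param compartment one of cytoplasm, periplasm, membrane, extracellular.
#' @param is_macromolecule TRUE for protein/complex species.
#' @return the modified model.
#' @export
add_metabolite <- function(model, id,
                           compartment = c("cytoplasm", "periplasm",
                                           "membrane", "extracellular"),
                           is_macromolecule = FALSE) {
  compartment <- match.arg(compartment)
  if (id %in% model$metabolites$id) stop("duplicate metabolite id: ", id)
  model$metabolites <- rbind(model$metabolites,
    data.frame(id = id, compartment = compartment,
               is_macromolecule = is_macromolecule, stringsAsFactors = FALSE))
  model
}

#' Add a reaction to an ME model
#'
#' Stoichiometric coefficients may depend linearly on the growth rate mu:
#' the evaluated coefficient is \code{stoich + mu * stoich_mu}.
#'
#' @param model an \code{me_model}.
#' @param id reaction id (unique).
#' @param kind reaction class; one of metabolic, translation,
#'   complex_formation, folding, damage, repair, exchange, sink, biomass.
#' @param stoich named numeric, constant part (negative = consumed).
#' @param stoich_mu named numeric, mu-proportional part.
#' @param lb,ub flux bounds (mmol gDW^-1 h^-1).
#' @param catalysts character vector of alternative catalyzing proteins
#'   (OR rule); each alternative becomes its own LP column.
#' @param flux_fixed_mu if not NA, flux is pinned to
#'   \code{flux_fixed_mu * mu} at assembly (used by the biomass reaction).
#' @param pathway for folding/degradation reactions: one of spontaneous,
#'   dnaK, groEL, hdeB, lon.
#' @param target protein id a folding/degradation/repair reaction acts on.
#' @param ros_forced TRUE for the hydrogen peroxide influx whose flux is set
#'   by the ROS environment.
#' @param lipid_pseudo TRUE for the membrane pseudo-reaction whose fatty-acid
#'   coefficients are set from the pH-dependent lipid composition.
#' @param unmodeled TRUE for the unmodeled-protein sink (flux pinned to
#'   \code{unmodeled_protein_fraction * total_proteome_mass * mu}).
#' @return the modified model.
#' @export
add_reaction <- function(model, id, kind, stoich = numeric(),
                         stoich_mu = numeric(), lb = 0, ub = 1000,
                         catalysts = character(), flux_fixed_mu = NA_real_,
                         pathway = NA_character_, target = NA_character_,
                         ros_forced = FALSE, lipid_pseudo = FALSE,
                         unmodeled = FALSE) {
  kinds <- c("metabolic", "translation", "complex_formation", "folding",
             "damage", "repair", "exchange", "sink", "biomass")
  if (!kind %in% kinds) stop("unknown reaction kind: ", kind)
  if (id %in% names(model$reactions)) stop("duplicate reaction id: ", id)
  if (lb > ub) stop("reaction ", id, ": lower bound exceeds upper bound")
  model$reactions[[id]] <- list(
    id = id, kind = kind, stoich = stoich, stoich_mu = stoich_mu,
    lb = lb, ub = ub, catalysts = catalysts, flux_fixed_mu = flux_fixed_mu,
    pathway = pathway, target = target, ros_forced = ros_forced,
    lipid_pseudo = lipid_pseudo, unmodeled = unmodeled)
  model
}

#' Add a protein specification
#'
#' Registers the protein and declares its native species
#' \code{protein_<id>} plus a free excess sink, so synthesis can exceed
#' catalytic demand (the coupling is a lower bound on synthesis).
#'
#' @param model an \code{me_model}.
#' @param id protein id.
#' @param gene gene name (knockout handle).
#' @param mw_kda molecular weight in kDa (g/mmol).
#' @param compartment cytoplasm, periplasm or membrane.
#' @param dHm_kj_mol,cp_kj_mol_k,tm_k Gibbs-Helmholtz stability parameters:
#'   melting enthalpy (kJ/mol), heat-capacity change (kJ/mol/K), melting
#'   temperature (K).
#' @param kf_ref reference folding rate (s^-1) at 37 C.
#' @param agg aggregation propensity (dimensionless, >= 0).
#' @param metal metal cofactor: Fe2, Mn2, Co2, Mg2 or none.
#' @param fe_s number of iron-sulfur clusters.
#' @param category functional category tag.
#' @param folding TRUE if the protein is routed through the folding network
#'   (translation yields the unfolded species).
#' @return the modified model.
#' @export
add_protein <- function(model, id, gene, mw_kda,
                        compartment = c("cytoplasm", "periplasm", "membrane"),
                        dHm_kj_mol = 450, cp_kj_mol_k = 8, tm_k = 330,
                        kf_ref = 5, agg = 0.5, metal = "none", fe_s = 0L,
                        category = "metabolism", folding = FALSE) {
  compartment <- match.arg(compartment)
  stopifnot(mw_kda > 0, tm_k > 273, agg >= 0, fe_s >= 0)
  if (id %in% model$proteins$id) stop("duplicate protein id: ", id)
  model$proteins <- rbind(model$proteins, data.frame(
    id = id, gene = gene, mw_kda = mw_kda, compartment = compartment,
    dHm_kj_mol = dHm_kj_mol, cp_kj_mol_k = cp_kj_mol_k, tm_k = tm_k,
    kf_ref = kf_ref, agg = agg, metal = metal, fe_s = as.integer(fe_s),
    category = category, folding = folding, stringsAsFactors = FALSE))
  model <- add_metabolite(model, paste0("protein_", id), compartment,
                          is_macromolecule = TRUE)
  add_reaction(model, paste0("SINK_protein_", id), "sink",
               stoich = stats::setNames(-1, paste0("protein_", id)))
}

protein_spec <- function(model, id) {
  i <- match(id, model$proteins$id)
  if (is.na(i)) stop("unknown protein: ", id)
  as.list(model$proteins[i, ])
}

#' Register a keff vector
#' @param model an \code{me_model}.
#' @param label vector label, e.g. "wild_type" or "heat_evolved".
#' @param values named numeric, reaction id -> keff in s^-1.
#' @param activate make this the active vector.
#' @return the modified model.
#' @export
set_keff_vector <- function(model, label, values, activate = FALSE) {
  if (any(values <= 0)) stop("keff values must be positive")
  model$keff_vectors[[label]] <- values
  if (activate || is.na(model$active_keff)) model$active_keff <- label
  model
}

#' Stress condition
#'
#' @param temp_c temperature in degrees Celsius.
#' @param ph extracellular pH.
#' @param ros_mult multiplier on the basal ROS level (1 = unstressed).
#' @param aa_supplement amino-acid supplementation preset: none, full,
#'   minus_ile_val, minus_met_cys, minus_phe_trp_tyr.
#' @return an object of class \code{stress_condition}.
#' @export
stress_condition <- function(temp_c = 37, ph = 7.0, ros_mult = 1,
                             aa_supplement = c("none", "full", "minus_ile_val",
                                               "minus_met_cys",
                                               "minus_phe_trp_tyr")) {
  aa_supplement <- match.arg(aa_supplement)
  stopifnot(ros_mult >= 0)
  if (temp_c < 20 || temp_c > 50)
    warning("temperature ", temp_c, " C outside the validity window 20-50 C")
  if (ph < 4.5 || ph > 7.5)
    warning("pH ", ph, " outside the validity window 4.5-7.5")
  structure(list(temp_c = temp_c, ph = ph, ros_mult = ros_mult,
                 aa_supplement = aa_supplement, t_k = temp_c + 273.15),
            class = "stress_condition")
}

#' Enzyme synthesis demand for a catalyzed flux
#'
#' The coupling at the heart of an ME model: a metabolic flux v catalyzed by
#' an enzyme with effective turnover rate keff requires enzyme synthesis at
#' rate mu*v/keff. keff is given in s^-1 as conventionally printed and is
#' converted to h^-1 internally, since fluxes and mu are per hour.
#'
#' @param v metabolic flux (mmol gDW^-1 h^-1, >= 0).
#' @param mu growth rate (h^-1, >= 0).
#' @param keff effective turnover rate (s^-1, > 0).
#' @return enzyme synthesis flux (mmol gDW^-1 h^-1).
#' @export
enzyme_demand <- function(v, mu, keff) {
  if (any(keff <= 0)) stop("keff must be positive")
  stopifnot(all(v >= 0), all(mu >= 0))
  mu * v / (keff * 3600)
}

## Arrhenius factor applied to metabolic keffs
keff_temperature_factor <- function(model, t_k) {
  exp(-model$params$keff_ea_kj / R_GAS * (1 / t_k - 1 / model$params$t_ref_k))
}

## effective keff (s^-1) of one catalyst alternative of one reaction
effective_keff <- function(model, rxn, catalyst, condition) {
  keffs <- model$keff_vectors[[model$active_keff]]
  k <- keffs[rxn$id]
  if (is.na(k)) stop("no keff entry for catalyzed reaction ", rxn$id)
  k <- unname(k) * keff_temperature_factor(model, condition$t_k)
  p <- protein_spec(model, catalyst)
  if (p$compartment == "membrane")
    k <- k * membrane_activity_factor(model, condition$ph)
  pen <- model$keff_penalty[[catalyst]]
  if (!is.null(pen)) k <- k * pen
  k
}

## folding-pathway keff (s^-1); encodes the competitive pathway partition:
## spontaneous folding slows with temperature and aggregation propensity,
## chaperone routes get agg-weighted boosts.
folding_keff <- function(model, p, pathway, condition) {
  fp <- model$params$folding
  switch(pathway,
    spontaneous = {
      kf_t <- exp(-fp$kf_ea_kj / R_GAS *
                    (1 / condition$t_k - 1 / model$params$t_ref_k))
      p$kf_ref * fp$kf_scale * kf_t / (1 + p$agg)
    },
    dnaK = fp$kd_base * (1 + p$agg),
    groEL = fp$kg_base * (1 + p$agg)^2,
    hdeB = fp$hb_base,
    lon = fp$lon_keff,
    stop("unknown folding pathway: ", pathway))
}

## unfolding equilibrium constant routed by compartment, capped for LP scaling
species_keq <- function(model, p, condition) {
  keq <- if (p$compartment == "periplasm") {
    periplasmic_unfolding_keq(p, condition$t_k, condition$ph,
                              model$acid$slope_kj_per_ph)
  } else {
    unfolding_keq(p, condition$t_k)
  }
  min(keq, model$params$folding$keq_cap)
}

#' Assemble the linear program at a fixed growth rate
#'
#' Evaluates all mu-dependent stoichiometry at \code{mu}, expands alternative
#' catalysts into separate columns, adds enzyme-usage coupling terms
#' (mu/keff per unit flux on the native catalyst species), ROS damage
#' consumption terms, folding-partition rows (folded share limited to
#' 1/(1+Keq) of translation), and the proteome budget row pinning modeled
#' protein synthesis mass to
#' \code{(1 - unmodeled_protein_fraction) * mu * total_proteome_mass}.
#'
#' @param model an \code{me_model}.
#' @param mu growth rate (h^-1, >= 0).
#' @param condition a \code{stress_condition}.
#' @return a list with the LP pieces (\code{mat}, \code{dir}, \code{rhs},
#'   \code{lb}, \code{ub}) and bookkeeping (\code{cols}: column/reaction/
#'   catalyst map; \code{row_ids}; \code{met_rows}).
#' @export
assemble_lp <- function(model, mu, condition = stress_condition()) {
  stopifnot(inherits(model, "me_model"), mu >= 0)
  if (is.na(model$active_keff)) stop("no active keff vector")
  mets <- model$metabolites$id
  rxns <- model$reactions

  ## column expansion over catalyst alternatives
  cols <- do.call(rbind, lapply(rxns, function(r) {
    if (length(r$catalysts) > 1) {
      data.frame(col = paste0(r$id, "__", r$catalysts), rxn = r$id,
                 catalyst = r$catalysts, stringsAsFactors = FALSE)
    } else {
      data.frame(col = r$id, rxn = r$id,
                 catalyst = if (length(r$catalysts)) r$catalysts
                            else NA_character_,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(cols) <- NULL
  nc <- nrow(cols)

  folding_prots <- model$proteins$id[model$proteins$folding]
  fold_rows <- if (length(folding_prots))
    paste0("fold_partition_", folding_prots) else character(0)
  row_ids <- c(mets, fold_rows, "proteome_budget")
  nr <- length(row_ids)
  mat <- matrix(0, nr, nc, dimnames = list(row_ids, cols$col))
  dir <- c(rep("==", length(mets)),
           rep("<=", length(folding_prots)), "==")
  rhs <- c(rep(0, length(mets)), rep(0, length(folding_prots)),
           (1 - model$params$unmodeled_protein_fraction) * mu *
             model$params$total_proteome_mass)

  lb <- numeric(nc); ub <- numeric(nc)
  s_nm <- model$ros$basal_superoxide_nm * condition$ros_mult
  lipid <- if (any(vapply(rxns, function(r) isTRUE(r$lipid_pseudo), TRUE)))
    membrane_lipid_composition(model, condition$ph) else NULL

  for (j in seq_len(nc)) {
    r <- rxns[[cols$rxn[j]]]
    st <- r$stoich
    if (length(r$stoich_mu)) {
      add <- mu * r$stoich_mu
      for (mname in names(add)) st[mname] <- sum(st[mname], add[mname],
                                                 na.rm = TRUE)
    }
    if (isTRUE(r$lipid_pseudo)) {
      st["fa_sat_c"] <- -lipid[["sat"]]
      st["fa_unsat_c"] <- -lipid[["unsat"]]
    }

    cat_id <- cols$catalyst[j]
    if (!is.na(cat_id)) {
      if (r$kind == "folding" || !is.na(r$pathway)) {
        p <- protein_spec(model, r$target)
        keff_h <- folding_keff(model, protein_spec(model, r$target),
                               r$pathway, condition) * 3600
        carrier <- if (r$pathway == "spontaneous")
          paste0("unfolded_", r$target) else paste0("protein_", cat_id)
        st[carrier] <- sum(st[carrier], -mu / keff_h, na.rm = TRUE)
      } else {
        keff_h <- effective_keff(model, r, cat_id, condition) * 3600
        sp <- paste0("protein_", cat_id)
        st[sp] <- sum(st[sp], -mu / keff_h, na.rm = TRUE)
        ## ROS damage: forced consumption of the native catalyst per unit
        ## flux, first-order in the effective superoxide level
        dr <- model$damage_rules[model$damage_rules$target == cat_id, ,
                                 drop = FALSE]
        if (nrow(dr) && s_nm > 0) {
          for (k in seq_len(nrow(dr))) {
            dcoef <- dr$rate_per_nm_h[k] * s_nm / keff_h
            st[sp] <- st[sp] - dcoef
            byp <- switch(dr$mechanism[k],
                          demetallation = paste0("apo_", cat_id),
                          fe_s_oxidation = paste0("damaged_", cat_id),
                          NA_character_)
            if (!is.na(byp)) st[byp] <- sum(st[byp], dcoef, na.rm = TRUE)
            ## cluster oxidation sheds more iron than repair re-inserts
            fe_rel <- if (dr$mechanism[k] == "fe_s_oxidation") 2 else 1
            st["fe2_c"] <- sum(st["fe2_c"], fe_rel * dcoef, na.rm = TRUE)
          }
        }
      }
    }

    miss <- setdiff(names(st), mets)
    if (length(miss)) stop("reaction ", r$id, " references undeclared ",
                           "metabolites: ", paste(miss, collapse = ", "))
    mat[names(st), j] <- mat[names(st), j] + unname(st)

    ## bounds
    if (!is.na(r$flux_fixed_mu)) {
      lb[j] <- ub[j] <- r$flux_fixed_mu * mu
    } else if (isTRUE(r$unmodeled)) {
      lb[j] <- ub[j] <- model$params$unmodeled_protein_fraction *
        model$params$total_proteome_mass * mu
    } else if (isTRUE(r$ros_forced)) {
      lb[j] <- ub[j] <- model$ros$h2o2_influx_per_nm *
        model$ros$basal_h2o2_nm * condition$ros_mult
    } else {
      lb[j] <- r$lb; ub[j] <- r$ub
    }
    ## HdeB-protected folding only operates under acid stress
    if (!is.na(r$pathway) && r$pathway == "hdeB" &&
        condition$ph >= model$acid$hdeb_gate_ph) {
      lb[j] <- ub[j] <- 0
    }
  }

  ## amino-acid supplementation presets open uptake exchanges
  open <- switch(condition$aa_supplement,
                 none = character(),
                 full = names(model$params$aa_exchange),
                 minus_ile_val = setdiff(names(model$params$aa_exchange),
                                         "ilv"),
                 minus_met_cys = setdiff(names(model$params$aa_exchange),
                                         "metcys"),
                 minus_phe_trp_tyr = setdiff(names(model$params$aa_exchange),
                                             "aro"))
  for (g in open) {
    j <- which(cols$col == model$params$aa_exchange[[g]])
    if (length(j)) lb[j] <- -model$params$aa_uptake_cap
  }

  ## folding partition rows: productive folding (including the unfolded pool
  ## held up by slow spontaneous folding, mu/kf per unit flux) cannot exceed
  ## the equilibrium folded share 1/(1+Keq) of translation
  for (pid in folding_prots) {
    p <- protein_spec(model, pid)
    keq <- species_keq(model, p, condition)
    rowname <- paste0("fold_partition_", pid)
    for (j in seq_len(nc)) {
      r <- rxns[[cols$rxn[j]]]
      if (r$kind == "folding" && identical(r$target, pid)) {
        mat[rowname, j] <- if (identical(r$pathway, "spontaneous")) {
          1 + mu / (folding_keff(model, p, "spontaneous", condition) * 3600)
        } else 1
      }
    }
    tr <- which(cols$rxn == paste0("TR_", pid))
    mat[rowname, tr] <- mat[rowname, tr] - 1 / (1 + keq)
  }

  ## proteome budget row over translation columns
  tr_cols <- which(vapply(cols$rxn, function(rid)
    rxns[[rid]]$kind == "translation", TRUE))
  for (j in tr_cols) {
    pid <- sub("^TR_", "", cols$rxn[j])
    mat["proteome_budget", j] <- protein_spec(model, pid)$mw_kda
  }

  list(mat = mat, dir = dir, rhs = rhs, lb = lb, ub = ub, cols = cols,
       row_ids = row_ids, met_rows = seq_along(mets), mu = mu,
       condition = condition)
}

## waste-minimizing phase-2 objective: prefer need-based proteomes among the
## (typically degenerate) optima
waste_objective <- function(model, lp) {
  obj <- numeric(nrow(lp$cols))
  sink <- vapply(lp$cols$rxn, function(rid)
    model$reactions[[rid]]$kind == "sink" &&
      !isTRUE(model$reactions[[rid]]$unmodeled), TRUE)
  obj[sink] <- 1
  obj
}

solution_from_lp <- function(model, lp, x, mu) {
  flux_col <- stats::setNames(x, lp$cols$col)
  flux <- tapply(x, lp$cols$rxn, sum)
  flux <- stats::setNames(as.numeric(flux), names(flux))
  resid <- as.vector(lp$mat[lp$met_rows, , drop = FALSE] %*% x)
  names(resid) <- lp$row_ids[lp$met_rows]
  tr <- grep("^TR_", names(flux_col), value = TRUE)
  translation <- stats::setNames(flux_col[tr], sub("^TR_", "", tr))
  ## translation columns are never catalyst-expanded, so names are clean
  names(translation) <- sub("^TR_", "", tr)
  structure(list(mu = mu, flux = flux, flux_by_column = flux_col,
                 translation = translation, status = "optimal",
                 mass_balance_residuals = resid, condition = lp$condition,
                 keff_label = model$active_keff),
            class = "me_solution")
}

infeasible_solution <- function(condition, keff_label) {
  structure(list(mu = NA_real_, flux = NULL, flux_by_column = NULL,
                 translation = NULL, status = "infeasible",
                 mass_balance_residuals = NULL, condition = condition,
                 keff_label = keff_label),
            class = "me_solution")
}

#' Maximize growth rate by bisection over coupled LPs
#'
#' Growth rate enters the LP coefficients nonlinearly (every coupling term is
#' mu-proportional), so the maximal growth rate is located by bisection on
#' LP feasibility: feasibility is monotone in mu on these models, the LP at
#' fixed mu is linear, and the supremum feasible mu is bracketed to
#' \code{tol}. The returned flux vector comes from the final feasible LP,
#' re-solved with a waste-minimizing objective so that the reported proteome
#' reflects catalytic need.
#'
#' @param model an \code{me_model}.
#' @param condition a \code{stress_condition}.
#' @param tol bisection tolerance on mu (h^-1).
#' @param mu_max upper end of the search bracket (h^-1).
#' @return an \code{me_solution}; status "infeasible" (with mu NA) if the
#'   model is infeasible even at mu = 0.
#' @export
maximize_growth <- function(model, condition = stress_condition(),
                            tol = 1e-6, mu_max = model$params$mu_max_scan) {
  feasible_at <- function(mu) {
    lp <- assemble_lp(model, mu, condition)
    s <- solve_lp(numeric(nrow(lp$cols)), lp$mat, lp$dir, lp$rhs, lp$lb,
                  lp$ub, feasibility_only = TRUE)
    s$status == "optimal"
  }
  if (!feasible_at(0)) return(infeasible_solution(condition,
                                                  model$active_keff))
  lo <- 0; hi <- mu_max
  if (feasible_at(hi)) {
    lo <- hi
  } else {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (feasible_at(mid)) lo <- mid else hi <- mid
    }
  }
  lp <- assemble_lp(model, lo, condition)
  s <- solve_lp(waste_objective(model, lp), lp$mat, lp$dir, lp$rhs, lp$lb,
                lp$ub)
  if (s$status != "optimal") {
    ## knife-edge mu: fall back to the plain feasible point
    s <- solve_lp(numeric(nrow(lp$cols)), lp$mat, lp$dir, lp$rhs, lp$lb,
                  lp$ub, feasibility_only = TRUE)
  }
  solution_from_lp(model, lp, s$x, lo)
}

#' Optimize a reaction flux at fixed growth rate
#'
#' Fixes mu, assembles the LP and minimizes or maximizes the flux through one
#' reaction (summed over its catalyst alternatives). This is the FVA
#' workhorse.
#'
#' @param model an \code{me_model}.
#' @param condition a \code{stress_condition}.
#' @param mu growth rate to fix (h^-1).
#' @param objective reaction id to optimize.
#' @param sense "max" or "min".
#' @return an \code{me_solution} with an extra \code{objective_value}
#'   element; status "infeasible" if mu is not attainable.
#' @export
fix_growth_and_optimize <- function(model, condition = stress_condition(),
                                    mu, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  lp <- assemble_lp(model, mu, condition)
  if (!objective %in% lp$cols$rxn) stop("unknown objective reaction: ",
                                        objective)
  obj <- as.numeric(lp$cols$rxn == objective)
  s <- solve_lp(obj, lp$mat, lp$dir, lp$rhs, lp$lb, lp$ub,
                maximize = (sense == "max"))
  if (s$status != "optimal") {
    out <- infeasible_solution(condition, model$active_keff)
    out$objective_value <- NA_real_
    return(out)
  }
  out <- solution_from_lp(model, lp, s$x, mu)
  out$objective_value <- s$objval
  out
}

#' Knock out a gene
#'
#' Turns off mRNA translation and protein synthesis for the gene's protein by
#' bounding its translation flux to zero. Returns a modified copy; the input
#' model is untouched.
#'
#' @param model an \code{me_model}.
#' @param gene gene name as registered in the protein table.
#' @return the modified model.
#' @export
knockout_gene <- function(model, gene) {
  hit <- model$proteins$id[model$proteins$gene == gene]
  if (!length(hit)) stop("unknown gene: ", gene)
  for (pid in hit) {
    tr <- paste0("TR_", pid)
    if (!tr %in% names(model$reactions))
      stop("protein ", pid, " has no translation reaction")
    model$reactions[[tr]]$lb <- 0
    model$reactions[[tr]]$ub <- 0
  }
  model
}

#' Enumerate the enzyme-coupling constraints of a model
#'
#' One row per (reaction, catalyst alternative) pair under the active keff
#' vector. The coupling direction is synthesis >= (mu/keff) * v, enforced in
#' the LP through the catalyst's species balance plus its free excess sink.
#'
#' @param model an \code{me_model}.
#' @return data.frame with reaction, enzyme, keff (s^-1), direction.
#' @export
coupling_constraints <- function(model) {
  keffs <- model$keff_vectors[[model$active_keff]]
  rows <- lapply(model$reactions, function(r) {
    if (!length(r$catalysts) || r$kind == "folding" || !is.na(r$pathway))
      return(NULL)
    data.frame(reaction = r$id, enzyme = r$catalysts,
               keff = unname(keffs[r$id]),
               direction = "synthesis >= (mu/keff)*v",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structural quality checks on an ME model
#'
#' Verifies unique ids, declared metabolites, bound sanity, keff coverage of
#' every catalyzed reaction in every registered vector, finiteness of
#' mu-dependent coefficients over the scan range, and structural
#' producibility/consumability of every non-exchange metabolite.
#'
#' @param model an \code{me_model}.
#' @return invisibly TRUE; stops with a message on the first violation.
#' @export
check_model <- function(model) {
  stopifnot(!anyDuplicated(model$metabolites$id),
            !anyDuplicated(names(model$reactions)),
            !anyDuplicated(model$proteins$id))
  mets <- model$metabolites$id
  prod <- cons <- stats::setNames(logical(length(mets)), mets)
  for (r in model$reactions) {
    if (r$lb > r$ub) stop("bounds violated in ", r$id)
    st <- r$stoich
    bad <- setdiff(unique(c(names(st), names(r$stoich_mu))), mets)
    if (length(bad)) stop("undeclared metabolites in ", r$id, ": ",
                          paste(bad, collapse = ", "))
    for (mu in c(0, model$params$mu_max_scan)) {
      co <- st
      if (length(r$stoich_mu))
        for (mn in names(r$stoich_mu))
          co[mn] <- sum(co[mn], mu * r$stoich_mu[mn], na.rm = TRUE)
      if (any(!is.finite(co))) stop("non-finite coefficient in ", r$id)
    }
    if (length(r$catalysts) && r$kind != "folding" && is.na(r$pathway)) {
      for (lab in names(model$keff_vectors)) {
        if (is.na(model$keff_vectors[[lab]][r$id]))
          stop("keff vector '", lab, "' misses catalyzed reaction ", r$id)
      }
    }
    neg <- names(st)[st < 0]; pos <- names(st)[st > 0]
    cons[neg] <- TRUE; prod[pos] <- TRUE
    if (r$kind == "exchange") {
      ## reversible exchanges open both directions for their metabolite
      cons[names(st)] <- cons[names(st)] | r$ub > 0
      prod[names(st)] <- prod[names(st)] | r$lb < 0
    }
    ## mu-dependent usage terms consume catalysts
    if (length(r$catalysts)) cons[paste0("protein_", r$catalysts)] <- TRUE
    ## the membrane pseudo-reaction consumes fatty acids at assembly time
    if (isTRUE(r$lipid_pseudo))
      cons[c("fa_sat_c", "fa_unsat_c")] <- TRUE
  }
  ## damage byproducts are produced by assembly-time ROS terms
  if (nrow(model$damage_rules)) {
    byp <- c(paste0("apo_", model$damage_rules$target),
             paste0("damaged_", model$damage_rules$target), "fe2_c")
    prod[intersect(byp, mets)] <- TRUE
  }
  orphan <- mets[!(prod & cons)]
  if (length(orphan)) stop("metabolites not both producible and consumable: ",
                           paste(orphan, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.me_model <- function(x, ...) {
  cat("ME model:", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions,", nrow(x$proteins), "proteins\n")
  cat("  keff vectors:", paste(names(x$keff_vectors), collapse = ", "),
      "(active:", x$active_keff, ")\n")
  cat("  unmodeled protein fraction:",
      x$params$unmodeled_protein_fraction, "\n")
  invisible(x)
}

#' @export
print.me_solution <- function(x, ...) {
  if (x$status == "optimal") {
    cat(sprintf("ME solution: mu* = %.6f 1/h (%s, %g C, pH %g, ROS %gx)\n",
                x$mu, x$keff_label, x$condition$temp_c, x$condition$ph,
                x$condition$ros_mult))
  } else {
    cat("ME solution: infeasible\n")
  }
  invisible(x)
}
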