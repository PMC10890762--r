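## Thermal stress: temperature-dependent protein stability and the
## cytoplasmic folding network (spontaneous, DnaK-assisted, GroEL/ES-mediated)
## plus Lon degradation of misfolded protein.

#' Gibbs free energy of unfolding at temperature T
#'
#' Gibbs-Helmholtz parameterization around the melting temperature Tm:
#' \deqn{\Delta G(T) = \Delta H_m (1 - T/T_m) - C_p ((T_m - T) + T \ln(T/T_m))}
#' Positive values mean the native state is favored; the value is zero at Tm
#' by construction.
#'
#' @param protein a protein spec (one row of the protein table, as a list)
#'   with fields \code{dHm_kj_mol}, \code{cp_kj_mol_k}, \code{tm_k}.
#' @param t_k temperature in Kelvin. Values outside the 293-323 K validity
#'   window trigger a warning but the closed form is still evaluated.
#' @return free energy of unfolding in kJ/mol.
#' @export
delta_g_unfold <- function(protein, t_k) {
  if (t_k < 293 || t_k > 323)
    warning("temperature ", t_k, " K outside the 293-323 K validity window")
  dh <- protein$dHm_kj_mol; cp <- protein$cp_kj_mol_k; tm <- protein$tm_k
  dh * (1 - t_k / tm) - cp * ((tm - t_k) + t_k * log(t_k / tm))
}

#' Equilibrium constant of unfolding (Native = Unfolded)
#'
#' \eqn{K_{eq}(T) = \exp(-\Delta G(T) / (R T))}. Equals 1 at the melting
#' temperature and increases with temperature for marginally stable proteins.
#'
#' @inheritParams delta_g_unfold
#' @return dimensionless equilibrium constant.
#' @export
unfolding_keq <- function(protein, t_k) {
  exp(-delta_g_unfold(protein, t_k) / (R_GAS * t_k))
}

#' Route a protein through the folding network
#'
#' Re-targets the protein's translation to the unfolded species and adds the
#' competing folding routes that convert unfolded to native protein:
#' spontaneous folding (self-coupled: sustaining a folding flux requires an
#' unfolded pool proportional to mu/kf, paid as extra translation), the
#' DnaK-assisted route and the GroEL/ES-mediated route (each coupled to its
#' chaperone's synthesis and consuming ATP per folding event). Cytoplasmic
#' proteins get all three routes; periplasmic proteins only fold
#' spontaneously (see \code{\link{add_hdeb_protection}} for the acid-stress
#' route). A free sink for the unfolded species carries the equilibrium
#' unfolded share; at assembly time a partition row limits total folding flux
#' to 1/(1+Keq(T)) of translation, so destabilized proteins must be
#' translated in excess of need. Temperature enters at LP assembly, not here.
#'
#' @param model an \code{me_model}; DnaK and GroEL proteins (ids "dnaK",
#'   "groL") must already be registered for cytoplasmic clients.
#' @param protein_id protein to route through the network.
#' @return the modified model.
#' @export
build_folding_network <- function(model, protein_id) {
  p <- protein_spec(model, protein_id)
  i <- match(protein_id, model$proteins$id)
  if (model$proteins$folding[i]) stop(protein_id,
                                      " already in the folding network")
  tr <- paste0("TR_", protein_id)
  if (!tr %in% names(model$reactions))
    stop("no translation reaction for ", protein_id)
  unf <- paste0("unfolded_", protein_id)
  nat <- paste0("protein_", protein_id)
  model <- add_metabolite(model, unf, p$compartment, is_macromolecule = TRUE)
  ## translation now emits the unfolded chain
  st <- model$reactions[[tr]]$stoich
  st <- st[names(st) != nat]
  st[unf] <- 1
  model$reactions[[tr]]$stoich <- st

  fold_st <- stats::setNames(c(-1, 1), c(unf, nat))
  fp <- model$params$folding
  model <- add_reaction(model, paste0("FOLD_spont_", protein_id), "folding",
                        stoich = fold_st, catalysts = protein_id,
                        pathway = "spontaneous", target = protein_id)
  if (p$compartment == "cytoplasm") {
    for (chap in c("dnaK", "groL")) {
      if (!chap %in% model$proteins$id)
        stop("chaperone ", chap, " not registered; add it before building ",
             "the folding network")
    }
    st_d <- c(fold_st, atp_c = -fp$atp_dnak)
    st_g <- c(fold_st, atp_c = -fp$atp_groel)
    model <- add_reaction(model, paste0("FOLD_dnaK_", protein_id), "folding",
                          stoich = st_d, catalysts = "dnaK",
                          pathway = "dnaK", target = protein_id)
    model <- add_reaction(model, paste0("FOLD_groEL_", protein_id), "folding",
                          stoich = st_g, catalysts = "groL",
                          pathway = "groEL", target = protein_id)
  }
  model <- add_reaction(model, paste0("SINK_unfolded_", protein_id), "sink",
                        stoich = stats::setNames(-1, unf))
  model$proteins$folding[i] <- TRUE
  model
}

#' Add Lon-mediated degradation of misfolded protein
#'
#' Unfolded protein is proteolyzed by the ATP-dependent Lon protease and its
#' amino acids recycled: an alternative to simply diluting the unfolded
#' share away, worthwhile when amino-acid synthesis is expensive. Coupled to
#' Lon synthesis like any catalyzed process.
#'
#' @param model an \code{me_model}; the protein must already be in the
#'   folding network and a protein with id "lon" must be registered.
#' @param protein_id protein whose unfolded species gains the route.
#' @return the modified model.
#' @export
lon_degradation <- function(model, protein_id) {
  p <- protein_spec(model, protein_id)
  unf <- paste0("unfolded_", protein_id)
  if (!unf %in% model$metabolites$id)
    stop("no unfolded species for ", protein_id,
         "; build the folding network first")
  if (!"lon" %in% model$proteins$id) stop("protease lon not registered")
  n_aa <- p$mw_kda / model$params$aa_mw_kda
  frac <- model$params$aa_fractions
  st <- stats::setNames(n_aa * frac, model$params$aa_pools[names(frac)])
  st[unf] <- -1
  st["atp_c"] <- -n_aa   # ~1 ATP per residue for processive proteolysis
  add_reaction(model, paste0("LON_", protein_id), "repair", stoich = st,
               catalysts = "lon", pathway = "lon", target = protein_id)
}
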