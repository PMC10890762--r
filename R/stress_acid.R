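## Acid stress: pH-dependent periplasmic protein stability, HdeB chaperone
## protection, membrane lipid composition shift, membrane-enzyme activity
## scaling. Acid stress acts only through these three channels; proton
## balance and cytoplasmic pH homeostasis are out of scope.

#' Unfolding equilibrium constant of a periplasmic protein under acid stress
#'
#' Periplasmic proteins are exposed to external pH: their unfolding free
#' energy is reduced additively by \code{slope * max(0, 7 - pH)} before the
#' Boltzmann conversion, so acidity destabilizes monotonically below pH 7 and
#' has no effect at or above it.
#'
#' @param protein a periplasmic protein spec (list with stability fields).
#' @param t_k temperature in Kelvin.
#' @param ph extracellular pH in [4.5, 7.5].
#' @param slope_kj_per_ph destabilization slope, kJ/mol per pH unit below 7.
#' @return dimensionless equilibrium constant.
#' @export
periplasmic_unfolding_keq <- function(protein, t_k, ph, slope_kj_per_ph = 6) {
  if (!identical(protein$compartment, "periplasm"))
    stop("periplasmic_unfolding_keq applies to periplasmic proteins only")
  if (ph < 4.5 || ph > 7.5)
    warning("pH ", ph, " outside the 4.5-7.5 validity window")
  dg <- delta_g_unfold(protein, t_k) - slope_kj_per_ph * max(0, 7 - ph)
  exp(-dg / (R_GAS * t_k))
}

#' Add HdeB protection of an unfolded periplasmic protein
#'
#' Adds a folding route in which the periplasmic chaperone HdeB holds the
#' unfolded client competent for spontaneous refolding. The route is coupled
#' to HdeB synthesis and only operates below the activation pH (gate in the
#' model's acid block, default 6.0); above it the LP column is closed.
#'
#' @param model an \code{me_model}; the client must be periplasmic and
#'   already in the folding network, and a protein "hdeB" registered.
#' @param protein_id periplasmic client protein.
#' @return the modified model.
#' @export
add_hdeb_protection <- function(model, protein_id) {
  p <- protein_spec(model, protein_id)
  if (p$compartment != "periplasm")
    stop("HdeB protects periplasmic proteins only")
  unf <- paste0("unfolded_", protein_id)
  if (!unf %in% model$metabolites$id)
    stop("build the folding network for ", protein_id, " first")
  if (!"hdeB" %in% model$proteins$id) stop("chaperone hdeB not registered")
  st <- stats::setNames(c(-1, 1), c(unf, paste0("protein_", protein_id)))
  add_reaction(model, paste0("FOLD_hdeB_", protein_id), "folding",
               stoich = st, catalysts = "hdeB", pathway = "hdeB",
               target = protein_id)
}

#' Membrane lipid composition at a given pH
#'
#' Linear interpolation of the tabulated fatty-acid stoichiometry of the
#' membrane pseudo-reaction; the unsaturated fraction is non-decreasing as pH
#' drops. pH outside the table hull is clamped with a warning. The total
#' lipid mass is the same in every row, so acidification changes composition,
#' not amount.
#'
#' @param model an \code{me_model} (uses \code{model$acid$lipid_table}).
#' @param ph extracellular pH.
#' @return named numeric with components \code{sat} and \code{unsat}.
#' @export
membrane_lipid_composition <- function(model, ph) {
  tab <- model$acid$lipid_table
  if (ph < min(tab$ph) || ph > max(tab$ph)) {
    warning("pH ", ph, " outside the lipid table hull; clamping")
    ph <- min(max(ph, min(tab$ph)), max(tab$ph))
  }
  c(sat = stats::approx(tab$ph, tab$sat, xout = ph)$y,
    unsat = stats::approx(tab$ph, tab$unsat, xout = ph)$y)
}

#' Membrane enzyme activity factor at a given pH
#'
#' Multiplies the keff of membrane-located enzymes; 1 at pH 7 and
#' monotonically smaller under acidification (tabulated, linearly
#' interpolated). Through the coupling v_synthesis = mu*v/keff, halving the
#' factor doubles the enzyme demand at fixed flux.
#'
#' @param model an \code{me_model} (uses \code{model$acid$activity_table}).
#' @param ph extracellular pH.
#' @return factor in (0, 1].
#' @export
membrane_activity_factor <- function(model, ph) {
  tab <- model$acid$activity_table
  ph <- min(max(ph, min(tab$ph)), max(tab$ph))
  stats::approx(tab$ph, tab$factor, xout = ph)$y
}
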