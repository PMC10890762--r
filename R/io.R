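## Serialization: model JSON (sections metabolites / reactions / proteins /
## coupling / parameters, with mu-dependent stoichiometric coefficients
## encoded as {"const": c, "mu_coeff": m}), protein tables as TSV.

#' Write an ME model to JSON
#'
#' The schema has five sections: \code{metabolites}, \code{reactions}
#' (stoichiometry as metabolite -> \{const, mu_coeff\}), \code{proteins},
#' \code{coupling} (keff vectors, active label, penalties, damage rules) and
#' \code{parameters} (global, acid and ROS blocks). Reading the file back
#' reproduces the model exactly.
#'
#' @param model an \code{me_model}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_me_model <- function(model, path) {
  rxns <- lapply(model$reactions, function(r) {
    mets <- union(names(r$stoich), names(r$stoich_mu))
    stoich <- lapply(stats::setNames(mets, mets), function(m) {
      list(const = if (m %in% names(r$stoich)) unname(r$stoich[m]) else 0,
           mu_coeff = if (m %in% names(r$stoich_mu))
             unname(r$stoich_mu[m]) else 0)
    })
    list(id = r$id, kind = r$kind, stoichiometry = stoich,
         lower_bound = r$lb, upper_bound = r$ub, catalysts = r$catalysts,
         flux_fixed_mu = r$flux_fixed_mu, pathway = r$pathway,
         target = r$target, ros_forced = r$ros_forced,
         lipid_pseudo = r$lipid_pseudo, unmodeled = r$unmodeled)
  })
  doc <- list(
    metabolites = model$metabolites,
    reactions = unname(rxns),
    proteins = model$proteins,
    coupling = list(keff_vectors = lapply(model$keff_vectors, as.list),
                    active_keff = model$active_keff,
                    keff_penalty = model$keff_penalty,
                    damage_rules = model$damage_rules),
    parameters = list(params = model$params, acid = model$acid,
                      ros = model$ros))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an ME model from JSON
#' @param path file written by \code{\link{write_me_model}}.
#' @return an \code{me_model}.
#' @export
read_me_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  s1 <- function(x, d = NA) if (is.null(x)) d else x
  rows2df <- function(rows) {
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)))
  }
  model <- me_model()
  model$metabolites <- rows2df(doc$metabolites)
  model$reactions <- stats::setNames(lapply(doc$reactions, function(r) {
    cs <- vapply(r$stoichiometry, function(s) as.numeric(s1(s$const, 0)), 0)
    ms <- vapply(r$stoichiometry, function(s) as.numeric(s1(s$mu_coeff, 0)),
                 0)
    list(id = r$id, kind = r$kind, stoich = cs[cs != 0],
         stoich_mu = ms[ms != 0], lb = r$lower_bound, ub = r$upper_bound,
         catalysts = as.character(unlist(r$catalysts)),
         flux_fixed_mu = as.numeric(s1(r$flux_fixed_mu)),
         pathway = as.character(s1(r$pathway)),
         target = as.character(s1(r$target)),
         ros_forced = isTRUE(r$ros_forced),
         lipid_pseudo = isTRUE(r$lipid_pseudo),
         unmodeled = isTRUE(r$unmodeled))
  }), vapply(doc$reactions, `[[`, "", "id"))
  model$proteins <- rows2df(doc$proteins)
  model$proteins$fe_s <- as.integer(model$proteins$fe_s)
  model$keff_vectors <- lapply(doc$coupling$keff_vectors, unlist)
  model$active_keff <- doc$coupling$active_keff
  model$keff_penalty <- lapply(doc$coupling$keff_penalty, as.numeric)
  dr <- doc$coupling$damage_rules
  model$damage_rules <- if (length(dr)) {
    df <- rows2df(dr)
    df$target <- as.character(df$target)
    df
  } else empty_damage_table()
  pars <- doc$parameters$params
  for (nm in c("unmodeled_protein_fraction", "total_proteome_mass",
               "aa_mw_kda", "atp_per_aa", "keff_ea_kj", "t_ref_k",
               "mu_max_scan", "aa_uptake_cap"))
    pars[[nm]] <- as.numeric(pars[[nm]])
  for (nm in c("aa_exchange", "aa_fractions", "aa_pools"))
    pars[[nm]] <- unlist(pars[[nm]])
  pars$aa_fractions <- vapply(pars$aa_fractions, as.numeric,
                              0)[names(pars$aa_fractions)]
  pars$folding <- lapply(pars$folding, as.numeric)
  model$params <- pars
  acid <- doc$parameters$acid
  model$acid <- list(slope_kj_per_ph = as.numeric(acid$slope_kj_per_ph),
                     hdeb_gate_ph = as.numeric(acid$hdeb_gate_ph),
                     lipid_table = rows2df(acid$lipid_table),
                     activity_table = rows2df(acid$activity_table))
  model$ros <- lapply(doc$parameters$ros, as.numeric)
  model
}

#' Write the protein table to TSV
#' @param model an \code{me_model}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_protein_table <- function(model, path) {
  tab <- model$proteins
  names(tab) <- c("id", "gene", "mw_kda", "compartment", "dHm_kj_mol",
                  "cp_kj_mol_k", "tm_k", "kf_ref", "agg", "metal", "fe_s",
                  "category", "folding")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein table from TSV
#' @param path TSV with the columns written by
#'   \code{\link{write_protein_table}}.
#' @return data.frame of protein specifications.
#' @export
read_protein_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
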