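## Post-solve analytics: flux variability analysis, proteome mass fractions
## and category aggregation, mass-balance QC, and condition-grid execution
## with CSV emission.

#' Flux variability analysis
#'
#' For each growth fraction f, growth is fixed at f times the maximal rate
#' and each target reaction is minimized and maximized. Exchange fluxes
#' follow the secretion-positive convention, so uptake appears negative.
#' Ranges at a higher growth fraction nest inside those at a lower one.
#'
#' @param model an \code{me_model}.
#' @param condition a \code{stress_condition}.
#' @param fractions growth fractions in (0, 1]; default the interval
#'   endpoints 0.95 and 1.
#' @param targets reaction ids to range (typically exchanges).
#' @param solution optional precomputed \code{maximize_growth} solution.
#' @param tol bisection tolerance when mu* must be computed here.
#' @return data.frame with reaction, fraction, min, max, status.
#' @export
fva <- function(model, condition = stress_condition(),
                fractions = c(0.95, 1), targets, solution = NULL,
                tol = 1e-6) {
  stopifnot(all(fractions > 0), all(fractions <= 1), length(targets) > 0)
  if (is.null(solution)) solution <- maximize_growth(model, condition,
                                                     tol = tol)
  if (solution$status != "optimal")
    stop("model infeasible; no growth optimum for FVA")
  rows <- list()
  for (f in fractions) {
    ## mu* is known to the bisection tolerance; fixing growth a few
    ## tolerances below keeps the fixed-growth LP off the knife edge of
    ## feasibility
    mu_f <- min(f * solution$mu, solution$mu - 10 * tol)
    for (tg in targets) {
      lo <- fix_growth_and_optimize(model, condition, mu_f, tg, "min")
      hi <- fix_growth_and_optimize(model, condition, mu_f, tg, "max")
      ok <- lo$status == "optimal" && hi$status == "optimal"
      rows[[length(rows) + 1]] <- data.frame(
        reaction = tg, fraction = f,
        min = if (ok) lo$objective_value else NA_real_,
        max = if (ok) hi$objective_value else NA_real_,
        status = if (ok) "optimal" else "infeasible",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proteome mass fractions of a solution
#'
#' The mass of protein i synthesized per gram dry weight is
#' \code{mw_i * v_translation_i / mu}; its mass fraction is that mass
#' normalized by the summed mass over all modeled proteins. The
#' modeled_protein_fraction is the summed mass relative to the total proteome
#' mass parameter and should sit at 1 minus the unmodeled protein fraction.
#'
#' @param model an \code{me_model}.
#' @param solution an optimal \code{me_solution}.
#' @return object of class \code{proteome_report}: list with a per-protein
#'   data.frame (\code{proteins}), \code{modeled_protein_fraction},
#'   \code{mu}, and \code{flag} ("ok" or "zero_growth").
#' @export
proteome_mass_fractions <- function(model, solution) {
  if (solution$status != "optimal") stop("solution is not optimal")
  if (solution$mu <= 0) {
    return(structure(list(proteins = data.frame(), mu = solution$mu,
                          modeled_protein_fraction = NA_real_,
                          flag = "zero_growth"),
                     class = "proteome_report"))
  }
  pt <- model$proteins
  v_tr <- solution$translation[pt$id]
  v_tr[is.na(v_tr)] <- 0
  mass <- pt$mw_kda * as.numeric(v_tr) / solution$mu
  total <- sum(mass)
  out <- data.frame(id = pt$id, gene = pt$gene, category = pt$category,
                    mass_g_per_gdw = mass,
                    mass_fraction = if (total > 0) mass / total else 0,
                    stringsAsFactors = FALSE)
  structure(list(proteins = out, mu = solution$mu,
                 modeled_protein_fraction =
                   total / model$params$total_proteome_mass,
                 flag = "ok"),
            class = "proteome_report")
}

#' @export
print.proteome_report <- function(x, ...) {
  cat(sprintf("Proteome report: %d proteins, modeled fraction %.4f\n",
              nrow(x$proteins), x$modeled_protein_fraction))
  invisible(x)
}

#' Aggregate proteome mass fractions by functional category
#'
#' @param report a \code{proteome_report}.
#' @param annotation optional named character protein id -> category,
#'   overriding the model's categories; proteins missing from it are counted
#'   under "unknown" with a warning.
#' @return named numeric category mass fractions summing to 1 over the
#'   modeled proteome.
#' @export
category_aggregate <- function(report, annotation = NULL) {
  df <- report$proteins
  cats <- df$category
  if (!is.null(annotation)) {
    cats <- unname(annotation[df$id])
    if (anyNA(cats)) {
      warning("unannotated proteins assigned category 'unknown': ",
              paste(df$id[is.na(cats)], collapse = ", "))
      cats[is.na(cats)] <- "unknown"
    }
  }
  tot <- tapply(df$mass_fraction, cats, sum)
  stats::setNames(as.numeric(tot), names(tot))
}

#' Per-metabolite mass-balance residuals of a solution
#'
#' At an optimal solution every non-exchange metabolite must balance exactly:
#' the report PASSes iff the largest absolute net flux is at most the
#' tolerance (default 1e-6 mmol/gDW/h).
#'
#' @param model an \code{me_model} (unused except for interface symmetry).
#' @param solution an optimal \code{me_solution}.
#' @param tolerance PASS threshold on |residual|.
#' @return data.frame (metabolite, residual) with attributes \code{pass} and
#'   \code{max_residual}.
#' @export
mass_balance_report <- function(model, solution, tolerance = 1e-6) {
  if (solution$status != "optimal") stop("solution is not optimal")
  r <- solution$mass_balance_residuals
  out <- data.frame(metabolite = names(r), residual = as.numeric(r),
                    stringsAsFactors = FALSE)
  attr(out, "max_residual") <- max(abs(out$residual))
  attr(out, "pass") <- attr(out, "max_residual") <= tolerance
  out
}

#' Solve a grid of stress conditions and emit CSV reports
#'
#' Solves the Cartesian product of temperatures, pH values and ROS
#' multipliers under the active keff vector and writes three long-format CSV
#' files: \code{phenotypes.csv} (growth rate and key exchange fluxes),
#' \code{proteome.csv} (per-protein mass fractions) and \code{fluxome.csv}
#' (per-reaction fluxes). Infeasible conditions are flagged and the run
#' continues. Floats are written at 6 significant digits; reruns with the
#' same inputs reproduce identical files.
#'
#' @param model an \code{me_model}.
#' @param temps_c temperatures (degrees C).
#' @param phs pH values.
#' @param ros_mults ROS multipliers.
#' @param keff_label keff vector to activate (default: current).
#' @param out_dir output directory (created if missing); NULL skips writing.
#' @param exchanges named character of phenotype exchange columns; defaults
#'   to glucose/oxygen uptake, CO2 and acetate production.
#' @param tol bisection tolerance.
#' @return invisible list of the three data.frames.
#' @export
condition_grid <- function(model, temps_c, phs, ros_mults,
                           keff_label = model$active_keff, out_dir = NULL,
                           exchanges = c(GUR = "EX_glc", OUR = "EX_o2",
                                         CO2 = "EX_co2", APR = "EX_ac"),
                           tol = 1e-6) {
  stopifnot(length(temps_c) > 0, length(phs) > 0, length(ros_mults) > 0)
  model <- set_keff_vector(model, keff_label,
                           model$keff_vectors[[keff_label]], activate = TRUE)
  grid <- expand.grid(temp_c = temps_c, ph = phs, ros_mult = ros_mults,
                      KEEP.OUT.ATTRS = FALSE)
  phen <- list(); prot <- list(); flux <- list()
  for (i in seq_len(nrow(grid))) {
    cond <- stress_condition(grid$temp_c[i], grid$ph[i], grid$ros_mult[i])
    cid <- sprintf("T%g_pH%g_ROS%g", cond$temp_c, cond$ph, cond$ros_mult)
    sol <- maximize_growth(model, cond, tol = tol)
    base <- data.frame(condition_id = cid, temp_c = cond$temp_c,
                       ph = cond$ph, ros_mult = cond$ros_mult,
                       keff_label = keff_label, stringsAsFactors = FALSE)
    if (sol$status != "optimal") {
      phen[[i]] <- cbind(base, mu_per_h = NA_real_,
                         as.list(stats::setNames(rep(NA_real_,
                           length(exchanges)), names(exchanges))),
                         status = "infeasible")
      next
    }
    ex <- vapply(exchanges, function(rid)
      if (rid %in% names(sol$flux)) unname(sol$flux[rid]) else NA_real_, 0)
    phen[[i]] <- cbind(base, mu_per_h = sol$mu, as.list(ex),
                       status = "optimal")
    rep_i <- proteome_mass_fractions(model, sol)
    prot[[i]] <- data.frame(condition_id = cid,
                            protein_id = rep_i$proteins$id,
                            mass_fraction = rep_i$proteins$mass_fraction,
                            category = rep_i$proteins$category,
                            stringsAsFactors = FALSE)
    flux[[i]] <- data.frame(condition_id = cid,
                            reaction_id = names(sol$flux),
                            flux = as.numeric(sol$flux),
                            stringsAsFactors = FALSE)
  }
  phen <- do.call(rbind, phen)
  prot <- do.call(rbind, prot)
  flux <- do.call(rbind, flux)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    num <- vapply(phen, is.numeric, TRUE)
    phen_w <- phen; phen_w[num] <- lapply(phen_w[num], signif, digits = 6)
    prot_w <- prot; prot_w$mass_fraction <- signif(prot_w$mass_fraction, 6)
    flux_w <- flux; flux_w$flux <- signif(flux_w$flux, 6)
    utils::write.csv(phen_w, file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(prot_w, file.path(out_dir, "proteome.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(flux_w, file.path(out_dir, "fluxome.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(phenotypes = phen, proteome = prot, fluxome = flux))
}

#' Write a solution's fluxome to CSV
#' @param solution an optimal \code{me_solution}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fluxome <- function(solution, path) {
  if (solution$status != "optimal") stop("solution is not optimal")
  utils::write.csv(data.frame(reaction_id = names(solution$flux),
                              flux_mmol_gDW_h = signif(
                                as.numeric(solution$flux), 6)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
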