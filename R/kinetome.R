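## Kinetome management: keff vectors, the single-effect sensitivity screen
## between two kinetomes, consolidation with provenance, and the
## keff-sweep redundancy probe.

#' Construct a keff vector
#' @param values named numeric, reaction id -> keff (s^-1, > 0).
#' @param label vector label.
#' @param provenance optional character notes per override.
#' @return named numeric with attributes \code{label} and \code{provenance}.
#' @export
keff_vector <- function(values, label, provenance = character()) {
  if (any(values <= 0)) stop("keff values must be positive")
  structure(values, label = label, provenance = provenance)
}

#' Consolidate a kinetome by overriding selected entries
#'
#' Returns a relabeled copy of the base vector with the given reactions
#' overridden; the provenance attribute records old -> new values. Applying
#' the same overrides twice is idempotent.
#'
#' @param base named numeric keff vector (s^-1).
#' @param overrides named numeric of replacement keffs.
#' @param label label of the consolidated vector.
#' @return a \code{keff_vector}.
#' @export
consolidate <- function(base, overrides = numeric(),
                        label = "consolidated") {
  if (length(overrides)) {
    if (any(overrides <= 0)) stop("override keffs must be positive")
    missing <- setdiff(names(overrides), names(base))
    if (length(missing)) stop("overrides for unknown reactions: ",
                              paste(missing, collapse = ", "))
  }
  out <- unclass(base)
  prov <- vapply(names(overrides), function(r)
    sprintf("%s: %g -> %g", r, out[r], overrides[r]), "")
  out[names(overrides)] <- overrides
  keff_vector(out, label, provenance = unname(prov))
}

#' Single-effect keff sensitivity screen
#'
#' For every reaction whose keff differs between the base and alternative
#' kinetome, swap exactly that one keff from base to alternative, recompute
#' the maximal growth rate, and restore. Records are independent (pure
#' function of model, vectors and condition) and returned sorted by |delta|
#' descending, ties broken by reaction id.
#'
#' @param model an \code{me_model} whose catalyzed reactions are covered by
#'   both vectors.
#' @param base,alt named numeric keff vectors (s^-1).
#' @param condition a \code{stress_condition}.
#' @param tol bisection tolerance passed to \code{\link{maximize_growth}}.
#' @return data.frame with reaction_id, mu_base, mu_swapped, delta, status.
#' @export
sensitivity_screen <- function(model, base, alt,
                               condition = stress_condition(), tol = 1e-6) {
  differing <- names(base)[!is.na(alt[names(base)]) &
                             abs(alt[names(base)] - base) > 0]
  differing <- sort(differing)
  model <- set_keff_vector(model, ".screen_base", unclass(base),
                           activate = TRUE)
  sol0 <- maximize_growth(model, condition, tol = tol)
  mu_base <- if (sol0$status == "optimal") sol0$mu else NA_real_
  rows <- lapply(differing, function(rid) {
    swapped <- unclass(base)
    swapped[rid] <- alt[rid]
    m2 <- set_keff_vector(model, ".screen_swap", swapped, activate = TRUE)
    sol <- maximize_growth(m2, condition, tol = tol)
    data.frame(reaction_id = rid, mu_base = mu_base,
               mu_swapped = if (sol$status == "optimal") sol$mu else NA_real_,
               delta = if (sol$status == "optimal") sol$mu - mu_base
                       else NA_real_,
               status = sol$status, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction_id = character(), mu_base = numeric(),
               mu_swapped = numeric(), delta = numeric(),
               status = character(), stringsAsFactors = FALSE)
  out <- out[order(-abs(out$delta), out$reaction_id), ]
  rownames(out) <- NULL
  out
}

#' Keff sweep for one reaction: growth vs catalyst cost
#'
#' Sweeps the keff of a single reaction over a grid, reporting the maximal
#' growth rate and the summed mass fraction of the reaction's catalysts.
#' Growth-critical reactions show mu* rising with keff until another
#' constraint binds; redundant reactions show near-constant mu* while the
#' catalyst mass fraction swings by orders of magnitude.
#'
#' @param model an \code{me_model}.
#' @param reaction_id reaction whose keff is swept.
#' @param keff_grid positive keff values (s^-1).
#' @param condition a \code{stress_condition}.
#' @param tol bisection tolerance.
#' @return data.frame with keff, mu, catalyst_mass_fraction, status.
#' @export
redundancy_probe <- function(model, reaction_id, keff_grid,
                             condition = stress_condition(), tol = 1e-6) {
  if (any(keff_grid <= 0)) stop("keff grid must be positive")
  r <- model$reactions[[reaction_id]]
  if (is.null(r)) stop("unknown reaction: ", reaction_id)
  cats <- r$catalysts
  base <- model$keff_vectors[[model$active_keff]]
  rows <- lapply(keff_grid, function(k) {
    v <- base; v[reaction_id] <- k
    m2 <- set_keff_vector(model, ".probe", v, activate = TRUE)
    sol <- maximize_growth(m2, condition, tol = tol)
    mf <- NA_real_
    if (sol$status == "optimal" && sol$mu > 0) {
      rep <- proteome_mass_fractions(m2, sol)
      mf <- sum(rep$proteins$mass_fraction[rep$proteins$id %in% cats])
    }
    data.frame(keff = k, mu = sol$mu, catalyst_mass_fraction = mf,
               status = sol$status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a keff vector from TSV
#'
#' Two tab-separated columns \code{reaction_id} and \code{keff_per_s}; the
#' header line is required.
#'
#' @param path file path.
#' @param label label for the resulting vector (defaults to the file name).
#' @return a \code{keff_vector}.
#' @export
read_keff_tsv <- function(path, label = sub("[.]tsv$", "", basename(path))) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(tab)[1:2], c("reaction_id", "keff_per_s")))
    stop("keff TSV must have header: reaction_id<TAB>keff_per_s")
  keff_vector(stats::setNames(tab$keff_per_s, tab$reaction_id), label)
}

#' Write a keff vector to TSV
#' @param keffs named numeric keff vector.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_keff_tsv <- function(keffs, path) {
  utils::write.table(
    data.frame(reaction_id = names(keffs), keff_per_s = as.numeric(keffs)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
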