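## Shared fixtures and independent oracles. The toy model and its baseline
## solutions are cached across test files; every cache entry is a pure
## function of (seed, condition, tol), so sharing cannot leak state.

.cache <- new.env(parent = emptyenv())

toy_model <- function() {
  if (is.null(.cache$toy)) .cache$toy <- build_toy_model(seed = 7)
  .cache$toy
}

## memoized maximize_growth on the cached toy
toy_solve <- function(temp_c = 37, ph = 7, ros = 1, tol = 1e-5,
                      keff = "wild_type", aa = "none") {
  key <- paste("s", temp_c, ph, ros, tol, keff, aa, sep = "_")
  if (is.null(.cache[[key]])) {
    m <- toy_model()
    m <- set_keff_vector(m, keff, m$keff_vectors[[keff]], activate = TRUE)
    .cache[[key]] <- maximize_growth(
      m, stress_condition(temp_c, ph, ros, aa_supplement = aa), tol = tol)
  }
  .cache[[key]]
}

## A minimal growth-coupled model (<= 8 reactions) small enough for
## brute-force oracles: substrate uptake, one catalyzed transport step, one
## catalyzed conversion, biomass. Translation feeds on the internal
## substrate; the proteome budget makes growth self-limiting.
mini_model <- function(uptake = 1) {
  m <- me_model()
  m <- add_metabolite(m, "s_e", "extracellular")
  m <- add_metabolite(m, "s_c", "cytoplasm")
  m <- add_metabolite(m, "prec_c", "cytoplasm")
  m <- add_protein(m, "E1", "e1", mw_kda = 30, category = "transport")
  m <- add_protein(m, "E2", "e2", mw_kda = 40, category = "metabolism")
  m <- add_reaction(m, "TR_E1", "translation",
                    stoich = c(s_c = -10, protein_E1 = 1))
  m <- add_reaction(m, "TR_E2", "translation",
                    stoich = c(s_c = -13, protein_E2 = 1))
  m <- add_reaction(m, "EX_s", "exchange", stoich = c(s_e = -1),
                    lb = -uptake, ub = 0)
  m <- add_reaction(m, "SUP", "metabolic", stoich = c(s_e = -1, s_c = 1),
                    catalysts = "E1")
  m <- add_reaction(m, "CONV", "metabolic", stoich = c(s_c = -1, prec_c = 2),
                    catalysts = "E2")
  m <- add_reaction(m, "GROWTH", "biomass", stoich = c(prec_c = -1),
                    flux_fixed_mu = 1)
  set_keff_vector(m, "wild_type", c(SUP = 5, CONV = 2), activate = TRUE)
}

## independent oracle: supremum of feasible mu by exhaustive grid scan over
## assembled LPs (uses only assemble_lp + solve_lp feasibility, not the
## bisection logic under test)
grid_scan_mu <- function(model, condition, mu_hi, step) {
  grid <- seq(0, mu_hi, by = step)
  feas <- vapply(grid, function(mu) {
    lp <- assemble_lp(model, mu, condition)
    s <- solve_lp(numeric(nrow(lp$cols)), lp$mat, lp$dir, lp$rhs, lp$lb,
                  lp$ub, feasibility_only = TRUE)
    s$status == "optimal"
  }, TRUE)
  list(sup = max(grid[feas]), pattern = feas)
}

## independent oracle: enumerate all basic solutions of an all-equality LP
## with bounds and return the min/max of a linear objective over the
## feasible vertices
enumerate_vertices <- function(mat, rhs, lb, ub, obj, tol = 1e-7) {
  m <- nrow(mat); n <- ncol(mat)
  stopifnot(n - m <= 12)
  best_min <- Inf; best_max <- -Inf
  for (bas in utils::combn(n, m, simplify = FALSE)) {
    B <- mat[, bas, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nb <- setdiff(seq_len(n), bas)
    bound_sets <- expand.grid(rep(list(c(TRUE, FALSE)), length(nb)))
    for (r in seq_len(nrow(bound_sets))) {
      xN <- ifelse(unlist(bound_sets[r, ]), lb[nb], ub[nb])
      if (any(!is.finite(xN))) next
      xB <- solve(B, rhs - mat[, nb, drop = FALSE] %*% xN)
      if (any(xB < lb[bas] - tol) || any(xB > ub[bas] + tol)) next
      x <- numeric(n); x[bas] <- xB; x[nb] <- xN
      v <- sum(obj * x)
      best_min <- min(best_min, v); best_max <- max(best_max, v)
    }
  }
  c(min = best_min, max = best_max)
}

## TRUE if the sequence rises to a single peak and then falls (tolerance for
## solver noise)
is_unimodal <- function(x, eps = 1e-3) {
  k <- which.max(x)
  all(diff(x[seq_len(k)]) >= -eps) &&
    all(diff(x[seq(k, length(x))]) <= eps)
}
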