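#' Structural zero-flux propagation
#'
#' ME models mix O(1) stoichiometric coefficients with O(mu/k_eff)
#' coupling entries. In double precision a closed translation reaction
#' only pins the catalyzed flux to within `tol / (mu/k_eff)`, which can
#' be a macroscopic leak. Before each solve the assembler therefore
#' tightens the bound vectors by exact structural reasoning, iterated to
#' a fixpoint:
#'
#' * a species none of whose reactions can currently produce it is dead;
#' * reactions consuming a dead species cannot carry flux in that
#'   direction (the corresponding bound is closed);
#' * at `mu > 0`, a reaction whose catalyst species is dead is closed
#'   (flux requires catalyst via the usage coupling).
#'
#' The propagation is sound (it only removes flux patterns that are
#' infeasible in exact arithmetic) and is recomputed from the current
#' bounds, so reopening reactions (e.g. the naive model) automatically
#' resurrects downstream capability.
#'
#' @param cache An LP structure cache (internal).
#' @param lb,ub Current bound vectors (reaction order of the cache).
#' @param mu Growth rate of the assembly.
#' @return A list with tightened `lb`, `ub`.
#' @keywords internal
propagate_bounds <- function(cache, lb, ub, mu) {
  pi <- cache$prop$pos_i; pj <- cache$prop$pos_j
  ni <- cache$prop$neg_i; nj <- cache$prop$neg_j
  ci <- cache$prop$cat_i; cj <- cache$prop$cat_j
  ns <- cache$n_species
  use_cat <- mu > 0 && length(cj) > 0
  repeat {
    alive <- logical(ns)
    ## forward production: positive coef with ub > 0
    if (length(pj)) alive[unique(pi[ub[pj] > 0])] <- TRUE
    ## reverse production: negative coef with lb < 0
    if (length(nj)) alive[unique(ni[lb[nj] < 0])] <- TRUE
    changed <- FALSE
    if (length(nj)) {
      kill <- !alive[ni] & ub[nj] > 0
      if (any(kill)) { ub[unique(nj[kill])] <- 0; changed <- TRUE }
    }
    if (length(pj)) {
      kill <- !alive[pi] & lb[pj] < 0
      if (any(kill)) { lb[unique(pj[kill])] <- 0; changed <- TRUE }
    }
    if (use_cat) {
      kill <- !alive[ci] & (ub[cj] > 0 | lb[cj] < 0)
      if (any(kill)) {
        j <- unique(cj[kill])
        ## close both directions; a positive lb is kept so the LP reports
        ## the infeasibility (lb > ub) rather than silently masking it
        ub[j] <- pmin(ub[j], 0)
        lb[j] <- pmax(lb[j], 0)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ## a reaction with lb > 0 whose flux was forced off is an immediate
  ## infeasibility; leave it to the LP (lb > ub) rather than deciding here
  list(lb = lb, ub = ub)
}
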