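#' Independent producibility/blockage oracle
#'
#' A solver-free cross-check for the LP-based blockage test, working by
#' iterative pruning to a greatest fixpoint over reaction viability:
#'
#' * a reaction direction is viable only if every species it consumes
#'   has some viable producer, every species it produces has some
#'   viable consumer (dead-end products forbid steady-state flux), and
#'   its catalyst species, if any, is producible (catalysis is required
#'   categorically, matching the usage coupling at any mu > 0);
#' * species producibility/drainability is then recomputed and pruning
#'   repeats until stable.
#'
#' Self-sustaining internal cycles survive the fixpoint, matching LP
#' semantics where cofactor pools may circulate freely. Exchange
#' reactions with negative lower bounds act as producers of their
#' extracellular species (the medium), and any open consumer acts as a
#' drain.
#'
#' @param model An `me_model` with current bounds applied.
#' @param extra_producible Species ids treated as externally supplied
#'   (used to emulate a sink when testing protein blockage).
#' @return A list with logical vectors `producible` and `drainable`
#'   (named by species), and data frame `viable` per reaction direction.
#' @export
reaction_viability <- function(model, extra_producible = character(0)) {
  rxs <- model$reactions
  nr <- length(rxs)
  sp_ids <- model$species$id
  si <- stats::setNames(seq_along(sp_ids), sp_ids)
  inf <- model$inf_bound

  cons <- vector("list", nr); prod <- vector("list", nr)
  cat_i <- integer(nr)
  fwd_ok <- logical(nr); rev_ok <- logical(nr)
  for (j in seq_len(nr)) {
    rx <- rxs[[j]]
    sgn <- vapply(rx$stoich, function(cf) sign(eval_mu(cf, 0.1)), 0)
    idx <- si[names(rx$stoich)]
    cons[[j]] <- idx[sgn < 0]
    prod[[j]] <- idx[sgn > 0]
    cat_i[j] <- if (is.null(rx$catalyst)) 0L else si[[rx$catalyst]]
    fwd_ok[j] <- min(rx$ub, inf) > 0
    rev_ok[j] <- max(rx$lb, -inf) < 0
  }
  extra <- logical(length(sp_ids))
  extra[si[intersect(extra_producible, sp_ids)]] <- TRUE

  repeat {
    producible <- extra
    drainable <- logical(length(sp_ids))
    for (j in seq_len(nr)) {
      if (fwd_ok[j]) {
        producible[prod[[j]]] <- TRUE
        drainable[cons[[j]]] <- TRUE
      }
      if (rev_ok[j]) {
        producible[cons[[j]]] <- TRUE
        drainable[prod[[j]]] <- TRUE
      }
      if ((fwd_ok[j] || rev_ok[j]) && cat_i[j] > 0L)
        drainable[cat_i[j]] <- TRUE  # usage coupling consumes catalyst
    }
    changed <- FALSE
    for (j in seq_len(nr)) {
      cat_ok <- cat_i[j] == 0L || producible[cat_i[j]]
      if (fwd_ok[j]) {
        ok <- cat_ok && all(producible[cons[[j]]]) && all(drainable[prod[[j]]])
        if (!ok) { fwd_ok[j] <- FALSE; changed <- TRUE }
      }
      if (rev_ok[j]) {
        ok <- cat_ok && all(producible[prod[[j]]]) && all(drainable[cons[[j]]])
        if (!ok) { rev_ok[j] <- FALSE; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  names(producible) <- sp_ids; names(drainable) <- sp_ids
  list(producible = producible, drainable = drainable,
       viable = data.frame(reaction = names(rxs), fwd = fwd_ok, rev = rev_ok,
                           stringsAsFactors = FALSE))
}

#' Is a species producible at steady state?
#'
#' @param model An `me_model`.
#' @param species Species id.
#' @return Logical flag.
#' @export
producibility_oracle <- function(model, species) {
  if (!species %in% model$species$id) stop("unknown species: ", species)
  va <- reaction_viability(model)
  unname(va$producible[species])
}

#' Oracle classification of protein blockage
#'
#' Emulates the sink test structurally: the protein species is treated
#' as externally supplied, and the protein is blocked when no viable
#' reaction can consume it — neither a complex-formation reaction nor
#' any reaction it catalyzes survives the pruning fixpoint.
#'
#' @param model The depleted model (bounds already closed).
#' @param protein Protein id.
#' @param cell Cell context.
#' @return `TRUE` when blocked.
#' @export
oracle_protein_blocked <- function(model, protein,
                                   cell = c("forespore", "mother_cell",
                                            "vegetative")) {
  cell <- match.arg(cell)
  sp <- protein_species_of(protein, if (inherits(model, "two_cell_model"))
    cell else "vegetative")
  if (!sp %in% model$species$id) stop("no protein species: ", sp)
  va <- reaction_viability(model, extra_producible = sp)
  !unname(va$drainable[sp])
}
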