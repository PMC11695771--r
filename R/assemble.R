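#' Assemble the fixed-growth-rate linear program
#'
#' At a fixed growth rate `mu` every coefficient of the ME model becomes a
#' number and the steady-state constraint `S(mu) v = 0` with bounds
#' `vL <= v <= vU` is an ordinary LP. Growth coupling is realized by
#' raising the objective reaction's lower bound to `mu`: the biomass flux
#' must meet the tested growth rate, so feasibility of the LP decides
#' whether `mu` is attainable.
#'
#' Catalyst usage couplings (`-mu/k_eff` on the catalyst species) are
#' injected here. The sparse structure is computed once per model and
#' cached in an attribute, so reassembly at a new `mu` only re-evaluates
#' the mu-dependent entries.
#'
#' @param model A validated `me_model`.
#' @param mu Growth rate, h^-1 (>= 0).
#' @return A list of class `lp_instance`: sparse matrix `A` (rows =
#'   species, columns = reactions), `lb`, `ub`, `obj` (indicator of the
#'   objective column), and the row/column ids.
#' @export
assemble_lp <- function(model, mu) {
  stopifnot(mu >= 0)
  cache <- lp_structure(model)
  xs <- cache$const_x
  if (length(cache$mu_entries)) {
    vals <- vapply(cache$mu_entries, function(e) {
      v <- if (!is.null(e$k_eff)) -mu / e$k_eff else eval_mu(e$coef, mu)
      v
    }, 0)
    if (any(!is.finite(vals)))
      stop("non-finite coefficient at mu = ", mu)
    xs <- c(xs, vals)
  }
  A <- Matrix::sparseMatrix(i = c(cache$const_i, cache$mu_i),
                            j = c(cache$const_j, cache$mu_j),
                            x = xs,
                            dims = c(cache$n_species, cache$n_reactions))
  bounds <- bound_vectors(model)
  obj <- numeric(cache$n_reactions)
  obj_idx <- match(model$objective, cache$col_ids)
  if (!is.na(obj_idx)) {
    obj[obj_idx] <- 1
    bounds$lb[obj_idx] <- max(bounds$lb[obj_idx], mu)
  }
  bounds <- propagate_bounds(cache, bounds$lb, bounds$ub, mu)
  structure(list(A = A, lb = unname(bounds$lb), ub = unname(bounds$ub),
                 obj = obj, row_ids = cache$row_ids, col_ids = cache$col_ids,
                 mu = mu),
            class = "lp_instance")
}

## internal: sparse triplet structure with mu-dependent entries factored out.
## Cached on the model via an attribute keyed by a structure signature so
## bound-only modifications (depletions, media) reuse the cache.
lp_structure <- function(model) {
  cache <- attr(model, "lp_cache")
  if (!is.null(cache)) return(cache)
  row_ids <- model$species$id
  col_ids <- names(model$reactions)
  ri <- stats::setNames(seq_along(row_ids), row_ids)
  const_i <- integer(0); const_j <- integer(0); const_x <- numeric(0)
  mu_i <- integer(0); mu_j <- integer(0); mu_entries <- list()
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    for (s in names(rx$stoich)) {
      coef <- rx$stoich[[s]]
      i <- ri[[s]]
      if (is.null(i)) stop("reaction ", rx$id, " references unknown species ", s)
      if (is_constant_coef(coef)) {
        const_i <- c(const_i, i); const_j <- c(const_j, j)
        const_x <- c(const_x, coef)
      } else {
        mu_i <- c(mu_i, i); mu_j <- c(mu_j, j)
        mu_entries[[length(mu_entries) + 1L]] <- list(coef = coef, k_eff = NULL)
      }
    }
    if (!is.null(rx$catalyst)) {
      i <- ri[[rx$catalyst]]
      if (is.null(i)) stop("reaction ", rx$id, " has unknown catalyst ", rx$catalyst)
      mu_i <- c(mu_i, i); mu_j <- c(mu_j, j)
      mu_entries[[length(mu_entries) + 1L]] <- list(coef = NULL, k_eff = rx$k_eff)
    }
  }
  ## sign structure for structural zero propagation: coefficient signs
  ## (mu-dependent entries judged at a representative mu > 0) plus
  ## catalyst usage entries
  mu_sign <- vapply(seq_along(mu_entries), function(k) {
    e <- mu_entries[[k]]
    if (!is.null(e$k_eff)) -1 else sign(eval_mu(e$coef, 0.1))
  }, 0)
  is_cat <- vapply(mu_entries, function(e) !is.null(e$k_eff), TRUE)
  prop <- list(
    pos_i = c(const_i[const_x > 0], mu_i[!is_cat & mu_sign > 0]),
    pos_j = c(const_j[const_x > 0], mu_j[!is_cat & mu_sign > 0]),
    neg_i = c(const_i[const_x < 0], mu_i[!is_cat & mu_sign < 0]),
    neg_j = c(const_j[const_x < 0], mu_j[!is_cat & mu_sign < 0]),
    cat_i = mu_i[is_cat], cat_j = mu_j[is_cat])
  list(n_species = length(row_ids), n_reactions = length(col_ids),
       row_ids = row_ids, col_ids = col_ids,
       const_i = const_i, const_j = const_j, const_x = const_x,
       mu_i = mu_i, mu_j = mu_j, mu_entries = mu_entries, prop = prop)
}

#' Precompute and attach the LP structure cache
#'
#' Structure (not bounds) is invariant under depletions, media and
#' objective changes, so attaching the cache once makes repeated
#' [assemble_lp()] calls cheap across scans.
#'
#' @param model An `me_model`.
#' @return The model with the cache attribute set.
#' @export
cache_lp_structure <- function(model) {
  attr(model, "lp_cache") <- lp_structure(model)
  model
}
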