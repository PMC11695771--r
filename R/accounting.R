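#' Map a base metabolite name to its species id in a cell
#'
#' @param species Base name (e.g. `"atp"`) or full species id.
#' @param cell One of forespore, mother_cell, vegetative.
#' @return Species id string.
#' @export
species_in_cell <- function(species, cell) {
  if (grepl("_[cse]$", species)) return(species)
  paste0(species, if (cell == "forespore") "_s" else "_c")
}

#' Per-reaction production fractions of a metabolite
#'
#' For the given species and cell, every reaction's production rate is
#' `max(0, coefficient(mu) * flux)`; fractions are normalized over the
#' total. Transport and substrate-level contributions are counted
#' identically: anything with positive net stoichiometry in the cell is
#' a producer (so channel import of ATP is an ATP source like Pgk).
#'
#' @param model The model the fluxes belong to.
#' @param fluxes Named flux vector (carries a `mu` attribute when it
#'   comes from [parsimonious_solution()]).
#' @param species Base metabolite name or species id.
#' @param cell Cell context.
#' @param mu Growth rate used to evaluate coefficients (default: the
#'   `mu` attribute of `fluxes`).
#' @param tol Rates below this are treated as zero.
#' @return A data frame (reaction, rate, fraction), total production in
#'   attribute `total`; zero rows if the species is never produced.
#' @export
production_fractions <- function(model, fluxes, species,
                                 cell = c("forespore", "mother_cell",
                                          "vegetative"),
                                 mu = attr(fluxes, "mu"), tol = 1e-9) {
  cell <- match.arg(cell)
  sp <- species_in_cell(species, cell)
  if (!sp %in% model$species$id) stop("species absent in cell: ", sp)
  if (is.null(mu)) stop("mu not supplied and fluxes carry no mu attribute")
  rates <- c()
  for (rx in model$reactions) {
    coef <- rx$stoich[[sp]]
    if (is.null(coef)) next
    v <- fluxes[[rx$id]]
    if (is.null(v) || is.na(v)) next
    r <- eval_mu(coef, mu) * v
    if (r > tol) rates[rx$id] <- r
  }
  if (length(rates) == 0) {
    out <- data.frame(reaction = character(), rate = numeric(),
                      fraction = numeric(), stringsAsFactors = FALSE)
    attr(out, "total") <- 0
    return(out)
  }
  rates <- sort(rates, decreasing = TRUE)
  out <- data.frame(reaction = names(rates), rate = unname(rates),
                    fraction = unname(rates) / sum(rates),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(rates)
  out
}

#' Forespore:mother-cell protein partition ratio
#'
#' Translation flux is the model proxy for protein abundance. The
#' forespore share is `f = FS/(FS + MC)`; classes follow the
#' fluorescence-ratio bins: depleted (< 0.2), diluted (0.2-0.5),
#' enriched (> 0.5).
#'
#' @param fluxes Named flux vector for a two-cell model.
#' @param model The `two_cell_model`.
#' @param protein Protein id.
#' @return A list with `protein`, `fs`, `mc`, `f`, `class`
#'   (`NA`/"undefined" when both fluxes are zero).
#' @export
protein_partition_ratio <- function(fluxes, model, protein) {
  fs_ids <- translation_ids_of(model, protein, "forespore")
  mc_ids <- translation_ids_of(model, protein, "mother_cell")
  if (length(fs_ids) == 0 || length(mc_ids) == 0)
    stop("protein lacks translation reactions in both copies: ", protein)
  fs <- sum(fluxes[fs_ids]); mc <- sum(fluxes[mc_ids])
  if (fs <= 0 && mc <= 0)
    return(list(protein = protein, fs = 0, mc = 0, f = NA_real_,
                class = "undefined"))
  f <- fs / (fs + mc)
  cls <- if (f < 0.2) "depleted" else if (f <= 0.5) "diluted" else "enriched"
  list(protein = protein, fs = unname(fs), mc = unname(mc),
       f = unname(f), class = cls)
}

#' Net metabolite traffic through the Q-A channel
#'
#' Resolves the net rate and direction (c->s or s->c) for every channel
#' transport from the reported flux distribution; zero-rate entries are
#' omitted.
#'
#' @param model A `two_cell_model` with tagged channel reactions.
#' @param fluxes Named flux vector.
#' @param tol Rates below this are omitted.
#' @return A data frame: species, direction, rate (mmol/gDW/h).
#' @export
channel_exchange_inventory <- function(model, fluxes, tol = 1e-9) {
  ids <- model$channel_reactions
  base <- unique(sub("_rev$", "", ids))
  rows <- list()
  for (id in base) {
    sp <- sub("^QA_transport_", "", id)
    fwd <- if (id %in% names(fluxes)) fluxes[[id]] else 0
    rev <- if (paste0(id, "_rev") %in% names(fluxes))
      fluxes[[paste0(id, "_rev")]] else 0
    net <- fwd - rev
    if (abs(net) <= tol) next
    rows[[id]] <- data.frame(
      species = sp,
      direction = if (net > 0) "c->s" else "s->c",
      rate = abs(net), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(species = character(), direction = character(),
                      rate = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(-out$rate), ]
}

#' Fold enrichment with exact hypergeometric tail
#'
#' Generic set-enrichment utility: `fold = (k/n) / (K/N)` for `k` hits
#' among `n` drawn, against `K` members in a background of `N`, with the
#' exact hypergeometric upper-tail probability `P(X >= k)`.
#'
#' @param k Hits in the selection.
#' @param n Selection size.
#' @param K Category size in the background.
#' @param N Background size.
#' @return A list with `fold` and `p_value`.
#' @export
fold_enrichment <- function(k, n, K, N) {
  stopifnot(k >= 0, n >= 1, K >= 1, N >= 1, k <= n, n <= N, k <= K, K <= N)
  fold <- (k / n) / (K / N)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(fold = fold, p_value = p)
}
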