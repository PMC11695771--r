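#' Q-A channel specification
#'
#' The SpoIIQ-SpoIIIA (Q-A) complex spans the two membranes separating
#' the engulfed forespore from the mother cell. It is modeled as a
#' complex assembled from the eight mother-cell spoIIIA subunits
#' (sigma-E regulated) and forespore SpoIIQ (sigma-F regulated) that
#' catalyzes open-pore transport between the two cytosols.
#'
#' @param mc_genes Mother-cell subunit gene ids (the spoIIIA operon).
#' @param fs_gene Forespore subunit gene id (spoIIQ).
#' @param species Base metabolite names the channel may carry; only
#'   species with a c<->e transport template in the source model are
#'   eligible.
#' @param k_eff Channel usage coupling rate (h^-1).
#' @return A list of class `channel_spec`.
#' @export
channel_spec <- function(mc_genes, fs_gene, species, k_eff = 65) {
  structure(list(mc_genes = mc_genes, fs_gene = fs_gene,
                 species = species, k_eff = k_eff), class = "channel_spec")
}

#' Default channel spec for a toy model
#'
#' Selects every transportable species class of the model (scenario
#' flags later restrict nucleotide classes by closing bounds).
#'
#' @param model A toy single-cell model with `meta`.
#' @return A `channel_spec`.
#' @export
toy_channel_spec <- function(model) {
  ch <- model$meta$channel
  channel_spec(ch$mc_genes, ch$fs_gene,
               unlist(model$meta$species_classes, use.names = FALSE),
               k_eff = ch$k_eff)
}

## id relabeling for the forespore copy
fs_species_id <- function(id) {
  ifelse(grepl("_c$", id), sub("_c$", "_s", id), paste0(id, "_s"))
}

#' Duplicate a single-cell model into a two-cell model
#'
#' Creates full mother-cell and forespore copies of every non-exchange
#' reaction (suffixes `_MC`/`_FS`), relabels forespore cytosolic species
#' `c -> s`, shares a single extracellular pool, and assembles the Q-A
#' channel complex and its transport reactions. Exchange reactions stay
#' single (mother-cell side); forespore copies of membrane transports to
#' `e` are closed by default, so the engulfed cell reaches the medium
#' only through the mother cell and the channel.
#'
#' @param model A validated single-cell `me_model` with compartments c, e.
#' @param channel A [channel_spec()].
#' @param close_fs_exchange Close forespore direct transport to `e`
#'   (default TRUE).
#' @return A `two_cell_model` (also an `me_model`) with provenance maps,
#'   objective set to the forespore biomass.
#' @export
duplicate_into_two_cells <- function(model, channel = toy_channel_spec(model),
                                     close_fs_exchange = TRUE) {
  stopifnot(inherits(model, "me_model"), inherits(channel, "channel_spec"))
  if (!all(c("c", "e") %in% model$compartments))
    stop("source model must have compartments c and e")
  miss <- setdiff(c(channel$mc_genes, channel$fs_gene), names(model$genes))
  if (length(miss)) stop("channel genes missing from model: ",
                         paste(miss, collapse = ", "))

  two <- me_model(paste0(model$id, "_two_cell"), c("c", "s", "e"),
                  inf_bound = model$inf_bound)
  is_e <- model$species$compartment == "e"
  sp_c <- model$species[!is_e, , drop = FALSE]
  two <- add_species(two, sp_c$id, "c", sp_c$category)
  two <- add_species(two, fs_species_id(sp_c$id), "s", sp_c$category)
  two <- add_species(two, model$species$id[is_e], "e",
                     model$species$category[is_e])
  e_ids <- model$species$id[is_e]

  relabel_stoich <- function(st) {
    nm <- names(st)
    new <- ifelse(nm %in% e_ids, nm, fs_species_id(nm))
    stats::setNames(st, new)
  }
  two$genes <- model$genes
  two$transcription_units <- model$transcription_units
  two$complexes <- model$complexes

  rx_map <- list()
  for (rx in model$reactions) {
    if (rx$type == "exchange") {
      two <- add_reaction(two, rx)
      rx_map[[rx$id]] <- c(mc = rx$id, fs = NA_character_)
      next
    }
    mc <- rx; mc$id <- paste0(rx$id, "_MC")
    two <- add_reaction(two, mc)
    fs <- rx
    fs$id <- paste0(rx$id, "_FS")
    fs$stoich <- relabel_stoich(rx$stoich)
    if (!is.null(rx$catalyst) && !rx$catalyst %in% e_ids)
      fs$catalyst <- fs_species_id(rx$catalyst)
    if (close_fs_exchange && any(names(rx$stoich) %in% e_ids)) {
      fs$lb <- 0; fs$ub <- 0
    }
    two <- add_reaction(two, fs)
    rx_map[[rx$id]] <- c(mc = mc$id, fs = fs$id)
  }

  class(two) <- c("two_cell_model", class(two))
  two$provenance <- data.frame(
    orig = model$species$id,
    mc = ifelse(is_e, model$species$id, model$species$id),
    fs = ifelse(is_e, model$species$id, fs_species_id(model$species$id)),
    stringsAsFactors = FALSE)
  two$reaction_map <- rx_map
  two$meta <- model$meta
  two$builtin_depletions <- character(0)
  two <- add_channel_transport(two, channel, source = model)
  two <- set_forespore_objective(two)
  two
}

#' Add (or rebuild) the Q-A channel complex and transport reactions
#'
#' For each selected species with a c<->e transport template in the
#' source model, adds a c<->s reaction with the template stoichiometry
#' retargeted to the forespore (template `e` species become mother-cell
#' `c` species, template `c` species become forespore `s` species, so
#' energy-coupled templates keep their chemistry on the receiving side),
#' the catalyst replaced by the Q-A complex, and open bounds; the
#' reaction is reversible iff the template was.
#'
#' @param two_cell A `two_cell_model`.
#' @param channel A [channel_spec()].
#' @param source The single-cell source model (for templates); defaults
#'   to scanning the two-cell mother-cell copies.
#' @return The modified `two_cell_model` with `channel_reactions` and
#'   `channel_complex` recorded.
#' @export
add_channel_transport <- function(two_cell, channel, source = NULL) {
  stopifnot(inherits(two_cell, "two_cell_model"))
  qa_id <- "cplx_QA"
  if (!qa_id %in% two_cell$species$id) {
    mc_prot <- paste0("protein_", channel$mc_genes)
    fs_prot <- fs_species_id(paste0("protein_", channel$fs_gene))
    miss <- setdiff(c(mc_prot, fs_prot), two_cell$species$id)
    if (length(miss)) stop("channel subunit species missing: ",
                           paste(miss, collapse = ", "))
    sub <- stats::setNames(rep(1, length(mc_prot) + 1L), c(mc_prot, fs_prot))
    two_cell <- add_complex(two_cell, qa_id, sub)
    two_cell <- add_complex_formation(two_cell, qa_id, "c", "complex")
    two_cell$channel_complex <- qa_id
  }
  templates <- if (is.null(source)) NULL else source$reactions
  e_ids <- two_cell$species$id[two_cell$species$compartment == "e"]
  retarget <- function(st) {
    nm <- names(st)
    new_nm <- ifelse(nm %in% e_ids | grepl("_e$", nm),
                     sub("_e$", "_c", nm), fs_species_id(nm))
    stats::setNames(st, new_nm)
  }
  added <- character(0)
  for (sp in channel$species) {
    e_sp <- paste0(sp, "_e")
    tpl_id <- NULL
    for (rid in names(templates)) {
      rx <- templates[[rid]]
      if (rx$type == "transport" && !grepl("_rev$", rid) &&
          e_sp %in% names(rx$stoich)) { tpl_id <- rid; break }
    }
    if (is.null(tpl_id))
      stop("channel selector names species without a transport template: ", sp)
    for (suff in c("", "_rev")) {
      tpl <- templates[[paste0(tpl_id, suff)]]
      if (is.null(tpl)) next  # irreversible template: forward only
      id <- paste0("QA_transport_", sp, suff)
      if (!is.null(two_cell$reactions[[id]])) next
      two_cell <- add_reaction(two_cell, me_reaction(
        id, "transport", retarget(tpl$stoich), lb = 0, ub = Inf,
        catalyst = qa_id, k_eff = channel$k_eff))
      added <- c(added, id)
    }
  }
  two_cell$channel_reactions <- union(two_cell$channel_reactions, added)
  two_cell
}

#' Depletion specification
#'
#' Depletions are simulated by closing (bounds set to zero) the target
#' proteins' translation reactions in the chosen cell copy, the model
#' equivalent of targeted proteolysis under steady state.
#'
#' @param proteins Character vector of protein/gene ids.
#' @param cell One of "vegetative", "mother_cell", "forespore".
#' @return A list of class `depletion_spec`.
#' @export
depletion_spec <- function(proteins,
                           cell = c("forespore", "mother_cell", "vegetative")) {
  cell <- match.arg(cell)
  structure(list(proteins = proteins, cell = cell), class = "depletion_spec")
}

## internal: translation reaction id for a protein in a cell context
translation_rx_id <- function(model, protein, cell) {
  base <- paste0("translation_", protein)
  id <- switch(cell,
               vegetative = base,
               mother_cell = paste0(base, "_MC"),
               forespore = paste0(base, "_FS"))
  if (is.null(model$reactions[[id]]))
    stop("no translation reaction for protein '", protein, "' in ", cell,
         " (looked for ", id, ")")
  id
}

#' Apply a depletion specification
#'
#' @param model An `me_model` or `two_cell_model`.
#' @param spec A [depletion_spec()].
#' @return A model copy with the listed translation reactions closed.
#' @export
apply_depletions <- function(model, spec) {
  stopifnot(inherits(spec, "depletion_spec"))
  if (spec$cell != "vegetative" && !inherits(model, "two_cell_model"))
    stop("cell-specific depletions require a two_cell_model")
  ids <- vapply(spec$proteins, function(p)
    translation_rx_id(model, p, spec$cell), "")
  set_bounds(model, ids, lb = 0, ub = 0)
}

#' Configure the growth medium
#'
#' Sets the listed exchange bounds and closes the uptake (lower) bound of
#' every unlisted exchange; secretion stays open. Uptake is encoded as
#' negative exchange flux, so a glutamate bound of -2 mmol/gDW/h caps
#' uptake at 2.
#'
#' @param model An `me_model`.
#' @param medium Named list: exchange reaction id -> c(lb, ub).
#' @return A model copy.
#' @export
configure_medium <- function(model, medium) {
  ex_ids <- names(model$reactions)[vapply(model$reactions,
                                          function(r) r$type == "exchange", TRUE)]
  miss <- setdiff(names(medium), ex_ids)
  if (length(miss)) stop("unknown exchange reaction(s): ",
                         paste(miss, collapse = ", "))
  for (ex in ex_ids) {
    if (ex %in% names(medium)) {
      b <- medium[[ex]]
      model <- set_bounds(model, ex, lb = b[[1]], ub = b[[2]])
    } else {
      model <- set_bounds(model, ex, lb = 0)
    }
  }
  model
}

#' Set the forespore-only objective
#'
#' The two-cell model optimizes only the forespore formation rate: the
#' forespore biomass reaction is the objective (its lower bound tracks
#' the tested growth rate at assembly), while mother-cell biomass keeps
#' open bounds and no growth coupling, reducing the two-growth-rate
#' problem to one dimension.
#'
#' @param two_cell A `two_cell_model`.
#' @return The modified model.
#' @export
set_forespore_objective <- function(two_cell) {
  stopifnot(inherits(two_cell, "two_cell_model"))
  for (id in c("biomass_MC", "biomass_FS"))
    if (is.null(two_cell$reactions[[id]]))
      stop("missing biomass reaction: ", id)
  two_cell <- set_bounds(two_cell, "biomass_MC", lb = 0, ub = Inf)
  set_objective(two_cell, "biomass_FS")
}

#' Apply sigma-factor partitioning
#'
#' Transcription of sigma-E and sigma-K units is closed in the forespore
#' copy and sigma-F units in the mother-cell copy, reflecting
#' compartment-specific sigma factor activity. Because peptidoglycan
#' synthesis is sigma-K regulated (mother cell only), the wall precursor
#' is granted an uncatalyzed integration reaction from the mother cell's
#' cytosol into the forespore.
#'
#' @param two_cell A `two_cell_model` whose TUs carry sigma annotations.
#' @return The modified model.
#' @export
apply_sigma_partition <- function(two_cell) {
  stopifnot(inherits(two_cell, "two_cell_model"))
  sg <- two_cell$meta$sigma_genes
  sigma_of <- function(tu) {
    s <- tu$sigma
    if (is.null(s) || !nzchar(s)) stop("TU ", tu$id, " lacks a sigma annotation")
    sub("^protein_", "", s)
  }
  for (tu_id in names(two_cell$transcription_units)) {
    s <- sigma_of(two_cell$transcription_units[[tu_id]])
    if (s %in% sg[c("mother_cell_early", "mother_cell_late")])
      two_cell <- set_bounds(two_cell, paste0("transcription_", tu_id, "_FS"),
                             lb = 0, ub = 0)
    if (s == sg[["forespore"]])
      two_cell <- set_bounds(two_cell, paste0("transcription_", tu_id, "_MC"),
                             lb = 0, ub = 0)
  }
  if (is.null(two_cell$reactions[["integration_wallp"]]))
    two_cell <- add_reaction(two_cell, me_reaction(
      "integration_wallp", "transport", list(wallp_c = -1, wallp_s = 1), 0, Inf))
  two_cell
}

#' Scenario flags for the two-cell model
#'
#' Flags map to reaction-bound edits only: channel nucleotide classes
#' opened or closed, the forespore F1FO ATP synthase present or absent,
#' and the built-in forespore depletion list.
#'
#' @param ndp_ntp_transport Allow NDP and NTP species through the channel.
#' @param atp_transport Allow ATP/ADP through the channel.
#' @param fs_atp_synthase Forespore ATP synthase present.
#' @param fs_depletions Protein ids closed in the forespore at build time
#'   (`NULL` = the model's built-in list).
#' @return A list of class `scenario_flags`.
#' @export
scenario_flags <- function(ndp_ntp_transport = TRUE, atp_transport = TRUE,
                           fs_atp_synthase = FALSE, fs_depletions = NULL) {
  structure(list(ndp_ntp_transport = ndp_ntp_transport,
                 atp_transport = atp_transport,
                 fs_atp_synthase = fs_atp_synthase,
                 fs_depletions = fs_depletions), class = "scenario_flags")
}

#' Apply scenario flags to a two-cell model
#'
#' @param two_cell A `two_cell_model` built from a toy model.
#' @param flags A [scenario_flags()] list.
#' @return The modified model; `builtin_depletions` records the
#'   build-time forespore depletion set for [build_naive_model()].
#' @export
apply_scenario <- function(two_cell, flags = scenario_flags()) {
  stopifnot(inherits(two_cell, "two_cell_model"), inherits(flags, "scenario_flags"))
  cls <- two_cell$meta$species_classes
  set_channel <- function(model, species, open) {
    ids <- c(paste0("QA_transport_", species),
             paste0("QA_transport_", species, "_rev"))
    ids <- ids[ids %in% names(model$reactions)]
    if (open) {
      model <- set_bounds(model, ids, lb = 0, ub = model$inf_bound)
    } else {
      model <- set_bounds(model, ids, lb = 0, ub = 0)
    }
    model
  }
  two_cell <- set_channel(two_cell, c(cls$ndp, cls$ntp), flags$ndp_ntp_transport)
  two_cell <- set_channel(two_cell, cls$atp, flags$atp_transport)
  if (!flags$fs_atp_synthase) {
    gene <- two_cell$meta$fs_atp_synthase_gene
    two_cell <- set_bounds(two_cell, paste0("translation_", gene, "_FS"),
                           lb = 0, ub = 0)
    two_cell$builtin_depletions <- union(two_cell$builtin_depletions, gene)
  }
  deps <- flags$fs_depletions
  if (is.null(deps)) deps <- two_cell$meta$builtin_fs_depletions
  if (length(deps)) {
    two_cell <- apply_depletions(two_cell, depletion_spec(deps, "forespore"))
    two_cell$builtin_depletions <- union(two_cell$builtin_depletions, deps)
  }
  two_cell
}

#' Build a ready-to-solve two-cell toy model
#'
#' Convenience pipeline: duplicate into two cells with the Q-A channel,
#' apply sigma partitioning, the glutamate medium, and scenario flags.
#'
#' @param single A toy single-cell model from
#'   [generate_toy_sporulation_model()].
#' @param flags A [scenario_flags()] list.
#' @param medium A medium list (default: glutamate minimal).
#' @return A solved-ready `two_cell_model`.
#' @export
build_two_cell_toy <- function(single, flags = scenario_flags(),
                               medium = toy_glutamate_medium(single)) {
  two <- duplicate_into_two_cells(single, toy_channel_spec(single))
  two <- apply_sigma_partition(two)
  two <- configure_medium(two, medium)
  apply_scenario(two, flags)
}
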