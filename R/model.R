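#' ME-model data structures
#'
#' An ME (metabolism-and-expression) model couples a metabolic network to
#' the transcription and translation reactions that synthesize its own
#' catalysts, with growth-rate-dependent coupling coefficients. The model
#' object is a plain list of registries (species, genes, transcription
#' units, complexes, reactions) with S3 class `me_model`; a two-cell
#' mother-cell/forespore model carries class `two_cell_model` in addition.
#'
#' Species compartments follow the sporulation convention: `c` mother-cell
#' (or single-cell) cytosol, `s` forespore cytosol, `e` extracellular.
#' Flux units are mmol/gDW/h; "open" bounds use a finite INF sentinel
#' (default 1000) so every LP has finite bounds.
#'
#' @param id Model identifier.
#' @param compartments Character vector of compartment letters.
#' @param inf_bound Finite sentinel used for open reaction bounds.
#' @return An empty `me_model`.
#' @export
me_model <- function(id = "model", compartments = c("c", "e"), inf_bound = 1000) {
  structure(list(
    id = id,
    compartments = compartments,
    inf_bound = inf_bound,
    species = data.frame(id = character(), compartment = character(),
                         category = character(), stringsAsFactors = FALSE),
    genes = list(),
    transcription_units = list(),
    complexes = list(),
    reactions = list(),
    objective = NA_character_
  ), class = "me_model")
}

REACTION_TYPES <- c("metabolic", "transport", "exchange", "transcription",
                    "translation", "complex_formation", "biomass", "sink", "demand")
SPECIES_CATEGORIES <- c("metabolite", "mRNA", "protein", "complex", "machinery")

#' Add species to a model
#'
#' @param model An `me_model`.
#' @param id Species id(s).
#' @param compartment Compartment letter, recycled.
#' @param category One of metabolite, mRNA, protein, complex, machinery.
#' @return The modified model.
#' @export
add_species <- function(model, id, compartment, category = "metabolite") {
  stopifnot(inherits(model, "me_model"))
  df <- data.frame(id = id, compartment = compartment, category = category,
                   stringsAsFactors = FALSE)
  model$species <- rbind(model$species, df)
  model
}

#' Register a gene
#'
#' @param model An `me_model`.
#' @param id Locus-tag style gene id.
#' @param peptide Id of the protein species produced.
#' @param length Transcript length in nucleotides (>= 1).
#' @param composition Named integer vector of residue counts per
#'   amino-acid species id.
#' @return The modified model.
#' @export
add_gene <- function(model, id, peptide, length, composition) {
  stopifnot(length >= 1, all(composition >= 0), sum(composition) >= 1)
  model$genes[[id]] <- list(id = id, peptide = peptide,
                            length = as.numeric(length),
                            composition = composition)
  model
}

#' Register a transcription unit
#'
#' @param model An `me_model`.
#' @param id TU id.
#' @param genes Ordered character vector of member gene ids (nonempty).
#' @param sigma Sigma-factor protein species id driving the unit.
#' @return The modified model.
#' @export
add_transcription_unit <- function(model, id, genes, sigma) {
  stopifnot(length(genes) >= 1)
  model$transcription_units[[id]] <- list(id = id, genes = genes, sigma = sigma)
  model
}

#' Register an enzyme complex
#'
#' @param model An `me_model`.
#' @param id Complex species id.
#' @param subunits Named integer vector, protein species id -> count (>= 1).
#' @return The modified model.
#' @export
add_complex <- function(model, id, subunits) {
  stopifnot(length(subunits) >= 1, all(subunits >= 1))
  model$complexes[[id]] <- list(id = id, subunits = subunits)
  model
}

#' Construct a reaction
#'
#' Stoichiometric coefficients may be plain numerics or `mu_expr`
#' objects (or strings in the mu-expression grammar, which are parsed).
#' A catalyst declares usage coupling: at assembly the catalyst species
#' receives an additional `-mu/k_eff` coefficient, so enzyme demand
#' scales with flux and growth rate.
#'
#' @param id Reaction id.
#' @param type One of the ME reaction types.
#' @param stoich Named list/vector: species id -> coefficient.
#' @param lb,ub Bounds (mmol/gDW/h); `Inf`/`-Inf` are replaced by the
#'   model's sentinel at assembly.
#' @param catalyst Optional catalyzing species id (protein, complex or
#'   machinery).
#' @param k_eff Effective catalytic rate (h^-1), required with a catalyst.
#' @return An object of class `me_reaction`.
#' @export
me_reaction <- function(id, type, stoich, lb = 0, ub = Inf,
                        catalyst = NULL, k_eff = NULL) {
  stopifnot(type %in% REACTION_TYPES, lb <= ub)
  if (!is.null(catalyst) && is.null(k_eff))
    stop("reaction ", id, ": a catalyst requires k_eff")
  st <- as.list(stoich)
  st <- lapply(st, function(v) {
    if (is.character(v)) coef_from_json(v) else v
  })
  if (length(st) == 0 && !type %in% c("exchange", "sink", "demand"))
    stop("reaction ", id, ": empty stoichiometry for type ", type)
  structure(list(id = id, type = type, stoich = st, lb = lb, ub = ub,
                 catalyst = catalyst, k_eff = k_eff), class = "me_reaction")
}

#' Add a reaction to a model
#'
#' @param model An `me_model`.
#' @param reaction An `me_reaction` (or arguments forwarded to
#'   [me_reaction()] via `...`).
#' @param ... Forwarded to [me_reaction()] when `reaction` is a string id.
#' @return The modified model.
#' @export
add_reaction <- function(model, reaction, ...) {
  if (is.character(reaction)) reaction <- me_reaction(reaction, ...)
  if (!is.null(model$reactions[[reaction$id]]))
    stop("duplicate reaction id: ", reaction$id)
  model$reactions[[reaction$id]] <- reaction
  model
}

#' Set reaction bounds
#'
#' @param model An `me_model`.
#' @param id Reaction id(s).
#' @param lb,ub New bounds (recycled). `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  lb <- if (is.null(lb)) rep(NA_real_, length(id)) else rep_len(lb, length(id))
  ub <- if (is.null(ub)) rep(NA_real_, length(id)) else rep_len(ub, length(id))
  for (k in seq_along(id)) {
    rx <- model$reactions[[id[k]]]
    if (is.null(rx)) stop("unknown reaction id: ", id[k])
    if (!is.na(lb[k])) rx$lb <- lb[k]
    if (!is.na(ub[k])) rx$ub <- ub[k]
    model$reactions[[id[k]]] <- rx
  }
  model
}

#' Set the model objective reaction
#'
#' The objective reaction is the biomass (formation-rate) reaction of the
#' cell of interest; at assembly its lower bound is raised to the tested
#' growth rate.
#'
#' @param model An `me_model`.
#' @param id Reaction id.
#' @return The modified model.
#' @export
set_objective <- function(model, id) {
  if (is.null(model$reactions[[id]])) stop("unknown reaction id: ", id)
  model$objective <- id
  model
}

#' Validate a model
#'
#' Returns machine-readable diagnostics rather than raising: dangling
#' species references, duplicate ids, bound violations, coefficient poles
#' on the growth-rate search interval, and objective problems. An empty
#' data frame means the model is valid.
#'
#' @param model An `me_model`.
#' @param mu_hi Upper end of the growth-rate interval checked for poles.
#' @return A data frame with columns `code`, `where`, `message`.
#' @export
validate_model <- function(model, mu_hi = 2) {
  findings <- list()
  note <- function(code, where, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      code = code, where = where, message = message, stringsAsFactors = FALSE)
  }
  sp_ids <- model$species$id
  if (anyDuplicated(sp_ids))
    note("duplicate_id", "species", paste("duplicate species ids:",
         paste(unique(sp_ids[duplicated(sp_ids)]), collapse = ", ")))
  bad_comp <- !model$species$compartment %in% model$compartments
  if (any(bad_comp))
    note("bad_compartment", "species",
         paste("species in undeclared compartments:",
               paste(sp_ids[bad_comp], collapse = ", ")))
  rx_ids <- names(model$reactions)
  if (anyDuplicated(rx_ids))
    note("duplicate_id", "reactions", paste("duplicate reaction ids:",
         paste(unique(rx_ids[duplicated(rx_ids)]), collapse = ", ")))
  known <- c(sp_ids)
  for (rx in model$reactions) {
    refs <- names(rx$stoich)
    miss <- setdiff(refs, known)
    if (length(miss))
      note("dangling_reference", rx$id,
           paste("unknown species:", paste(miss, collapse = ", ")))
    if (!is.null(rx$catalyst) && !rx$catalyst %in% known)
      note("dangling_reference", rx$id, paste("unknown catalyst:", rx$catalyst))
    if (rx$lb > rx$ub)
      note("bound_violation", rx$id, "lower bound exceeds upper bound")
    for (s in refs) {
      if (!mu_expr_finite_on(rx$stoich[[s]], mu_hi))
        note("pole", rx$id, paste("coefficient on", s,
             "has a pole or blow-up on [0,", mu_hi, "]"))
    }
  }
  for (tu in model$transcription_units) {
    if (length(tu$genes) < 1) note("empty_tu", tu$id, "no genes")
    miss <- setdiff(tu$genes, names(model$genes))
    if (length(miss))
      note("dangling_reference", tu$id,
           paste("unknown genes:", paste(miss, collapse = ", ")))
  }
  if (is.na(model$objective)) {
    note("objective", "model", "no objective reaction set")
  } else if (is.null(model$reactions[[model$objective]])) {
    note("objective", "model", paste("objective reaction missing:", model$objective))
  }
  if (length(findings) == 0)
    return(data.frame(code = character(), where = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Machinery rate parameters for expression reactions
#'
#' @param k_trx RNA polymerase coupling rate (h^-1).
#' @param k_rib Ribosome coupling rate (h^-1).
#' @param k_mRNA mRNA usage coupling rate (h^-1); mRNA degradation is
#'   folded into this dilution term.
#' @param atp_per_residue ATP hydrolyzed per residue translated.
#' @param atp_species,adp_species,ntp_species Species ids used by
#'   expression chemistry.
#' @return A named list.
#' @export
machinery_params <- function(k_trx = 50, k_rib = 50, k_mRNA = 5,
                             atp_per_residue = 2,
                             atp_species = "atp_c", adp_species = "adp_c",
                             ntp_species = c("atp_c", "gtp_c", "ctp_c", "utp_c")) {
  list(k_trx = k_trx, k_rib = k_rib, k_mRNA = k_mRNA,
       atp_per_residue = atp_per_residue, atp_species = atp_species,
       adp_species = adp_species, ntp_species = ntp_species)
}

#' Build transcription and translation reactions for a transcription unit
#'
#' Adds one transcription reaction for the unit (consuming NTPs in
#' proportion to transcript length and the sigma-specific RNA polymerase
#' holoenzyme at `-mu/k_trx`) producing a single unit transcript, plus one
#' translation reaction per member gene (consuming the transcript at
#' `-mu/k_mRNA`, amino acids per residue composition, ATP per residue, and
#' the ribosome at `-mu/k_rib`) producing the peptide. Charged-tRNA
#' chemistry is collapsed into direct amino-acid consumption with a fixed
#' ATP cost per residue.
#'
#' @param model An `me_model` whose machinery species exist.
#' @param tu_id Id of a registered transcription unit.
#' @param params A [machinery_params()] list.
#' @param holoenzyme Species id of the RNA polymerase holoenzyme for the
#'   unit's sigma factor.
#' @param ribosome Species id of the ribosome machinery.
#' @return The modified model.
#' @export
build_expression_reactions <- function(model, tu_id, params = machinery_params(),
                                       holoenzyme, ribosome = "ribosome") {
  tu <- model$transcription_units[[tu_id]]
  if (is.null(tu)) stop("unknown transcription unit: ", tu_id)
  miss <- setdiff(tu$genes, names(model$genes))
  if (length(miss)) stop("TU ", tu_id, " references unknown genes: ",
                         paste(miss, collapse = ", "))
  for (mach in c(holoenzyme, ribosome))
    if (!mach %in% model$species$id)
      stop("missing machinery species: ", mach)

  mrna_id <- paste0("mRNA_", tu_id)
  if (!mrna_id %in% model$species$id)
    model <- add_species(model, mrna_id, "c", "mRNA")

  total_len <- sum(vapply(tu$genes, function(g) model$genes[[g]]$length, 0))
  per_ntp <- total_len / length(params$ntp_species)  # mmol NTP per mmol transcript
  st <- as.list(c(stats::setNames(rep(-per_ntp, length(params$ntp_species)),
                                  params$ntp_species)))
  st[[mrna_id]] <- 1
  model <- add_reaction(model, me_reaction(
    id = paste0("transcription_", tu_id), type = "transcription",
    stoich = st, lb = 0, ub = Inf,
    catalyst = holoenzyme, k_eff = params$k_trx))

  for (g in tu$genes) {
    gene <- model$genes[[g]]
    if (!gene$peptide %in% model$species$id)
      model <- add_species(model, gene$peptide, "c", "protein")
    comp <- gene$composition
    n_res <- sum(comp)
    st <- as.list(-comp)
    names(st) <- names(comp)
    atp_cost <- params$atp_per_residue * n_res
    st[[params$atp_species]] <- (if (is.null(st[[params$atp_species]]))
      0 else st[[params$atp_species]]) - atp_cost
    st[[params$adp_species]] <- atp_cost
    st[[mrna_id]] <- parse_mu_expression(sprintf("-mu/%g", params$k_mRNA))
    st[[gene$peptide]] <- 1
    model <- add_reaction(model, me_reaction(
      id = paste0("translation_", g), type = "translation",
      stoich = st, lb = 0, ub = Inf,
      catalyst = ribosome, k_eff = params$k_rib))
  }
  model
}

#' Add a complex-formation reaction for a registered complex
#'
#' @param model An `me_model`.
#' @param complex_id Registered complex id.
#' @param compartment Compartment for the complex species.
#' @param category Species category (complex or machinery).
#' @return The modified model.
#' @export
add_complex_formation <- function(model, complex_id, compartment = "c",
                                  category = "complex") {
  cx <- model$complexes[[complex_id]]
  if (is.null(cx)) stop("unknown complex: ", complex_id)
  if (!complex_id %in% model$species$id)
    model <- add_species(model, complex_id, compartment, category)
  st <- as.list(-cx$subunits)
  names(st) <- names(cx$subunits)
  st[[complex_id]] <- 1
  add_reaction(model, me_reaction(
    id = paste0("formation_", complex_id), type = "complex_formation",
    stoich = st, lb = 0, ub = Inf))
}

#' @export
print.me_model <- function(x, ...) {
  cat("<me_model> ", x$id, "\n", sep = "")
  cat("  compartments: ", paste(x$compartments, collapse = ", "), "\n", sep = "")
  cat("  species: ", nrow(x$species), " | genes: ", length(x$genes),
      " | TUs: ", length(x$transcription_units),
      " | complexes: ", length(x$complexes),
      " | reactions: ", length(x$reactions), "\n", sep = "")
  cat("  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

## internal: reaction bound vectors with the INF sentinel applied
bound_vectors <- function(model) {
  inf <- model$inf_bound
  lb <- vapply(model$reactions, function(r) max(r$lb, -inf), 0)
  ub <- vapply(model$reactions, function(r) min(r$ub, inf), 0)
  list(lb = lb, ub = ub)
}
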