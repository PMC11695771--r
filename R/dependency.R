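#' Options for the inactivation/blockage analysis
#'
#' @param eps_act Activity threshold on translation flux (strict:
#'   `t_A > eps_act` is active).
#' @param sink_bound Upper bound of protein sink reactions, ten times
#'   the LP feasibility tolerance by default.
#' @param blocked_frac A candidate is blocked when its maximized sink
#'   flux stays below `blocked_frac * sink_bound`.
#' @param mu_slack Relative slack below the depleted optimum at which
#'   the sink maximization runs. At exactly `mu_max` the LP sits on a
#'   knife edge where the feasible set is (numerically) a point and
#'   sink maximization is vacuous; a sliver of slack restores the
#'   intended semantics without changing any classification.
#' @return A named list.
#' @export
dependency_options <- function(eps_act = 1e-9, sink_bound = 1e-7,
                               blocked_frac = 1e-3, mu_slack = 1e-4) {
  list(eps_act = eps_act, sink_bound = sink_bound,
       blocked_frac = blocked_frac, mu_slack = mu_slack)
}

## internal: translation reaction ids of a protein in a cell context
translation_ids_of <- function(model, protein, cell) {
  id <- switch(cell,
               vegetative = paste0("translation_", protein),
               mother_cell = paste0("translation_", protein, "_MC"),
               forespore = paste0("translation_", protein, "_FS"))
  id[id %in% names(model$reactions)]
}

## internal: protein species id in a cell context
protein_species_of <- function(protein, cell) {
  p <- paste0("protein_", protein)
  if (cell == "forespore") fs_species_id(p) else p
}

#' Protein activity from translation flux
#'
#' A protein's activity is its translation flux in the reported
#' (parsimonious) flux distribution; it is active when the flux exceeds
#' the activity threshold strictly.
#'
#' @param fluxes Named flux vector from [parsimonious_solution()].
#' @param model The model the fluxes belong to.
#' @param protein Protein id.
#' @param cell Cell context.
#' @param options A [dependency_options()] list.
#' @return A list with `protein`, `cell`, `t_A`, `active`.
#' @export
protein_activity <- function(fluxes, model, protein,
                             cell = c("forespore", "mother_cell", "vegetative"),
                             options = dependency_options()) {
  cell <- match.arg(cell)
  ids <- translation_ids_of(model, protein, cell)
  if (length(ids) == 0)
    stop("protein has no translation reaction in ", cell, ": ", protein)
  t_A <- sum(fluxes[ids])
  list(protein = protein, cell = cell, t_A = unname(t_A),
       active = t_A > options$eps_act)
}

## internal: activity vector for many proteins at once
activity_vector <- function(fluxes, model, proteins, cell) {
  vapply(proteins, function(p) {
    ids <- translation_ids_of(model, p, cell)
    if (length(ids) == 0) NA_real_ else sum(fluxes[ids])
  }, 0)
}

#' Rebuild the naive model (no built-in depletions)
#'
#' Reopens every build-time forespore depletion (including the absent
#' ATP synthase) so that depletions suggested by proteomics can be
#' assessed against a model that knows nothing about them.
#'
#' @param two_cell A `two_cell_model` with recorded built-in depletions.
#' @return The naive model; `naive_reopened` records the reopened set.
#' @export
build_naive_model <- function(two_cell) {
  stopifnot(inherits(two_cell, "two_cell_model"))
  reopened <- character(0)
  for (p in two_cell$builtin_depletions) {
    ids <- translation_ids_of(two_cell, p, "forespore")
    if (length(ids)) {
      two_cell <- set_bounds(two_cell, ids, lb = 0, ub = Inf)
      reopened <- c(reopened, p)
    }
  }
  two_cell$naive_reopened <- reopened
  two_cell$builtin_depletions <- setdiff(two_cell$builtin_depletions, reopened)
  two_cell
}

#' Scan single depletions for induced protein inactivation
#'
#' For each candidate depletion the model is re-solved (bisection for
#' the new maximal forespore formation rate, then a parsimonious flux
#' distribution) and every protein that was active in the wild type but
#' has zero translation flux after the depletion is recorded as
#' inactivated (pending the blockage refinement). Only wild-type-active
#' proteins can be classified, so the universe is restricted to them.
#'
#' @param model A solved-ready model (usually a `two_cell_model`).
#' @param candidate_depletions Protein ids to deplete, one at a time.
#' @param cell Cell context for both the depletion and the affected
#'   proteins.
#' @param universe Protein ids considered as affected candidates
#'   (default: all genes).
#' @param options A [dependency_options()] list.
#' @param solve_opts A [solve_options()] list.
#' @return A list with `records` (data frame: depleted_protein,
#'   affected_protein, classification, t_wt, t_dep, mu_max), `wild_type`
#'   (fluxes, mu_max, active set), and `errors`.
#' @export
dependency_scan <- function(model, candidate_depletions,
                            cell = c("forespore", "mother_cell"),
                            universe = names(model$genes),
                            options = dependency_options(),
                            solve_opts = solve_options()) {
  cell <- match.arg(cell)
  model <- cache_lp_structure(model)
  wt <- maximize_growth(model, solve_opts)
  if (wt$status != "optimal") stop("wild-type model does not solve")
  wt_flux <- parsimonious_solution(model, wt$mu_max, solve_opts)
  act_wt <- activity_vector(wt_flux, model, universe, cell)
  wt_active <- universe[!is.na(act_wt) & act_wt > options$eps_act]

  rows <- list(); errors <- list()
  for (pB in candidate_depletions) {
    res <- tryCatch({
      dep <- apply_depletions(model, depletion_spec(pB, cell))
      r <- maximize_growth(dep, solve_opts)
      if (r$status != "optimal")
        stop("depleted model infeasible at the search floor")
      dep_flux <- parsimonious_solution(dep, r$mu_max, solve_opts)
      act_dep <- activity_vector(dep_flux, dep, wt_active, cell)
      hit <- wt_active[act_dep <= options$eps_act & wt_active != pB]
      if (length(hit) == 0) NULL else
        data.frame(depleted_protein = pB, affected_protein = hit,
                   classification = "inactive",
                   t_wt = unname(act_wt[match(hit, universe)]),
                   t_dep = unname(act_dep[match(hit, wt_active)]),
                   mu_max = r$mu_max, stringsAsFactors = FALSE)
    }, error = function(e) structure(conditionMessage(e), class = "scan_error"))
    if (inherits(res, "scan_error")) errors[[pB]] <- unclass(res)
    else if (!is.null(res)) rows[[pB]] <- res
  }
  records <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(depleted_protein = character(), affected_protein = character(),
                  classification = character(), t_wt = numeric(),
                  t_dep = numeric(), mu_max = numeric(), stringsAsFactors = FALSE)
  list(records = records,
       wild_type = list(mu_max = wt$mu_max, fluxes = wt_flux,
                        active = wt_active),
       errors = errors)
}

#' Blockage test via sink-reaction maximization
#'
#' Distinguishes optimum-dependent inactivity from true blockage: for
#' each candidate a sink reaction (0 -> protein) with a tiny upper bound
#' is added to the depleted model, the growth rate is fixed at the
#' depleted optimum, and the summed sink flux is maximized. A candidate
#' whose sink cannot carry flux has no remaining route through any of
#' its catalyzed reactions and is blocked; one whose sink fills to its
#' bound is merely inactive in the optimum.
#'
#' @param model The (un-depleted) model.
#' @param depleted Protein id depleted.
#' @param candidates Protein ids flagged inactive for this depletion.
#' @param cell Cell context.
#' @param mu Growth rate to fix (default: re-derived by bisection).
#' @param options A [dependency_options()] list.
#' @param solve_opts A [solve_options()] list.
#' @return A data frame: depleted_protein, affected_protein,
#'   classification ("blocked"/"inactive"), sink_flux.
#' @export
blockage_test <- function(model, depleted, candidates,
                          cell = c("forespore", "mother_cell"),
                          mu = NULL, options = dependency_options(),
                          solve_opts = solve_options()) {
  cell <- match.arg(cell)
  if (length(candidates) == 0)
    return(data.frame(depleted_protein = character(),
                      affected_protein = character(),
                      classification = character(), sink_flux = numeric(),
                      stringsAsFactors = FALSE))
  dep <- apply_depletions(model, depletion_spec(depleted, cell))
  if (is.null(mu)) {
    r <- maximize_growth(dep, solve_opts)
    if (r$status != "optimal") stop("depleted model does not solve")
    mu <- r$mu_max
  }
  mu <- mu * (1 - options$mu_slack)
  sink_ids <- character(length(candidates))
  for (k in seq_along(candidates)) {
    sp <- protein_species_of(candidates[k], cell)
    if (!sp %in% dep$species$id) stop("no protein species: ", sp)
    sink_ids[k] <- paste0("sink_", sp)
    dep <- add_reaction(dep, me_reaction(
      sink_ids[k], "sink", stats::setNames(list(1), sp),
      lb = 0, ub = options$sink_bound))
  }
  obj <- stats::setNames(rep(1, length(sink_ids)), sink_ids)
  flux <- tryCatch(optimize_at_mu(dep, mu, obj, maximize = TRUE,
                                  options = solve_opts),
                   error = function(e) NULL)
  if (is.null(flux))  # knife-edge at mu_max: retry just below
    flux <- optimize_at_mu(dep, max(mu - solve_opts$bisect_tol, 0), obj,
                           maximize = TRUE, options = solve_opts)
  s <- flux[sink_ids]
  data.frame(depleted_protein = depleted, affected_protein = candidates,
             classification = ifelse(
               s < options$blocked_frac * options$sink_bound,
               "blocked", "inactive"),
             sink_flux = unname(s), stringsAsFactors = FALSE)
}

#' Full dependency analysis (inactivation + blockage)
#'
#' Runs [dependency_scan()] and refines every hit with [blockage_test()].
#'
#' @inheritParams dependency_scan
#' @return A list with `records` (classification is "blocked" or
#'   "inactive"), `wild_type`, `errors`.
#' @export
dependency_analysis <- function(model, candidate_depletions,
                                cell = c("forespore", "mother_cell"),
                                universe = names(model$genes),
                                options = dependency_options(),
                                solve_opts = solve_options()) {
  cell <- match.arg(cell)
  scan <- dependency_scan(model, candidate_depletions, cell, universe,
                          options, solve_opts)
  rec <- scan$records
  if (nrow(rec)) {
    out <- list()
    for (pB in unique(rec$depleted_protein)) {
      sub <- rec[rec$depleted_protein == pB, ]
      bt <- blockage_test(model, pB, sub$affected_protein, cell,
                          mu = sub$mu_max[1], options, solve_opts)
      sub$classification <- bt$classification[match(sub$affected_protein,
                                                    bt$affected_protein)]
      sub$sink_flux <- bt$sink_flux[match(sub$affected_protein,
                                          bt$affected_protein)]
      out[[pB]] <- sub
    }
    rec <- do.call(rbind, c(out, make.row.names = FALSE))
  }
  scan$records <- rec
  scan
}

#' Write dependency records as TSV
#'
#' Columns depleted_protein, affected_protein, classification, in
#' deterministic order.
#'
#' @param records Records data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dependency_tsv <- function(records, path) {
  df <- records[order(records$depleted_protein, records$affected_protein),
                c("depleted_protein", "affected_protein", "classification")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
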