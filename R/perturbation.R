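#' Essentiality scan over depletion sets
#'
#' A protein (set) is deemed essential in a context when closing its
#' translation reaction(s) leaves no feasible growth above the
#' essentiality floor `eps_mu` — the bisection analogue of "the model
#' became infeasible". The floor separates numerically-zero from tiny
#' growth: `eps_mu = max(1e-4, 0.1 * mu_wt)` by default. In a
#' double-precision LP the expression-machinery fluxes scale roughly
#' with `mu^2/k_eff` and sink below the feasibility tolerance for very
#' small `mu`, so the floor is kept at a resolvable fraction of the
#' wild-type rate; depletion outcomes in growth-coupled models are
#' structural (near-wild-type growth or none), making the partition
#' insensitive to the floor within (0, mu_wt).
#'
#' By monotone feasibility, essentiality is decided by a single
#' feasibility LP at the floor (warm-started from the wild type), which
#' keeps proteome-scale scans cheap; `full_mu = TRUE` additionally
#' bisects for `mu_max` per depletion.
#'
#' @param model An `me_model` or `two_cell_model`, medium configured.
#' @param depletion_sets A list of [depletion_spec()] objects.
#' @param options A [solve_options()] list.
#' @param eps_mu Essentiality floor (h^-1); `NULL` = derived from the
#'   wild type.
#' @param full_mu Also compute `mu_max` per depletion by bisection.
#' @return A data frame with columns `depletion_set` (comma-joined ids),
#'   `context`, `mu_max` (NA unless `full_mu` or infeasible), and
#'   `essential`; attribute `mu_wt` carries the wild-type rate.
#' @export
essentiality_scan <- function(model, depletion_sets, options = solve_options(),
                              eps_mu = NULL, full_mu = FALSE) {
  model <- cache_lp_structure(model)
  wt <- maximize_growth(model, options)
  if (wt$status != "optimal" || wt$mu_max < 1e-4)
    stop("wild-type model does not grow above the essentiality floor")
  if (is.null(eps_mu)) eps_mu <- max(1e-4, 0.1 * wt$mu_max)
  base <- feasible_at(model, eps_mu, options)
  rows <- vector("list", length(depletion_sets))
  for (k in seq_along(depletion_sets)) {
    spec <- depletion_sets[[k]]
    rows[[k]] <- tryCatch({
      dep <- apply_depletions(model, spec)
      f <- feasible_at(dep, eps_mu, options, state = base$state)
      if (identical(f$feasible, NA))
        stop("solver error for depletion set ",
             paste(spec$proteins, collapse = ","))
      ess <- !f$feasible
      mu <- if (ess) 0 else NA_real_
      if (full_mu) {
        r <- maximize_growth(dep, options)
        mu <- if (r$status == "optimal") r$mu_max else 0
      }
      data.frame(depletion_set = paste(spec$proteins, collapse = ","),
                 context = spec$cell, mu_max = mu, essential = ess,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(depletion_set = paste(spec$proteins, collapse = ","),
                 context = spec$cell, mu_max = NA_real_, essential = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  attr(out, "mu_wt") <- wt$mu_max
  attr(out, "eps_mu") <- eps_mu
  out
}

#' Single-protein depletion specs for a whole proteome
#'
#' @param model Model providing the gene registry.
#' @param cell Target cell context.
#' @param proteins Protein ids (default: every gene in the model).
#' @return A list of [depletion_spec()] objects.
#' @export
single_depletions <- function(model, cell, proteins = names(model$genes)) {
  lapply(proteins, function(p) depletion_spec(p, cell))
}

#' Partition proteins by essentiality context
#'
#' Deterministic partition of a common protein universe over the seven
#' nonempty regions of the forespore/mother-cell/vegetative Venn diagram
#' plus the none region.
#'
#' @param vg,mc,fs Data frames from [essentiality_scan()] over
#'   single-protein sets covering the same universe.
#' @return A list of class `essentiality_groups` with one character
#'   vector per region (`fs_only`, `mc_only`, `vg_only`, `fs_mc`,
#'   `fs_vg`, `mc_vg`, `fs_mc_vg`, `none`) and the `universe`.
#' @export
classify_essentiality_groups <- function(vg, mc, fs) {
  uni <- sort(vg$depletion_set)
  if (!identical(sort(mc$depletion_set), uni) ||
      !identical(sort(fs$depletion_set), uni))
    stop("the three scans cover different protein universes")
  ess <- function(df) df$depletion_set[which(df$essential)]
  V <- ess(vg); M <- ess(mc); F <- ess(fs)
  grp <- list(
    fs_only = setdiff(F, union(M, V)),
    mc_only = setdiff(M, union(F, V)),
    vg_only = setdiff(V, union(F, M)),
    fs_mc = setdiff(intersect(F, M), V),
    fs_vg = setdiff(intersect(F, V), M),
    mc_vg = setdiff(intersect(M, V), F),
    fs_mc_vg = intersect(intersect(F, M), V),
    none = setdiff(uni, union(union(F, M), V))
  )
  grp <- lapply(grp, sort)
  grp$universe <- uni
  structure(grp, class = "essentiality_groups")
}

#' @export
print.essentiality_groups <- function(x, ...) {
  cat("<essentiality_groups> universe:", length(x$universe), "proteins\n")
  for (r in c("fs_only", "mc_only", "vg_only", "fs_mc", "fs_vg", "mc_vg",
              "fs_mc_vg", "none"))
    cat(sprintf("  %-9s %4d  %s\n", r, length(x[[r]]),
                paste(utils::head(x[[r]], 8), collapse = ", ")))
  invisible(x)
}

#' Germination/outgrowth essentiality
#'
#' A protein is deemed essential for germination and outgrowth when it
#' is essential for vegetative growth: an outgrowing spore needs at
#' least the vegetative proteome.
#'
#' @param protein Protein id.
#' @param vg Vegetative [essentiality_scan()] data frame.
#' @return Logical flag.
#' @export
germination_essential <- function(protein, vg) {
  i <- match(protein, vg$depletion_set)
  if (is.na(i)) stop("protein not covered by the vegetative scan: ", protein)
  isTRUE(vg$essential[i])
}

#' Write an essentiality table as TSV
#'
#' Columns `depletion_set`, `context`, `mu_max`, `essential`, sorted by
#' depletion set for deterministic output.
#'
#' @param records Scan data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_essentiality_tsv <- function(records, path) {
  df <- records[order(records$context, records$depletion_set),
                c("depletion_set", "context", "mu_max", "essential")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
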