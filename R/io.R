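#' Model JSON dialect
#'
#' ME models serialize to a versioned JSON document: compartments,
#' species, genes, transcription units, complexes, reactions (with
#' stoichiometric coefficients as numbers or mu-expression strings),
#' the objective, and — for two-cell models — a provenance block with
#' the channel registry and built-in depletions. The round trip is
#' lossless: reading back a written model reproduces the same LP at any
#' growth rate, and re-serialization is byte-identical.
#'
#' @param model An `me_model` or `two_cell_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  rx_to_json <- function(rx) {
    st <- lapply(rx$stoich, coef_to_json)
    out <- list(id = rx$id, type = rx$type, stoich = st,
                lb = if (is.finite(rx$lb)) rx$lb else -model$inf_bound,
                ub = if (is.finite(rx$ub)) rx$ub else model$inf_bound)
    if (!is.null(rx$catalyst)) {
      out$catalyst <- rx$catalyst
      out$k_eff <- rx$k_eff
    }
    out
  }
  doc <- list(
    format_version = "1.0",
    id = model$id,
    compartments = as.list(model$compartments),
    inf_bound = model$inf_bound,
    species = lapply(seq_len(nrow(model$species)), function(i)
      as.list(model$species[i, ])),
    genes = lapply(model$genes, function(g)
      list(id = g$id, peptide = g$peptide, length = g$length,
           composition = as.list(g$composition))),
    transcription_units = lapply(model$transcription_units, function(tu)
      list(id = tu$id, genes = as.list(tu$genes), sigma = tu$sigma)),
    complexes = lapply(model$complexes, function(cx)
      list(id = cx$id, subunits = as.list(cx$subunits))),
    reactions = lapply(model$reactions, rx_to_json),
    objective = model$objective
  )
  if (inherits(model, "two_cell_model")) {
    doc$two_cell <- list(
      provenance = model$provenance,
      channel_complex = model$channel_complex,
      channel_reactions = as.list(model$channel_reactions),
      builtin_depletions = as.list(model$builtin_depletions)
    )
  }
  if (!is.null(model$meta)) {
    meta <- model$meta
    ## named atomic vectors must become lists to keep their names in JSON
    meta$sigma_genes <- as.list(meta$sigma_genes)
    meta$species_classes <- lapply(meta$species_classes, as.list)
    meta$channel$mc_genes <- as.list(meta$channel$mc_genes)
    meta$builtin_fs_depletions <- as.list(meta$builtin_fs_depletions)
    doc$meta <- meta
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a model from its JSON document
#'
#' Unknown top-level fields are rejected; mu-expression strings are
#' re-parsed through the coefficient grammar.
#'
#' @param path Path to a model JSON file.
#' @return An `me_model` (or `two_cell_model`).
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  known <- c("format_version", "id", "compartments", "inf_bound", "species",
             "genes", "transcription_units", "complexes", "reactions",
             "objective", "two_cell", "meta")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    stop("unknown top-level field(s) in model document: ",
         paste(extra, collapse = ", "))
  if (is.null(doc$format_version) || doc$format_version != "1.0")
    stop("unsupported or missing format_version (expected \"1.0\")")
  if (is.null(doc$objective))
    stop("model document has no objective")
  m <- me_model(doc$id, unlist(doc$compartments), inf_bound = doc$inf_bound)
  for (sp in doc$species)
    m <- add_species(m, sp$id, sp$compartment, sp$category)
  for (g in doc$genes)
    m <- add_gene(m, g$id, g$peptide, g$length,
                  unlist(g$composition))
  for (tu in doc$transcription_units)
    m <- add_transcription_unit(m, tu$id, unlist(tu$genes), tu$sigma)
  for (cx in doc$complexes)
    m$complexes[[cx$id]] <- list(id = cx$id, subunits = unlist(cx$subunits))
  for (rx in doc$reactions) {
    r <- me_reaction(rx$id, rx$type, rx$stoich, rx$lb, rx$ub,
                     catalyst = rx$catalyst, k_eff = rx$k_eff)
    m <- add_reaction(m, r)
  }
  m <- set_objective(m, doc$objective)
  if (!is.null(doc$two_cell)) {
    class(m) <- c("two_cell_model", class(m))
    prov <- doc$two_cell$provenance
    m$provenance <- data.frame(orig = vapply(prov, `[[`, "", "orig"),
                               mc = vapply(prov, `[[`, "", "mc"),
                               fs = vapply(prov, `[[`, "", "fs"),
                               stringsAsFactors = FALSE)
    m$channel_complex <- doc$two_cell$channel_complex
    m$channel_reactions <- unlist(doc$two_cell$channel_reactions)
    m$builtin_depletions <- unlist(doc$two_cell$builtin_depletions)
    if (is.null(m$builtin_depletions)) m$builtin_depletions <- character(0)
  }
  if (!is.null(doc$meta)) {
    meta <- doc$meta
    meta$species_classes <- lapply(meta$species_classes, unlist)
    meta$sigma_genes <- unlist(meta$sigma_genes)
    meta$channel$mc_genes <- unlist(meta$channel$mc_genes)
    meta$builtin_fs_depletions <- unlist(meta$builtin_fs_depletions)
    m$meta <- meta
  }
  m
}

#' MD5 of a model's serialized form
#'
#' Convenience for determinism checks (same config, same seed, same
#' bytes).
#'
#' @param model An `me_model`.
#' @return MD5 string.
#' @export
model_digest <- function(model) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_model_json(model, tf)
  unname(tools::md5sum(tf))
}

#' Write a flux vector as a TSV table
#'
#' @param fluxes Named flux vector.
#' @param path Output path.
#' @param tol Entries with |flux| below this are dropped.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(fluxes, path, tol = 0) {
  df <- data.frame(reaction = names(fluxes), flux = unname(fluxes),
                   stringsAsFactors = FALSE)
  if (tol > 0) df <- df[abs(df$flux) > tol, ]
  df <- df[order(df$reaction), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
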