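#' Analytic micromodel with closed-form maximal growth rate
#'
#' A minimal growth-coupled model used to validate the solver: one
#' metabolite M, a capped uptake catalyzed by an enzyme E with usage
#' coupling `-mu/k_eff`, enzyme formation M -> E, and biomass M -> 0.
#' At steady state the uptake flux is `mu k/(k - mu)`, so the uptake cap
#' binds at `mu_max = cap k/(cap + k)`.
#'
#' @param k_eff Effective catalytic rate of the uptake enzyme (h^-1), > 0.
#' @param uptake_cap Upper bound on the uptake flux (mmol/gDW/h), >= 0.
#' @return An `me_model` with objective `biomass`.
#' @export
make_analytic_micromodel <- function(k_eff = 1, uptake_cap = 10) {
  stopifnot(k_eff > 0, uptake_cap >= 0)
  m <- me_model("micromodel", c("c", "e"))
  m <- add_species(m, c("M_c", "E_c"), "c", c("metabolite", "protein"))
  m <- add_reaction(m, me_reaction("uptake", "transport", list(M_c = 1),
                                   0, uptake_cap, catalyst = "E_c", k_eff = k_eff))
  m <- add_reaction(m, me_reaction("biomass", "biomass", list(M_c = -1), 0, Inf))
  m <- add_reaction(m, me_reaction("formation_E", "complex_formation",
                                   list(M_c = -1, E_c = 1), 0, Inf))
  set_objective(m, "biomass")
}

#' Closed-form maximal growth rate of the analytic micromodel
#' @param k_eff,uptake_cap As in [make_analytic_micromodel()].
#' @return `uptake_cap * k_eff / (uptake_cap + k_eff)`.
#' @export
micromodel_mu_max <- function(k_eff, uptake_cap) {
  uptake_cap * k_eff / (uptake_cap + k_eff)
}

#' Configuration for the toy sporulation ME model
#'
#' The generator is deterministic: the same configuration (and seed, when
#' `keff_jitter > 0`) yields a byte-identical serialized model.
#'
#' @param k_eff Default effective catalytic rate for metabolic and
#'   transport enzymes (h^-1).
#' @param k_channel Effective rate of the Q-A channel complex (h^-1).
#' @param k_trx,k_rib,k_mRNA Machinery coupling rates (h^-1).
#' @param atp_per_residue ATP cost per residue translated.
#' @param glu_uptake Glutamate uptake bound magnitude (mmol/gDW/h).
#' @param inf_bound Finite sentinel for open bounds.
#' @param keff_jitter Relative lognormal jitter applied to enzyme k_eff
#'   values (0 disables; uses `seed`).
#' @param seed Integer seed for the jitter.
#' @return A named list of class `toy_config`.
#' @export
toy_config <- function(k_eff = 65, k_channel = 12, k_trx = 50, k_rib = 50,
                       k_mRNA = 25, atp_per_residue = 2, glu_uptake = 2,
                       inf_bound = 1000, keff_jitter = 0, seed = 1L) {
  stopifnot(k_eff > 0, k_channel > 0, k_trx > 0, k_rib > 0, k_mRNA > 0,
            glu_uptake >= 0, keff_jitter >= 0)
  structure(list(k_eff = k_eff, k_channel = k_channel, k_trx = k_trx,
                 k_rib = k_rib, k_mRNA = k_mRNA,
                 atp_per_residue = atp_per_residue, glu_uptake = glu_uptake,
                 inf_bound = inf_bound, keff_jitter = keff_jitter,
                 seed = as.integer(seed)), class = "toy_config")
}

## gene roster: composition counts are residues per peptide
toy_gene_table <- function() {
  enz <- c(ala = 2, glu = 2, asp = 2, thr = 2, ile = 1, met = 1)
  ssp <- c(ala = 24, glu = 22, asp = 21, thr = 20, val = 1, ile = 5, met = 4)
  spo <- c(ala = 4, glu = 3, asp = 2, thr = 1, val = 1, ile = 1, met = 1)
  genes <- list()
  add <- function(ids, comp = enz, len = 120) {
    for (g in ids) genes[[g]] <<- list(comp = comp, len = len)
  }
  add(c("rpoB", "rpsA", "sigA", "sigE", "sigF", "sigK"), enz, 240)
  add(c("rocG", "odhA", "pdhA", "pdhD", "sucC", "sucD", "sdhA", "citG",
        "mdh", "citZ", "citB", "icd"))
  add(c("pycA", "pckA", "eno", "pgm", "pgk", "gapA", "gapB", "tpiA",
        "fbaA", "fbp", "pfkA", "pyk", "lctE"))
  add(c("ilvA", "ilvC", "ilvD", "bcaT", "alsS", "alsD"))
  add(c("alaT", "aspB", "thrC", "metE"))
  add(c("purF", "purB", "guaB", "pyrB", "cmpA", "pyrH", "pyrG",
        "adk", "gmk", "cmk", "ndk"))
  add(c("atpA", "murAA"))
  add(c("gltT", "fruA", "mctC", "citM", "aapA", "nupC"))
  add("sspA", ssp, 300)
  add(c("spoIIQ", paste0("spoIIIA", LETTERS[1:8])), spo, 350)
  genes
}

## transcription units: list(genes, sigma)
toy_tu_table <- function() {
  list(
    TU_rpoB = list(genes = "rpoB", sigma = "sigA"),
    TU_rpsA = list(genes = "rpsA", sigma = "sigA"),
    TU_sigA = list(genes = "sigA", sigma = "sigA"),
    TU_sigE = list(genes = "sigE", sigma = "sigA"),
    TU_sigF = list(genes = "sigF", sigma = "sigA"),
    TU_sigK = list(genes = "sigK", sigma = "sigA"),
    TU_tca1 = list(genes = c("rocG", "odhA", "pdhA", "pdhD"), sigma = "sigA"),
    TU_tca2 = list(genes = c("sucC", "sucD", "sdhA", "citG", "mdh"), sigma = "sigA"),
    TU_tca3 = list(genes = c("citZ", "citB", "icd"), sigma = "sigA"),
    TU_gly1 = list(genes = c("pycA", "pckA", "eno", "pgm", "pgk"), sigma = "sigA"),
    TU_gly2 = list(genes = c("gapA", "gapB", "tpiA", "fbaA"), sigma = "sigA"),
    TU_gly3 = list(genes = c("fbp", "pfkA", "pyk", "lctE"), sigma = "sigA"),
    TU_ilv = list(genes = c("ilvA", "ilvC", "ilvD", "bcaT"), sigma = "sigA"),
    TU_als = list(genes = c("alsS", "alsD"), sigma = "sigA"),
    TU_aa1 = list(genes = c("alaT", "aspB", "thrC", "metE"), sigma = "sigA"),
    TU_nuc1 = list(genes = c("purF", "purB", "guaB"), sigma = "sigA"),
    TU_nuc2 = list(genes = c("pyrB", "cmpA", "pyrH", "pyrG"), sigma = "sigA"),
    TU_kin = list(genes = c("adk", "gmk", "cmk", "ndk"), sigma = "sigA"),
    TU_atp = list(genes = "atpA", sigma = "sigA"),
    TU_mur = list(genes = "murAA", sigma = "sigK"),
    TU_trans1 = list(genes = c("gltT", "fruA", "mctC"), sigma = "sigA"),
    TU_trans2 = list(genes = c("citM", "aapA", "nupC"), sigma = "sigA"),
    TU_sspA = list(genes = "sspA", sigma = "sigA"),
    TU_spoIIQ = list(genes = "spoIIQ", sigma = "sigF"),
    TU_spoIIIA = list(genes = paste0("spoIIIA", LETTERS[1:8]), sigma = "sigE")
  )
}

## channel-transportable species classes (base metabolite names)
toy_species_classes <- function() {
  list(sugars = "f6p",
       organic_acids = c("pyr", "lac", "actn", "succ", "cit"),
       amino_acids = c("glu", "ala", "asp", "met", "val", "ile"),
       nmp = c("amp", "gmp", "ump", "cmp"),
       ndp = c("gdp", "udp", "cdp"),
       ntp = c("gtp", "utp", "ctp"),
       atp = c("atp", "adp"))
}

#' Generate the toy single-cell sporulation ME model
#'
#' A compact single-cell ME model of B. subtilis central metabolism and
#' gene expression on glutamate minimal medium, emulating the pathway
#' motifs relevant to sporulation modeling: glutamate entry and AKG
#' oxidation (RocG, OdhAB-PdhD, SucCD), lower TCA to oxaloacetate, the
#' citrate/Icd NADPH route, the gluconeogenesis/glycolysis shuttle
#' enzymes (PycA, PckA, Eno, Pgm, Pgk, GapA/GapB, TpiA, FbaA, Fbp, PfkA,
#' Pyk) with lactate (LctE) as NADH overflow, lumped oxidative
#' phosphorylation (F1FO), nucleotide synthesis and the kinase ladder
#' (Adk, Gmk, Cmk, PyrH, Ndk, PyrG), amino-acid biosynthesis including
#' the IlvA/IlvC/IlvD/AlsS branched-chain motif with the AlsD acetoin
#' escape, sigma-factor-specific transcription units, the Q-A channel
#' genes (spoIIQ under sigma-F, the eight spoIIIA subunits under
#' sigma-E), peptidoglycan precursor synthesis under sigma-K, and c<->e
#' transport templates for sugars, organic acids, amino acids and
#' nucleotides (the fructose-6-phosphate importer is
#' phosphotransferase-style, paying PEP on the receiving side).
#'
#' @param config A [toy_config()].
#' @return An `me_model` with compartments c and e and objective
#'   `biomass`; `model$meta` records species classes, sigma roles and
#'   transporter templates for the two-cell build.
#' @export
generate_toy_sporulation_model <- function(config = toy_config()) {
  stopifnot(inherits(config, "toy_config"))
  m <- me_model("toy_sporulation", c("c", "e"), inf_bound = config$inf_bound)

  mets_c <- c("glu", "akg", "succoa", "succ", "fum", "mal", "oaa", "cit",
              "icit", "accoa", "pyr", "lac", "actn", "pep", "p2g", "p3g",
              "bpg13", "g3p", "dhap", "fdp", "f6p", "alac", "ahb", "dhiv",
              "dhmb", "kiv", "kmv", "kb2", "ala", "asp", "thr", "met",
              "val", "ile", "nad", "nadh", "nadp", "nadph", "atp", "adp",
              "amp", "imp", "gmp", "gdp", "gtp", "ump", "udp", "utp",
              "cmp", "cdp", "ctp", "wallp")
  m <- add_species(m, paste0(mets_c, "_c"), "c", "metabolite")
  classes <- toy_species_classes()
  transportable <- unlist(classes, use.names = FALSE)
  m <- add_species(m, paste0(transportable, "_e"), "e", "metabolite")

  genes <- toy_gene_table()
  for (g in names(genes))
    m <- add_gene(m, g, paste0("protein_", g),
                  length = genes[[g]]$len,
                  composition = stats::setNames(genes[[g]]$comp,
                                                paste0(names(genes[[g]]$comp), "_c")))
  m <- add_species(m, paste0("protein_", names(genes)), "c", "protein")

  tus <- toy_tu_table()
  for (tu in names(tus))
    m <- add_transcription_unit(m, tu, tus[[tu]]$genes,
                                paste0("protein_", tus[[tu]]$sigma))

  ## machinery complexes
  for (sg in c("sigA", "sigE", "sigF", "sigK")) {
    cid <- paste0("RNAP_", sg)
    m <- add_complex(m, cid, stats::setNames(c(1, 1),
                                             paste0("protein_", c("rpoB", sg))))
    m <- add_complex_formation(m, cid, "c", "machinery")
  }
  m <- add_complex(m, "ribosome", c(protein_rpsA = 1))
  m <- add_complex_formation(m, "ribosome", "c", "machinery")
  m <- add_complex(m, "cplx_PDH", c(protein_pdhA = 1, protein_pdhD = 1))
  m <- add_complex_formation(m, "cplx_PDH")
  m <- add_complex(m, "cplx_ODH", c(protein_odhA = 1, protein_pdhD = 1))
  m <- add_complex_formation(m, "cplx_ODH")
  m <- add_complex(m, "cplx_SucCD", c(protein_sucC = 1, protein_sucD = 1))
  m <- add_complex_formation(m, "cplx_SucCD")

  ## expression reactions
  params <- machinery_params(k_trx = config$k_trx, k_rib = config$k_rib,
                             k_mRNA = config$k_mRNA,
                             atp_per_residue = config$atp_per_residue)
  for (tu in names(tus))
    m <- build_expression_reactions(m, tu, params,
                                    holoenzyme = paste0("RNAP_", tus[[tu]]$sigma))

  ## enzyme k_eff (optionally jittered, deterministically from the seed)
  kf <- function(gene) {
    if (config$keff_jitter <= 0) return(config$k_eff)
    h <- sum(utf8ToInt(gene)) + config$seed
    set.seed(h %% .Machine$integer.max)
    config$k_eff * exp(stats::rnorm(1, 0, config$keff_jitter))
  }
  cat_of <- function(gene) paste0("protein_", gene)
  ## catalyzed reactions are irreversible by ME convention (a backward flux
  ## would produce its own enzyme through the usage coupling); reversible
  ## chemistry is encoded as a forward/reverse pair sharing the catalyst
  mrx <- function(id, stoich, cat, reversible = FALSE, type = "metabolic",
                  k = NULL) {
    st <- stats::setNames(as.list(stoich), paste0(names(stoich), "_c"))
    keff <- if (is.null(k)) kf(id) else k
    out <- list(me_reaction(id, type, st, 0, Inf, catalyst = cat, k_eff = keff))
    if (reversible) {
      out[[2]] <- me_reaction(paste0(id, "_rev"), type,
                              lapply(st, function(v) -v), 0, Inf,
                              catalyst = cat, k_eff = keff)
    }
    out
  }

  rxns <- list(
    ## carbon entry, TCA, energy
    mrx("rocG", c(glu = -1, nad = -1, akg = 1, nadh = 1), cat_of("rocG")),
    mrx("odh", c(akg = -1, nad = -1, succoa = 1, nadh = 1), "cplx_ODH"),
    mrx("pdh", c(pyr = -1, nad = -1, accoa = 1, nadh = 1), "cplx_PDH"),
    mrx("sucCD", c(succoa = -1, adp = -1, succ = 1, atp = 1), "cplx_SucCD"),
    mrx("sdhA", c(succ = -1, fum = 1), cat_of("sdhA")),
    mrx("citG", c(fum = -1, mal = 1), cat_of("citG")),
    mrx("mdh", c(mal = -1, nad = -1, oaa = 1, nadh = 1), cat_of("mdh")),
    mrx("citZ", c(oaa = -1, accoa = -1, cit = 1), cat_of("citZ")),
    mrx("citB", c(cit = -1, icit = 1), cat_of("citB")),
    mrx("icd", c(icit = -1, nadp = -1, akg = 1, nadph = 1), cat_of("icd")),
    mrx("pycA", c(pyr = -1, atp = -1, oaa = 1, adp = 1), cat_of("pycA")),
    mrx("pckA", c(oaa = -1, atp = -1, pep = 1, adp = 1), cat_of("pckA")),
    mrx("oxphos", c(nadh = -1, adp = -1, nad = 1, atp = 1), cat_of("atpA")),
    mrx("lctE", c(pyr = -1, nadh = -1, lac = 1, nad = 1), cat_of("lctE"),
        reversible = TRUE),
    ## glycolysis / gluconeogenesis
    mrx("pgk", c(bpg13 = -1, adp = -1, p3g = 1, atp = 1), cat_of("pgk"),
        reversible = TRUE),
    mrx("pgm", c(p3g = -1, p2g = 1), cat_of("pgm"), reversible = TRUE),
    mrx("eno", c(p2g = -1, pep = 1), cat_of("eno"), reversible = TRUE),
    mrx("gapA", c(g3p = -1, nad = -1, bpg13 = 1, nadh = 1), cat_of("gapA")),
    mrx("gapB", c(bpg13 = -1, nadph = -1, g3p = 1, nadp = 1), cat_of("gapB")),
    mrx("tpiA", c(dhap = -1, g3p = 1), cat_of("tpiA"), reversible = TRUE),
    mrx("fbaA", c(dhap = -1, g3p = -1, fdp = 1), cat_of("fbaA"),
        reversible = TRUE),
    mrx("fbp", c(fdp = -1, f6p = 1), cat_of("fbp")),
    mrx("pfkA", c(f6p = -1, atp = -1, fdp = 1, adp = 1), cat_of("pfkA")),
    mrx("pyk", c(pep = -1, adp = -1, pyr = 1, atp = 1), cat_of("pyk")),
    ## amino acids
    mrx("alaT", c(pyr = -1, glu = -1, ala = 1, akg = 1), cat_of("alaT")),
    mrx("aspB", c(oaa = -1, glu = -1, asp = 1, akg = 1), cat_of("aspB")),
    mrx("thrC", c(asp = -1, nadh = -1, thr = 1, nad = 1), cat_of("thrC")),
    mrx("metE", c(asp = -1, atp = -1, nadph = -1, met = 1, adp = 1, nadp = 1),
        cat_of("metE")),
    mrx("ilvA", c(thr = -1, kb2 = 1), cat_of("ilvA")),
    mrx("alsS_als", c(pyr = -2, alac = 1), cat_of("alsS")),
    mrx("alsS_ahb", c(pyr = -1, kb2 = -1, ahb = 1), cat_of("alsS")),
    mrx("alsD", c(alac = -1, actn = 1), cat_of("alsD")),
    ## reductoisomerase modeled NADH-dependent at toy scale: the branch
    ## then draws on overflow reducing power rather than the NADPH pool
    mrx("ilvC_val", c(alac = -1, nadh = -1, dhiv = 1, nad = 1), cat_of("ilvC")),
    mrx("ilvC_ile", c(ahb = -1, nadh = -1, dhmb = 1, nad = 1), cat_of("ilvC")),
    mrx("ilvD_val", c(dhiv = -1, kiv = 1), cat_of("ilvD")),
    mrx("ilvD_ile", c(dhmb = -1, kmv = 1), cat_of("ilvD")),
    mrx("bcaT_val", c(kiv = -1, glu = -1, val = 1, akg = 1), cat_of("bcaT")),
    mrx("bcaT_ile", c(kmv = -1, glu = -1, ile = 1, akg = 1), cat_of("bcaT")),
    ## nucleotides
    mrx("imp_syn", c(f6p = -1, glu = -1, atp = -2, imp = 1, adp = 2, akg = 1),
        cat_of("purF")),
    mrx("purB", c(imp = -1, asp = -1, amp = 1, fum = 1), cat_of("purB")),
    mrx("guaB", c(imp = -1, nad = -1, atp = -1, gmp = 1, nadh = 1, adp = 1),
        cat_of("guaB")),
    mrx("ump_syn", c(asp = -1, f6p = -1, atp = -2, ump = 1, adp = 2),
        cat_of("pyrB")),
    mrx("cmp_syn", c(ump = -1, glu = -1, cmp = 1, akg = 1), cat_of("cmpA")),
    mrx("adk", c(amp = -1, atp = -1, adp = 2), cat_of("adk")),
    mrx("gmk", c(gmp = -1, atp = -1, gdp = 1, adp = 1), cat_of("gmk")),
    mrx("cmk_cmp", c(cmp = -1, atp = -1, cdp = 1, adp = 1), cat_of("cmk")),
    mrx("cmk_ump", c(ump = -1, atp = -1, udp = 1, adp = 1), cat_of("cmk")),
    mrx("pyrH", c(ump = -1, atp = -1, udp = 1, adp = 1), cat_of("pyrH")),
    mrx("ndk_gdp", c(gdp = -1, atp = -1, gtp = 1, adp = 1), cat_of("ndk")),
    mrx("ndk_udp", c(udp = -1, atp = -1, utp = 1, adp = 1), cat_of("ndk")),
    mrx("ndk_cdp", c(cdp = -1, atp = -1, ctp = 1, adp = 1), cat_of("ndk")),
    mrx("pyrG", c(utp = -1, atp = -1, glu = -1, ctp = 1, adp = 1, akg = 1),
        cat_of("pyrG")),
    ## cell wall precursor (sigma-K regulated enzyme)
    mrx("murAA", c(f6p = -1, atp = -2, glu = -1, wallp = 1, adp = 2, akg = 1),
        cat_of("murAA"))
  )
  for (rx in rxns) for (r in rx) m <- add_reaction(m, r)

  ## transport templates c<->e and exchanges; reversible carriers become
  ## import/export pairs sharing the transporter, as for enzymes above
  trx <- function(id, stoich, cat, reversible = FALSE) {
    keff <- kf(id)
    out <- list(me_reaction(id, "transport", stoich, 0, Inf,
                            catalyst = cat, k_eff = keff))
    if (reversible) {
      out[[2]] <- me_reaction(paste0(id, "_rev"), "transport",
                              lapply(stoich, function(v) -v), 0, Inf,
                              catalyst = cat, k_eff = keff)
    }
    out
  }
  tlist <- list(
    trx("t_glu", list(glu_e = -1, glu_c = 1), cat_of("gltT")),
    trx("t_f6p", list(f6p_e = -1, pep_c = -1, f6p_c = 1, pyr_c = 1),
        cat_of("fruA"))
  )
  ## organic-acid and citrate-family carriers are reversible; amino-acid
  ## permeases are concentrative importers (no efflux)
  carriers <- c(pyr = "mctC", lac = "mctC", actn = "mctC", succ = "mctC",
                cit = "citM",
                ala = "aapA", asp = "aapA", met = "aapA",
                val = "aapA", ile = "aapA")
  for (sp in names(carriers))
    tlist[[length(tlist) + 1L]] <-
      trx(paste0("t_", sp),
          stats::setNames(list(-1, 1), paste0(sp, c("_e", "_c"))),
          cat_of(carriers[[sp]]),
          reversible = carriers[[sp]] %in% c("mctC", "citM"))
  ## G/C/U nucleotide carriers are concentrative importers (no efflux);
  ## the adenine pair moves by translocase-style exchange and is
  ## reversible, so ATP import can cycle against ADP return
  nucs <- c(classes$nmp, classes$ndp, classes$ntp, classes$atp)
  for (sp in nucs)
    tlist[[length(tlist) + 1L]] <-
      trx(paste0("t_", sp),
          stats::setNames(list(-1, 1), paste0(sp, c("_e", "_c"))),
          cat_of("nupC"), reversible = sp %in% c("atp", "adp"))
  for (rx in tlist) for (r in rx) m <- add_reaction(m, r)
  for (sp in transportable)
    m <- add_reaction(m, me_reaction(paste0("EX_", sp, "_e"), "exchange",
                                     stats::setNames(list(-1), paste0(sp, "_e")),
                                     0, Inf))

  ## biomass: structural protein, wall precursor, NTP precursors, ATP cost
  m <- add_reaction(m, me_reaction(
    "biomass", "biomass",
    list(protein_sspA = -0.022, wallp_c = -0.22,
         gtp_c = -0.07, ctp_c = -0.045, utp_c = -0.045,
         atp_c = -2.37, adp_c = 2.3),
    0, Inf))
  m <- set_objective(m, "biomass")

  m$meta <- list(
    species_classes = classes,
    sigma_genes = c(housekeeping = "sigA", mother_cell_early = "sigE",
                    forespore = "sigF", mother_cell_late = "sigK"),
    channel = list(mc_genes = paste0("spoIIIA", LETTERS[1:8]),
                   fs_gene = "spoIIQ", k_eff = config$k_channel),
    builtin_fs_depletions = c("pckA", "citZ", "metE", "aspB", "rocG", "alaT"),
    fs_atp_synthase_gene = "atpA",
    glu_exchange = "EX_glu_e",
    glu_uptake = config$glu_uptake,
    config = unclass(config)
  )
  m
}

#' Glutamate minimal medium for the toy model
#'
#' @param model A toy model (single- or two-cell).
#' @param uptake Glutamate uptake bound magnitude (mmol/gDW/h); the
#'   exchange lower bound is set to `-uptake`.
#' @return A medium spec usable with [configure_medium()].
#' @export
toy_glutamate_medium <- function(model, uptake = model$meta$glu_uptake) {
  list(EX_glu_e = c(lb = -uptake, ub = model$inf_bound))
}
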