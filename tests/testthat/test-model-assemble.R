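test_that("validate_model reports dangling references and duplicate ids", {
  m <- me_model()
  m <- add_species(m, "a_c", "c")
  m <- add_reaction(m, me_reaction("r1", "metabolic", list(a_c = -1, ghost_c = 1)))
  v <- validate_model(m)
  expect_true("dangling_reference" %in% v$code)
  expect_error(add_reaction(m, me_reaction("r1", "metabolic", list(a_c = 1))),
               "duplicate")
  expect_true("objective" %in% v$code)  # none set yet
})

test_that("validate_model flags coefficient poles on the search interval", {
  m <- me_model()
  m <- add_species(m, "a_c", "c")
  m <- add_reaction(m, me_reaction("r", "metabolic",
                                   list(a_c = parse_mu_expression("1/(mu - 0.5)"))))
  m <- add_reaction(m, me_reaction("bio", "biomass", list(a_c = -1)))
  m <- set_objective(m, "bio")
  v <- validate_model(m, mu_hi = 2)
  expect_true("pole" %in% v$code)
})

test_that("the generated toy model validates cleanly", {
  expect_equal(nrow(validate_model(toy_single())), 0)
})

test_that("assembly is pure and evaluates couplings as -mu/k_eff", {
  m <- make_analytic_micromodel(k_eff = 2, uptake_cap = 10)
  lp1 <- assemble_lp(m, 0.5)
  lp2 <- assemble_lp(m, 0.5)
  expect_identical(as.matrix(lp1$A), as.matrix(lp2$A))
  expect_identical(lp1$lb, lp2$lb)
  i <- match("E_c", lp1$row_ids); j <- match("uptake", lp1$col_ids)
  expect_equal(lp1$A[i, j], -0.5 / 2)
  lp0 <- assemble_lp(m, 0)
  expect_equal(lp0$A[i, j], 0)  # no machinery demand at zero growth
})

test_that("LP dimensions equal species x reactions and biomass lb tracks mu", {
  m <- make_analytic_micromodel()
  lp <- assemble_lp(m, 0.3)
  expect_equal(dim(lp$A), c(nrow(m$species), length(m$reactions)))
  expect_equal(lp$lb[match("biomass", lp$col_ids)], 0.3)
})

test_that("expression reactions follow naming and composition contracts", {
  m <- me_model()
  m <- add_species(m, c("ala_c", "atp_c", "adp_c", "gtp_c", "ctp_c", "utp_c"),
                   "c")
  m <- add_species(m, c("RNAPtest", "ribosome"), "c", "machinery")
  m <- add_gene(m, "BSU00001", "protein_BSU00001", 300, c(ala_c = 10))
  m <- add_transcription_unit(m, "TU1", "BSU00001", "sigA")
  m <- build_expression_reactions(m, "TU1", machinery_params(),
                                  holoenzyme = "RNAPtest")
  expect_true(all(c("transcription_TU1", "translation_BSU00001") %in%
                    names(m$reactions)))
  tr <- m$reactions[["translation_BSU00001"]]
  expect_equal(tr$stoich[["ala_c"]], -10)
  expect_s3_class(tr$stoich[["mRNA_TU1"]], "mu_expr")
  expect_error(build_expression_reactions(m, "TU1", machinery_params(),
                                          holoenzyme = "missing"),
               "missing machinery")
})
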