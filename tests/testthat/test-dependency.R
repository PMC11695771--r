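test_that("activity is summed translation flux with a strict threshold", {
  v <- c(translation_gapA_FS = 3e-4, translation_metE_FS = 0)
  two <- toy_two_default()
  a <- protein_activity(v, two, "gapA", "forespore")
  expect_true(a$active)
  expect_equal(a$t_A, 3e-4)
  b <- protein_activity(v, two, "metE", "forespore")
  expect_false(b$active)
  ## threshold edge: exactly eps_act is inactive (strict inequality)
  opts <- dependency_options(eps_act = 3e-4)
  expect_false(protein_activity(v, two, "gapA", "forespore", opts)$active)
})

test_that("the naive model reopens exactly the built-in depletions", {
  two <- toy_two_default()
  naive <- build_naive_model(two)
  expect_setequal(naive$naive_reopened,
                  union(toy_single()$meta$builtin_fs_depletions, "atpA"))
  for (p in naive$naive_reopened)
    expect_gt(naive$reactions[[paste0("translation_", p, "_FS")]]$ub, 0)
  ## relaxation: naive growth is at least the constrained growth
  r_con <- maximize_growth(two)
  r_nai <- maximize_growth(naive)
  expect_gte(r_nai$mu_max, r_con$mu_max - 1e-6)
  ## re-closing reproduces the constrained optimum
  reclosed <- apply_depletions(naive, depletion_spec(naive$naive_reopened,
                                                     "forespore"))
  r_rec <- maximize_growth(reclosed)
  expect_equal(r_rec$mu_max, r_con$mu_max, tolerance = 1e-5)
})

test_that("wild-type-inactive proteins are never classified as dependents", {
  da <- ilvc_analysis()
  expect_true(all(da$records$affected_protein %in% da$wild_type$active))
  expect_false("ilvC" %in% da$records$affected_protein)
  expect_true(all(da$records$t_wt > dependency_options()$eps_act))
})

test_that("blockage with an empty candidate list returns an empty frame", {
  bt <- blockage_test(toy_two_shuttle(), "ilvC", character(0),
                      cell = "forespore", mu = 0.01)
  expect_equal(nrow(bt), 0)
})

test_that("blocked is a subset of inactive for the IlvC depletion", {
  rec <- ilvc_analysis()$records
  ## every blocked protein was first flagged inactive by the scan
  expect_true(all(rec$classification %in% c("blocked", "inactive")))
  blocked <- rec$affected_protein[rec$classification == "blocked"]
  expect_true(all(blocked %in% rec$affected_protein))
  ## sinks of blocked proteins carry no flux; inactive ones fill the bound
  opts <- dependency_options()
  expect_true(all(rec$sink_flux[rec$classification == "blocked"] <
                    opts$blocked_frac * opts$sink_bound))
  expect_true(all(rec$sink_flux[rec$classification == "inactive"] >=
                    opts$blocked_frac * opts$sink_bound))
})

test_that("dependency TSV output has the documented shape", {
  rec <- data.frame(depleted_protein = "x", affected_protein = c("b", "a"),
                    classification = c("blocked", "inactive"),
                    stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  write_dependency_tsv(rec, tf)
  back <- utils::read.delim(tf)
  expect_equal(names(back),
               c("depleted_protein", "affected_protein", "classification"))
  expect_equal(back$affected_protein, c("a", "b"))
})
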