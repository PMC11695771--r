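test_that("duplication bookkeeping identity and naming conventions hold", {
  single <- toy_single()
  two <- duplicate_into_two_cells(single, toy_channel_spec(single))
  n_ex <- sum(vapply(single$reactions, function(r) r$type == "exchange", TRUE))
  n_r <- length(single$reactions) - n_ex
  n_channel <- length(two$channel_reactions)
  ## + 1 channel assembly (QA complex formation)
  expect_equal(length(two$reactions), 2 * n_r + n_ex + n_channel + 1)
  expect_true("atp_s" %in% two$species$id)   # c -> s relabel
  expect_true("atp_c" %in% two$species$id)
  expect_true(all(c("gapA_MC", "gapA_FS") %in% names(two$reactions)))
  expect_identical(two$objective, "biomass_FS")
})

test_that("forespore copies of membrane transport to e are closed", {
  two <- toy_two_default()
  expect_equal(two$reactions[["t_glu_FS"]]$ub, 0)
  expect_gt(two$reactions[["t_glu_MC"]]$ub, 0)
})

test_that("sigma partitioning closes the right transcription copies", {
  two <- toy_two_default()
  expect_equal(two$reactions[["transcription_TU_spoIIIA_FS"]]$ub, 0)  # sigma-E
  expect_gt(two$reactions[["transcription_TU_spoIIIA_MC"]]$ub, 0)
  expect_equal(two$reactions[["transcription_TU_spoIIQ_MC"]]$ub, 0)  # sigma-F
  expect_gt(two$reactions[["transcription_TU_spoIIQ_FS"]]$ub, 0)
  expect_equal(two$reactions[["transcription_TU_mur_FS"]]$ub, 0)     # sigma-K
  expect_true("integration_wallp" %in% names(two$reactions))
})

test_that("apply_depletions touches exactly the targeted translation bounds", {
  two <- toy_two_default()
  dep <- apply_depletions(two, depletion_spec("gmk", "forespore"))
  expect_equal(dep$reactions[["translation_gmk_FS"]]$ub, 0)
  expect_gt(dep$reactions[["translation_gmk_MC"]]$ub, 0)
  others <- setdiff(names(two$reactions), "translation_gmk_FS")
  same <- vapply(others, function(id)
    identical(two$reactions[[id]]$ub, dep$reactions[[id]]$ub) &&
      identical(two$reactions[[id]]$lb, dep$reactions[[id]]$lb), TRUE)
  expect_true(all(same))
  expect_error(apply_depletions(two, depletion_spec("nosuch", "forespore")),
               "no translation reaction")
})

test_that("configure_medium opens listed uptakes and closes the rest", {
  single <- toy_single()
  veg <- configure_medium(single, toy_glutamate_medium(single, uptake = 2))
  expect_equal(veg$reactions[["EX_glu_e"]]$lb, -2)
  expect_equal(veg$reactions[["EX_gmp_e"]]$lb, 0)
  expect_gt(veg$reactions[["EX_lac_e"]]$ub, 0)  # secretion stays open
  expect_error(configure_medium(single, list(EX_nope_e = c(-1, 0))),
               "unknown exchange")
})

test_that("empty medium supports no growth; glutamate supports growth", {
  single <- toy_single()
  starved <- configure_medium(single, list())
  expect_false(feasible_at(starved, 0.01)$feasible)
  expect_gt(veg_growth()$mu_max, 0.05)
  expect_lt(veg_growth()$mu_max, 0.2)
})

test_that("scenario flags are idempotent bound edits", {
  two <- toy_two_default()
  again <- apply_scenario(two, scenario_flags())
  same <- vapply(names(two$reactions), function(id)
    identical(two$reactions[[id]]$lb, again$reactions[[id]]$lb) &&
      identical(two$reactions[[id]]$ub, again$reactions[[id]]$ub), TRUE)
  expect_true(all(same))
  no_ndp <- apply_scenario(two, scenario_flags(ndp_ntp_transport = FALSE))
  expect_equal(no_ndp$reactions[["QA_transport_gdp"]]$ub, 0)
  expect_gt(no_ndp$reactions[["QA_transport_gmp"]]$ub, 0)  # NMPs still open
})

test_that("closing every channel transport starves the forespore", {
  two <- toy_two_default()
  allsp <- unlist(two$meta$species_classes, use.names = FALSE)
  ids <- c(paste0("QA_transport_", allsp), paste0("QA_transport_", allsp, "_rev"))
  ids <- ids[ids %in% names(two$reactions)]
  closed <- set_bounds(two, ids, lb = 0, ub = 0)
  expect_false(feasible_at(closed, 0.005)$feasible)
})
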