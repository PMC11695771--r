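test_that("essentiality records are order-invariant and floor-consistent", {
  two <- toy_two_no_transport()
  specs <- list(depletion_spec("gmk", "forespore"),
                depletion_spec("cmk", "forespore"),
                depletion_spec(c("cmk", "pyrG"), "forespore"))
  a <- essentiality_scan(two, specs)
  b <- essentiality_scan(two, rev(specs))
  b <- b[match(a$depletion_set, b$depletion_set), ]
  expect_equal(a$essential, b$essential)
  expect_equal(a$essential, c(TRUE, FALSE, TRUE))
})

test_that("invalid depletion specs are reported per record, not fatal", {
  two <- toy_two_default()
  recs <- essentiality_scan(two, list(depletion_spec("gmk", "forespore"),
                                      depletion_spec("nosuch", "forespore")))
  expect_equal(nrow(recs), 2)
  expect_false(is.na(recs$essential[1]))
  expect_true(is.na(recs$essential[2]))
  expect_match(recs$error[2], "translation")
})

test_that("group classification partitions the universe deterministically", {
  mk <- function(ess) data.frame(depletion_set = letters[1:5],
                                 context = "x", mu_max = NA_real_,
                                 essential = ess, stringsAsFactors = FALSE)
  g <- classify_essentiality_groups(
    vg = mk(c(TRUE, TRUE, FALSE, FALSE, FALSE)),
    mc = mk(c(TRUE, FALSE, TRUE, FALSE, FALSE)),
    fs = mk(c(TRUE, FALSE, FALSE, TRUE, FALSE)))
  expect_equal(g$fs_mc_vg, "a")
  expect_equal(g$vg_only, "b")
  expect_equal(g$mc_only, "c")
  expect_equal(g$fs_only, "d")
  expect_equal(g$none, "e")
  all_regions <- c(g$fs_only, g$mc_only, g$vg_only, g$fs_mc, g$fs_vg,
                   g$mc_vg, g$fs_mc_vg, g$none)
  expect_setequal(all_regions, letters[1:5])
  expect_equal(anyDuplicated(all_regions), 0)
  ## three empty scans put everything in the none region
  g0 <- classify_essentiality_groups(mk(rep(FALSE, 5)), mk(rep(FALSE, 5)),
                                     mk(rep(FALSE, 5)))
  expect_equal(g0$none, letters[1:5])
  expect_error(classify_essentiality_groups(mk(rep(FALSE, 5)),
                                            mk(rep(FALSE, 5))[1:3, ],
                                            mk(rep(FALSE, 5))),
               "universe")
})

test_that("germination essentiality mirrors the vegetative flag", {
  vg <- data.frame(depletion_set = c("gmk", "lctE"), context = "vegetative",
                   mu_max = NA_real_, essential = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  expect_true(germination_essential("gmk", vg))
  expect_false(germination_essential("lctE", vg))
  expect_error(germination_essential("zzz", vg), "not covered")
})

test_that("essentiality TSV output is stable and complete", {
  recs <- data.frame(depletion_set = c("b", "a"), context = "forespore",
                     mu_max = c(0, NA), essential = c(TRUE, FALSE),
                     stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  write_essentiality_tsv(recs, tf)
  back <- utils::read.delim(tf)
  expect_equal(back$depletion_set, c("a", "b"))
  expect_equal(names(back), c("depletion_set", "context", "mu_max", "essential"))
})
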