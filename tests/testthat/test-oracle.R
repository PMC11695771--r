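test_that("medium species seed producibility; empty medium reaches nothing new", {
  veg <- toy_vegetative()
  expect_true(producibility_oracle(veg, "glu_c"))
  expect_true(producibility_oracle(veg, "f6p_c"))
  expect_true(producibility_oracle(veg, "wallp_c"))
  expect_true(producibility_oracle(veg, "protein_sspA"))
  starved <- configure_medium(toy_single(), list())
  expect_false(producibility_oracle(starved, "glu_c"))
  expect_false(producibility_oracle(starved, "f6p_c"))
})

test_that("closing ilvC makes isoleucine unreachable in the vegetative cell", {
  veg <- toy_vegetative()
  expect_true(producibility_oracle(veg, "ile_c"))
  dep <- apply_depletions(veg, depletion_spec("ilvC", "vegetative"))
  expect_false(producibility_oracle(dep, "ile_c"))
  expect_false(producibility_oracle(dep, "dhmb_c"))
  ## ilvC is vegetative-essential, so the expression cascade collapses too:
  ## every translated protein needs isoleucine; only the medium remains
  expect_false(producibility_oracle(dep, "thr_c"))
  expect_true(producibility_oracle(dep, "glu_e"))
})

test_that("protein blockage oracle distinguishes dead-end from escape routes", {
  sh <- toy_two_shuttle()
  dep <- apply_depletions(sh, depletion_spec("ilvC", "forespore"))
  expect_true(oracle_protein_blocked(dep, "ilvA", "forespore"))
  expect_true(oracle_protein_blocked(dep, "ilvD", "forespore"))
  expect_false(oracle_protein_blocked(dep, "alsS", "forespore"))  # acetoin escape
  expect_false(oracle_protein_blocked(sh, "ilvA", "forespore"))   # wild type open
})
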