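test_that("production fractions normalize and ignore consumers", {
  m <- me_model()
  m <- add_species(m, c("x_c", "a_c"), "c")
  m <- add_reaction(m, me_reaction("p1", "metabolic", list(a_c = -1, x_c = 2)))
  m <- add_reaction(m, me_reaction("p2", "metabolic", list(a_c = -1, x_c = 1)))
  m <- add_reaction(m, me_reaction("use", "demand", list(x_c = -1)))
  v <- c(p1 = 1, p2 = 2, use = 4)
  pf <- production_fractions(m, v, "x", "vegetative", mu = 0.1)
  expect_equal(sum(pf$fraction), 1)
  expect_equal(pf$rate[pf$reaction == "p1"], 2)
  expect_false("use" %in% pf$reaction)
  ## fractions invariant under uniform flux rescaling
  pf2 <- production_fractions(m, v * 7, "x", "vegetative", mu = 0.1)
  expect_equal(pf$fraction, pf2$fraction)
  ## single producer has fraction one; never-produced species is empty
  pf3 <- production_fractions(m, c(p1 = 1, p2 = 0, use = 2), "x",
                              "vegetative", mu = 0.1)
  expect_equal(pf3$fraction, 1)
  pf4 <- production_fractions(m, c(p1 = 0, p2 = 0, use = 0), "x",
                              "vegetative", mu = 0.1)
  expect_equal(nrow(pf4), 0)
})

test_that("partition ratios use the fluorescence bins and handle zeros", {
  two <- toy_two_default()
  v <- stats::setNames(numeric(length(two$reactions)), names(two$reactions))
  v["translation_pyk_FS"] <- 1e-3
  pr <- protein_partition_ratio(v, two, "pyk")
  expect_equal(pr$f, 1)
  expect_equal(pr$class, "enriched")
  v["translation_pyk_MC"] <- 1e-3
  expect_equal(protein_partition_ratio(v, two, "pyk")$f, 0.5)
  expect_equal(protein_partition_ratio(v, two, "pyk")$class, "diluted")
  v2 <- v; v2["translation_pyk_FS"] <- 1e-4
  expect_equal(protein_partition_ratio(v2, two, "pyk")$class, "depleted")
  z <- protein_partition_ratio(v * 0, two, "pyk")
  expect_equal(z$class, "undefined")
  expect_true(is.na(z$f))
  ## f invariant under uniform rescaling
  expect_equal(protein_partition_ratio(v * 3, two, "pyk")$f,
               protein_partition_ratio(v, two, "pyk")$f)
})

test_that("channel inventory resolves net direction and flips with sign", {
  two <- toy_two_default()
  v <- stats::setNames(numeric(length(two$reactions)), names(two$reactions))
  v["QA_transport_f6p"] <- 0.2
  v["QA_transport_pyr"] <- 0.1; v["QA_transport_pyr_rev"] <- 0.4
  inv <- channel_exchange_inventory(two, v)
  expect_equal(inv$direction[inv$species == "f6p"], "c->s")
  expect_equal(inv$direction[inv$species == "pyr"], "s->c")
  expect_equal(inv$rate[inv$species == "pyr"], 0.3)
  ## antisymmetry: swapping forward and reverse flips every direction
  v2 <- v
  v2["QA_transport_pyr"] <- 0.4; v2["QA_transport_pyr_rev"] <- 0.1
  inv2 <- channel_exchange_inventory(two, v2)
  expect_equal(inv2$direction[inv2$species == "pyr"], "c->s")
  ## all-zero fluxes give an empty inventory
  expect_equal(nrow(channel_exchange_inventory(two, v * 0)), 0)
})

test_that("fold enrichment matches exhaustive enumeration for small N", {
  fe <- fold_enrichment(5, 10, 10, 100)
  expect_equal(fe$fold, 5)
  expect_equal(fold_enrichment(7, 25, 7, 25)$fold, 1)
  z <- fold_enrichment(0, 5, 10, 50)
  expect_equal(z$fold, 0)
  expect_equal(z$p_value, 1)
  ## enumeration oracle: P(X >= k) by direct summation over choose()
  for (case in list(c(3, 6, 8, 20), c(2, 4, 5, 12), c(1, 10, 10, 25))) {
    k <- case[1]; n <- case[2]; K <- case[3]; N <- case[4]
    pe <- sum(vapply(k:min(n, K), function(i)
      choose(K, i) * choose(N - K, n - i), 0)) / choose(N, n)
    expect_equal(fold_enrichment(k, n, K, N)$p_value, pe, tolerance = 1e-12)
  }
  expect_error(fold_enrichment(6, 5, 10, 50))
})
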