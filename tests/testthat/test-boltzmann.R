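rt_kcal <- function(temp = 298.15) 1.987204259e-3 * temp

sigma_ensemble <- function(sigma, delta_G, temperature = 298.15) {
  base <- matrix(seq_len(12), 4, 3)
  make_ensemble(
    lapply(seq_along(sigma), function(i) base + i),
    delta_G = delta_G, sigma_P = sigma, temperature = temperature
  )
}

test_that("Boltzmann weights follow the closed form", {
  expect_equal(boltzmann_weights(c(0, 0, 0)), rep(1 / 3, 3))
  # an energy gap of RT ln 2 gives populations 2:1
  expect_equal(
    boltzmann_weights(c(0, rt_kcal() * log(2))),
    c(2 / 3, 1 / 3),
    tolerance = 1e-12
  )
  w <- boltzmann_weights(c(0, 50))
  expect_equal(w[1], 1, tolerance = 1e-12)
  expect_lt(w[2], 1e-30)
})

test_that("Boltzmann weights validate their inputs", {
  expect_error(boltzmann_weights(numeric(0)), "nonempty")
  expect_error(boltzmann_weights(c(0, 1), temperature = -10), "> 0")
  expect_error(boltzmann_weights(c(-0.5, 1)), ">= 0")
  expect_error(boltzmann_weights(c(0.5, 1)), "min delta_G = 0")
})

test_that("weights sum to one and the average stays inside the shielding range", {
  set.seed(99)
  for (i in 1:25) {
    k <- sample(1:12, 1)
    dg <- c(0, runif(k - 1, 0, 6))
    sg <- runif(k, 250, 450)
    temp <- runif(1, 50, 1000)
    res <- boltzmann_shielding(sigma_ensemble(sg, dg, temperature = temp))
    expect_equal(sum(res$weights), 1, tolerance = 1e-12)
    expect_gte(res$sigma_bol, res$sigma_lowest)
    expect_lte(res$sigma_bol, res$sigma_highest)
  }
})

test_that("Boltzmann-averaged shieldings reproduce hand-computed values", {
  expect_equal(boltzmann_shielding(sigma_ensemble(310, 0))$sigma_bol, 310)
  expect_equal(
    boltzmann_shielding(sigma_ensemble(c(300, 310), c(0, 0)))$sigma_bol,
    305
  )
  # weights (2/3, 1/3) at an RT ln 2 gap
  expect_equal(
    boltzmann_shielding(sigma_ensemble(c(300, 310), c(0, rt_kcal() * log(2))))$sigma_bol,
    300 * 2 / 3 + 310 * 1 / 3,
    tolerance = 1e-9
  )
})

test_that("temperature limits: infinite-T mean and zero-T ground state", {
  sg <- c(300, 320, 340)
  dg <- c(0, 1.2, 4.5)
  hot <- boltzmann_shielding(sigma_ensemble(sg, dg, temperature = 1e9))
  expect_equal(hot$sigma_bol, mean(sg), tolerance = 1e-6)
  cold <- boltzmann_shielding(sigma_ensemble(sg, dg, temperature = 1e-3))
  expect_equal(cold$sigma_bol, 300)
})

test_that("missing shieldings fail loudly, naming the conformer", {
  ens <- sigma_ensemble(c(300, NA, 310), c(0, 1, 2))
  expect_error(boltzmann_shielding(ens), "c002")
})

test_that("symmetry-equivalent phosphorus shieldings are averaged per conformer", {
  base <- matrix(seq_len(12), 4, 3)
  ens <- make_ensemble(
    list(base, base + 1),
    delta_G = c(0, 0),
    sigma_P = list(c(298, 302), c(310, 310))
  )
  expect_equal(boltzmann_shielding(ens)$sigma_bol, mean(c(300, 310)))
})

test_that("referencing maps the reference compound onto its own shift", {
  sch <- reference_scheme(sigma_ref = 300)
  expect_equal(shielding_to_shift(300, sch), -62.0)
  expect_equal(shielding_to_shift(280, sch), -42.0)
  as_printed <- reference_scheme(sigma_ref = 300, convention = "as_printed")
  expect_equal(shielding_to_shift(300, as_printed), 62.0)
  # the two sign conventions differ by a constant 124 ppm
  sg <- seq(200, 400, by = 25)
  expect_equal(
    shielding_to_shift(sg, as_printed) - shielding_to_shift(sg, sch),
    rep(2 * 62.0, length(sg))
  )
  # strictly decreasing in shielding under both conventions
  expect_true(all(diff(shielding_to_shift(sg, sch)) < 0))
  expect_true(all(diff(shielding_to_shift(sg, as_printed)) < 0))
})

test_that("predict_molecule composes Boltzmann averaging and referencing", {
  sch <- reference_scheme(sigma_ref = 300)
  single <- predict_molecule("m", sigma_ensemble(310, 0), sch)
  expect_equal(single$delta_single, single$delta_boltzmann)
  expect_identical(single$n_conformers_used, 1L)

  two <- predict_molecule("m", sigma_ensemble(c(300, 310), c(0, 0)), sch)
  expect_equal(two$delta_boltzmann, (300 - 305) - 62.0) # -67
  expect_lte(two$delta_highest_shielding, two$delta_lowest_shielding)

  expect_error(
    predict_molecule("m", sigma_ensemble(c(300, NA), c(0, 1)), sch),
    "shielding"
  )
})
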