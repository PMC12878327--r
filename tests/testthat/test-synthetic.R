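test_that("generation is bit-identical under the same seed", {
  cfg <- synthetic_config(n_molecules = 15, seed = 42)
  d1 <- suppressMessages(generate_dataset(cfg))
  d2 <- suppressMessages(generate_dataset(cfg))
  expect_identical(d1$records, d2$records)
  expect_identical(d1$ground_truth, d2$ground_truth)
  expect_identical(
    d1$ensembles[["SYN00007"]]$conformers,
    d2$ensembles[["SYN00007"]]$conformers
  )
})

test_that("molecule streams are independent of the total count", {
  d_small <- suppressMessages(generate_dataset(synthetic_config(n_molecules = 10, seed = 5)))
  d_large <- suppressMessages(generate_dataset(synthetic_config(n_molecules = 25, seed = 5)))
  expect_equal(d_small$records, d_large$records[1:10, ], ignore_attr = TRUE)
  expect_identical(
    d_small$ensembles[["SYN00003"]]$conformers,
    d_large$ensembles[["SYN00003"]]$conformers
  )
})

test_that("zero noise and zero offsets make experiment equal truth", {
  cfg <- rlang::exec(synthetic_config,
    n_molecules = 12, seed = 8, noise_sd = 0,
    !!!zero_offsets
  )
  d <- suppressMessages(generate_dataset(cfg))
  expect_equal(d$records$delta_exp, d$ground_truth$delta_true)
})

test_that("experimental shifts decompose into truth, offsets and noise", {
  d <- suppressMessages(generate_dataset(synthetic_config(n_molecules = 40, seed = 21)))
  gt <- d$ground_truth
  expect_equal(
    d$records$delta_exp,
    gt$delta_true + gt$solvent_offset + gt$class_offset + gt$noise
  )
  # revealed labels match the assigned solvent; hidden ones read unknown
  known <- d$records$solvent != "unknown"
  expect_identical(d$records$solvent[known], gt$solvent_assigned[known])
  expect_identical(known, gt$solvent_known)
})

test_that("every compound class appears in a moderate data set", {
  d <- suppressMessages(generate_dataset(synthetic_config(n_molecules = 50, seed = 31)))
  expect_setequal(
    unique(d$ground_truth$class_label),
    c(
      "monoalkyl_phosphinate", "phosphonite", "phosphonate",
      "dialkyl_phosphinate", "other"
    )
  )
  # the declared class matches what the classifier says about the SMILES
  expect_identical(d$records$class_label, d$ground_truth$class_label)
})

test_that("conformer counts grow with molecule size and respect the cap and window", {
  d <- suppressMessages(generate_dataset(synthetic_config(n_molecules = 60, seed = 17)))
  gt <- d$ground_truth
  expect_true(cor(gt$n_atoms, gt$n_conformers, method = "spearman") > 0.3)
  expect_true(all(gt$n_conformers >= 1))
  expect_true(all(gt$n_conformers <= 30))
  for (ens in d$ensembles) {
    expect_equal(min(ens$conformers$delta_G), 0)
    expect_true(all(ens$conformers$delta_G <= 6))
    expect_false(is.unsorted(ens$conformers$delta_G))
  }
})

test_that("surrogate shieldings invert exactly through the physical reference", {
  cfg <- rlang::exec(synthetic_config,
    n_molecules = 6, seed = 3, noise_sd = 0, g_amplitude = 0,
    !!!zero_offsets
  )
  d <- suppressMessages(generate_dataset(cfg))
  sch <- reference_scheme(sigma_ref = cfg$sigma_ref)
  for (i in seq_len(nrow(d$records))) {
    ens <- d$ensembles[[d$records$mol_id[i]]]
    sigma <- surrogate_shielding(ens, "vac", d$ground_truth, g_amplitude = 0)
    expect_equal(
      unique(shielding_to_shift(sigma, sch)),
      d$ground_truth$delta_true[i]
    )
  }
})

test_that("the surrogate is deterministic and geometry-keyed", {
  d <- suppressMessages(generate_dataset(synthetic_config(n_molecules = 4, seed = 9)))
  ens <- d$ensembles[[1]]
  s1 <- surrogate_shielding(ens, "vac", d$ground_truth)
  s2 <- surrogate_shielding(ens, "vac", d$ground_truth)
  expect_identical(s1, s2)
  # reordering/pruning conformers does not change a conformer's shielding
  sub <- ens
  sub$conformers <- ens$conformers[rev(seq_len(nrow(ens$conformers))), ]
  expect_identical(
    surrogate_shielding(sub, "vac", d$ground_truth),
    rev(s1)
  )
  expect_error(
    surrogate_shielding(ens, "vac", d$ground_truth[0, ]),
    "not in the ground truth"
  )
})

test_that("modelling the assigned solvent cancels exactly its offset", {
  cfg <- synthetic_config(
    n_molecules = 10, seed = 12, noise_sd = 0, g_amplitude = 0,
    solvent_known_fraction = 1,
    solvent_offsets = c(CHCl3 = 3, H2O = -5)
  )
  d <- suppressMessages(generate_dataset(cfg))
  sch <- reference_scheme(sigma_ref = cfg$sigma_ref)
  gt <- d$ground_truth
  for (i in seq_len(nrow(gt))) {
    ens <- d$ensembles[[gt$mol_id[i]]]
    matched <- shielding_to_shift(
      surrogate_shielding(ens, gt$solvent_assigned[i], gt, g_amplitude = 0), sch
    )[1]
    vac <- shielding_to_shift(
      surrogate_shielding(ens, "vac", gt, g_amplitude = 0), sch
    )[1]
    expect_equal(matched, gt$delta_true[i] + gt$solvent_offset[i])
    expect_equal(vac, gt$delta_true[i])
  }
})

test_that("the conformer perturbation bounds ensemble-vs-single differences", {
  d <- suppressMessages(generate_dataset(synthetic_config(n_molecules = 8, seed = 77)))
  sch <- reference_scheme(sigma_ref = 350)
  for (id in names(d$ensembles)) {
    ens <- d$ensembles[[id]]
    ens$conformers$sigma_P <- surrogate_shielding(
      ens, "vac", d$ground_truth,
      g_amplitude = 2
    )
    pred <- predict_molecule(id, ens, sch)
    # sigma_bol lies within [sigma_min, sigma_max], g bounded by 2 ppm
    expect_lte(abs(pred$delta_boltzmann - pred$delta_single), 4.0)
  }
})

test_that("ensemble averaging does not hurt on average when noise is independent", {
  # scaled down for runtime: small data sets over many seeds
  improvements <- vapply(1:20, function(s) {
    cfg <- rlang::exec(synthetic_config,
      n_molecules = 25, seed = 1000 + s, noise_sd = 5,
      conformer_law = c(a = 0.0314, b = 2.515, scale = 0.1, max = 8),
      !!!zero_offsets
    )
    res <- quiet_pipeline(pipeline_config(synthetic = cfg, conditions = "vac"))
    imp <- res$report$improvements
    imp$improvement_pct[imp$cohort_kind == "all" &
      imp$alternative == "vacuum_ensemble"]
  }, double(1))
  expect_gte(mean(improvements), 0)
})
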