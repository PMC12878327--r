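test_that("error metrics match hand arithmetic", {
  perfect <- compute_error_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mse, 0)

  m <- compute_error_metrics(c(0, 0), c(1, -1))
  expect_equal(m$rmse, 1)
  expect_equal(m$mae, 1)
  expect_equal(m$mse, 0)

  # sign convention: exp - calc, so overestimated shifts give negative MSE
  over <- compute_error_metrics(c(10, 20), c(15, 25))
  expect_equal(over$mse, -5)

  expect_error(compute_error_metrics(numeric(0), numeric(0)), "At least one")
  expect_error(compute_error_metrics(c(1, NA), c(1, 2)), "Missing")
  expect_error(compute_error_metrics(1, 2, shift_range = 0), "> 0")
})

test_that("RMSE >= MAE always; equality only for equal absolute errors", {
  set.seed(12)
  for (i in 1:30) {
    n <- sample(2:50, 1)
    m <- compute_error_metrics(rnorm(n, sd = 10), rnorm(n, sd = 10))
    expect_gte(m$rmse, m$mae)
    expect_lte(abs(m$mse), m$mae)
  }
  eq <- compute_error_metrics(c(0, 0, 0), c(2, -2, 2))
  expect_equal(eq$rmse, eq$mae)
})

test_that("cohort MSEs pool to the overall MSE", {
  set.seed(13)
  exp_all <- rnorm(100, sd = 30)
  calc_all <- exp_all + rnorm(100, sd = 8)
  split_at <- rep(1:3, c(20, 30, 50))
  pooled <- compute_error_metrics(exp_all, calc_all)$mse
  cohort_mse <- vapply(
    1:3,
    function(g) compute_error_metrics(exp_all[split_at == g], calc_all[split_at == g])$mse,
    double(1)
  )
  expect_equal(sum(cohort_mse * c(20, 30, 50)) / 100, pooled, tolerance = 1e-9)
})

test_that("improvement_percent reproduces reported table arithmetic", {
  # (reference RMSE, alternative RMSE) -> printed improvement at 1 decimal
  cases <- list(
    list(30.82, 29.37, 4.7), # vacuum single point -> Boltzmann ensemble
    list(26.92, 26.47, 1.7), # chloroform cohort, implicit solvent
    list(25.33, 23.03, 9.1), # toluene cohort
    list(39.86, 40.79, -2.3) # acetonitrile cohort: a decline
  )
  for (cs in cases) {
    expect_equal(
      p31shift:::round_half_up(improvement_percent(cs[[1]], cs[[2]]), 1),
      cs[[3]]
    )
  }
  expect_equal(improvement_percent(17.5, 17.5), 0)
  expect_error(improvement_percent(0, 1), "> 0")
})

test_that("improvement sign antisymmetry holds", {
  set.seed(14)
  for (i in 1:20) {
    a <- runif(1, 1, 50)
    b <- runif(1, 1, 50)
    expect_equal(
      sign(improvement_percent(a, b)),
      -sign(improvement_percent(b, a))
    )
  }
})

test_that("quantile_split sizes differ by at most one, larger groups first", {
  recs <- function(n) {
    tibble::tibble(
      mol_id = sprintf("m%05d", seq_len(n)),
      n_atoms = sample.int(80, n, replace = TRUE)
    )
  }
  set.seed(15)
  q <- quantile_split(recs(10007), "n_atoms", k = 5)
  expect_equal(unname(table(q$cohort)[sprintf("Q%d", 1:5)]), c(2002, 2002, 2001, 2001, 2001),
    ignore_attr = TRUE
  )
  expect_equal(as.vector(table(quantile_split(recs(5), "n_atoms", 5)$cohort)), rep(1, 5))
  expect_equal(
    unname(table(quantile_split(recs(7), "n_atoms", 5)$cohort)[sprintf("Q%d", 1:5)]),
    c(2, 2, 1, 1, 1),
    ignore_attr = TRUE
  )
  expect_error(quantile_split(recs(3), "n_atoms", 5), "Cannot split")
})

test_that("quantile cohorts partition the records monotonically", {
  set.seed(16)
  recs <- tibble::tibble(
    mol_id = sprintf("m%04d", 1:537),
    n_atoms = sample.int(60, 537, replace = TRUE)
  )
  q <- quantile_split(recs, "n_atoms", k = 5)
  expect_setequal(q$mol_id, recs$mol_id)
  expect_identical(anyDuplicated(q$mol_id), 0L)
  # values are non-decreasing across cohort boundaries
  expect_false(is.unsorted(q$value))
})

test_that("phosphorus classes match their defining substitution patterns", {
  expect_identical(classify_p_class("CCP(=O)(OCC)OCC"), "phosphonate")
  expect_identical(classify_p_class("CCP(OCC)OCC"), "phosphonite")
  expect_identical(classify_p_class("CC[PH](=O)OCC"), "monoalkyl_phosphinate")
  expect_identical(classify_p_class("CCP(=O)(CC)OCC"), "dialkyl_phosphinate")
  expect_identical(classify_p_class("CP(C)C"), "other") # trimethylphosphine
  expect_identical(classify_p_class("COP(OC)OC"), "other") # phosphite: no P-C
  expect_identical(classify_p_class("CCP(=O)(O)OCC"), "other") # free acid OH, not OR
  expect_error(classify_p_class("CCO"), "no phosphorus")
})

test_that("classification is invariant under rewriting the SMILES", {
  equivalent <- list(
    c("CCP(=O)(OCC)OCC", "O=P(CC)(OCC)OCC", "CCOP(=O)(CC)OCC"),
    c("CCP(OCC)OCC", "C(C)P(OCC)OCC"),
    c("CP(C)C", "P(C)(C)C")
  )
  for (grp in equivalent) {
    labels <- vapply(grp, classify_p_class, character(1))
    expect_identical(unique(labels), labels[[1]])
  }
})

test_that("multi-phosphorus molecules take the highest-priority matching class", {
  # one P is a phosphonate environment, the other a phosphonite
  two_p <- "CCP(=O)(OCC)OCCP(OCC)OCC"
  expect_identical(classify_p_class(two_p), "phosphonate")
})

test_that("stratified_report: perfect predictions give zero everywhere", {
  records <- suppressMessages(as_molecule_table(tibble::tibble(
    mol_id = c("a", "b", "c", "d"),
    smiles = c("CP(C)C", "CCP(=O)(OCC)OCC", "CCP(OCC)OCC", "CC[PH](=O)OCC"),
    delta_exp = c(-60, 30, 140, 25),
    solvent = c("CHCl3", "CHCl3", "unknown", "H2O")
  )))
  shifts <- tidyr::crossing(
    tibble::tibble(mol_id = records$mol_id, delta = records$delta_exp),
    condition = c("ref", "alt")
  )
  shifts$delta_calc <- shifts$delta
  rep <- suppressMessages(suppressWarnings(stratified_report(
    records, shifts[, c("mol_id", "condition", "delta_calc")],
    condition_pairs = list(c("ref", "alt")), k = 2
  )))
  expect_true(all(rep$metrics$rmse == 0))
  expect_true(all(rep$improvements$improvement_pct == 0))
  # unknown-solvent records form their own solvent cohort
  expect_true("unknown" %in% rep$metrics$cohort[rep$metrics$cohort_kind == "solvent"])
  # class cohorts carry the mean experimental and calculated shifts
  cls <- rep$metrics[rep$metrics$cohort_kind == "class", ]
  expect_equal(cls$mean_delta_exp, cls$mean_delta_calc)
})

test_that("stratified_report excludes and counts records without experiment", {
  records <- suppressMessages(as_molecule_table(tibble::tibble(
    mol_id = c("a", "b", "c"),
    smiles = c("CP(C)C", "CCP(=O)(OCC)OCC", "CCP(OCC)OCC"),
    delta_exp = c(-60, NA, 140)
  )))
  shifts <- tibble::tibble(
    mol_id = c("a", "b", "c"), condition = "x",
    delta_calc = c(-58, 31, 150)
  )
  rep <- suppressMessages(suppressWarnings(
    stratified_report(records, shifts, by = "all", k = 1)
  ))
  expect_identical(rep$n_excluded, 1L)
  expect_identical(rep$metrics$n, 2L)
})
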