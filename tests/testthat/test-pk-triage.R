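test_that("permeability classes follow the 20e-6 cm/s rule with HIA ~96%", {
  hi <- classify_permeability(25e-6, "Caco-2")
  expect_identical(hi$class, "high")
  expect_equal(hi$hia, 0.96)

  mdck <- classify_permeability(1.77e-5, "MDCK")  # below 20e-6: moderate
  expect_identical(mdck$class, "moderate")
  expect_true(is.na(mdck$hia))
  expect_equal(mdck$band, 1e-5)

  expect_equal(classify_permeability(1.0e-5)$log_papp, -5.0)
  expect_identical(classify_permeability(5e-7)$class, "low")
  expect_error(classify_permeability(0), "positive")
})

test_that("permeability classification is monotone in papp", {
  lvl <- c(low = 1L, moderate = 2L, high = 3L)
  papp <- sort(10^runif(50, -7, -3.5))
  cls <- lvl[classify_permeability(papp)$class]
  expect_true(all(diff(cls) >= 0L))
})

test_that("clearance stability flags use strict thresholds", {
  f <- stability_flags(cl_hepa = 15)
  expect_true(f[["stable"]] && f[["enhanced"]])
  expect_false(stability_flags(cl_hepa = 150)[["stable"]])
  expect_false(stability_flags(cl_hepa = 100)[["stable"]])  # boundary: strict
  expect_false(stability_flags(cl_hepa = 50)[["enhanced"]])
  expect_true(stability_flags(cl_hepa = 50, cl_micro = 7.9)[["microsomal_stable"]])
  expect_false(stability_flags(cl_hepa = 50, cl_micro = 8.0)[["microsomal_stable"]])
  expect_true(is.na(stability_flags(cl_hepa = 50)[["microsomal_stable"]]))
  expect_error(stability_flags(), "at least one clearance")
})

test_that("bioavailability and lipophilicity-risk rules match the narrative", {
  expect_true(bioavailability_and_risk(2.9, 460)[["oral_risk"]])
  expect_false(bioavailability_and_risk(2.32, 371.3)[["oral_risk"]])
  expect_false(bioavailability_and_risk(2.9, 400)[["oral_risk"]])  # needs both
  expect_true(bioavailability_and_risk(1, 300, f_oral = 0.9)[["high_f"]])  # inclusive
  expect_false(bioavailability_and_risk(1, 300, f_oral = 0.89)[["high_f"]])
  expect_true(bioavailability_and_risk(1, 300, fdamdd = 0.009)[["fdamdd_exceeded"]])
  expect_error(bioavailability_and_risk(NA, 300), "required")
})

test_that("toxicity similarity matches the direct Pearson formula and is PSD", {
  set.seed(11)
  m <- matrix(runif(30), 5, 6,
              dimnames = list(NULL, c("dili", "ames", "roa", "fdamdd",
                                      "hht", "neuro")))
  cm <- tox_similarity(m)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 6))
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(cm[i, j], pearson_oracle(m[, i], m[, j]), tolerance = 1e-12)
  expect_gte(min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # identical / negated columns
  m2 <- cbind(a = m[, 1], b = m[, 1], c = 1 - m[, 1])
  cm2 <- tox_similarity(m2)
  expect_equal(cm2["a", "b"], 1.0)
  expect_equal(cm2["a", "c"], -1.0)

  # constant column: NaN with warning, never silently zero
  m3 <- cbind(m[, 1:2], flat = rep(0.5, 5))
  expect_warning(cm3 <- tox_similarity(m3), "flat")
  expect_true(all(is.na(cm3["flat", c(1, 2)])))

  # orientation flag transposes the correlation target
  expect_equal(dim(tox_similarity(m, orientation = "compounds")), c(5L, 5L))
  expect_error(tox_similarity(m - 2), "\\[0, 1\\]")
})

test_that("lead ranking is lexicographic in (MPO score, mean affinity)", {
  mpo <- data.frame(compound_id = c("A", "B"), D = c(6, 5))
  ea <- data.frame(compound_id = c("A", "B"), target = "t", ea = c(-5, -12))
  expect_identical(rank_leads(mpo, ea)$compound_id[1], "A")  # D dominates

  mpo2 <- data.frame(compound_id = c("A", "B", "C"), D = c(5, 5, 5))
  ea2 <- data.frame(compound_id = c("A", "B", "C"), target = "t",
                    ea = c(-7, -9, -9))
  r <- rank_leads(mpo2, ea2)
  expect_identical(r$compound_id, c("B", "C", "A"))  # EA then id order
  expect_error(rank_leads(mpo2, ea2[1:2, ]), "affinity energy")
})

test_that("published-score rows rank the lead analog first", {
  t1 <- read_descriptor_table(extdata("table1_descriptors_reconstructed.csv"))
  ea <- utils::read.csv(extdata("ea_reconstructed.csv"))
  printed <- c("LASSBio-2125", "LASSBio-2129")
  mt <- mpo_table(t1[t1$compound_id %in% printed, ], mpo_config(calibrated = TRUE))
  r <- rank_leads(mt, ea[ea$compound_id %in% printed, ])
  expect_identical(r$compound_id[1], "LASSBio-2129")
})

test_that("the triage report is a pure function of its inputs", {
  t1 <- read_descriptor_table(extdata("table1_descriptors_reconstructed.csv"))
  pk <- utils::read.csv(extdata("table2_pk_reconstructed.csv"))
  a <- triage_report(t1, pk)
  b <- triage_report(t1, pk)
  expect_identical(a, b)
  lead <- a[a$compound_id == "LASSBio-2129", ]
  expect_identical(lead$perm_mdck, "moderate")
  expect_true(lead$stable && lead$enhanced && lead$microsomal_stable)
  expect_false(lead$oral_risk)
  expect_true(lead$high_f)
})
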