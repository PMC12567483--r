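test_that("desirability honors thresholds, zero limits, and the TPSA hump", {
  cfg <- mpo_config()
  expect_equal(desirability("logp", 2.0, cfg), 1.0)   # inside threshold
  expect_equal(desirability("logp", 3.0, cfg), 1.0)   # exactly at threshold
  expect_equal(desirability("logp", 5.0, cfg), 0.0)   # at zero limit
  expect_equal(desirability("logp", 4.0, cfg), 0.5)
  expect_equal(desirability("tpsa", 65, cfg), 1.0)    # inside 40-90
  expect_equal(desirability("tpsa", 40, cfg), 1.0)
  expect_equal(desirability("tpsa", 90, cfg), 1.0)
  expect_equal(desirability("tpsa", 20, cfg), 0.0)
  expect_equal(desirability("tpsa", 120, cfg), 0.0)
  expect_equal(desirability("tpsa", 30, cfg), 0.5)
  expect_equal(desirability("tpsa", 105, cfg), 0.5)
  expect_error(desirability("molar_refractivity", 1, cfg), "unknown attribute")
  expect_error(desirability("logp", NaN, cfg), "finite")
})

test_that("a row strictly inside all thresholds scores the maximum 6.0", {
  row <- list(compound_id = "perfect", mw = 330, tpsa = 65, hbd = 1,
              logp = 2, logd74 = 1.5, pka_basic = 7)
  res <- mpo_score(row)
  expect_equal(res$score, 6.0)
  expect_length(res$violations, 0L)
})

test_that("missing attributes abort with the attribute named", {
  row <- list(compound_id = "x", mw = 330, tpsa = 65, hbd = 1,
              logp = 2, logd74 = NA, pka_basic = 7)
  expect_error(mpo_score(row), "logd74")
})

test_that("score is bounded, monotone in each risk attribute, unimodal in TPSA", {
  cfg <- mpo_config()
  set.seed(2129)
  base <- list(mw = 330, tpsa = 65, hbd = 1, logp = 2, logd74 = 1.5,
               pka_basic = 7)
  for (i in 1:200) {
    row <- list(compound_id = "r",
                mw = runif(1, 100, 700), tpsa = runif(1, 0, 160),
                hbd = sample(0:6, 1), logp = runif(1, -2, 8),
                logd74 = runif(1, -2, 6), pka_basic = runif(1, 2, 13))
    D <- mpo_score(row, cfg)$score
    expect_gte(D, 0); expect_lte(D, 6)
    # increasing any monotone attribute never increases D
    for (a in c("logp", "logd74", "mw", "hbd", "pka_basic")) {
      row2 <- row; row2[[a]] <- row[[a]] + runif(1, 0, 50)
      expect_lte(mpo_score(row2, cfg)$score, D + 1e-12)
    }
  }
  # TPSA unimodal: desirability non-decreasing up to the plateau, then non-increasing
  tp <- seq(0, 160, by = 0.5)
  Tt <- desirability("tpsa", tp, cfg)
  expect_true(all(diff(Tt[tp <= 40]) >= -1e-12))
  expect_true(all(diff(Tt[tp >= 90]) <= 1e-12))
})

test_that("scores agree with an independently coded desirability sum", {
  cfg <- mpo_config()
  set.seed(17)
  for (i in 1:1000) {
    vals <- list(mw = runif(1, 150, 650), tpsa = runif(1, 0, 150),
                 hbd = sample(0:5, 1), logp = runif(1, -1, 7),
                 logd74 = runif(1, -1, 5), pka_basic = runif(1, 3, 12))
    got <- mpo_score(c(compound_id = "r", vals), cfg)$score
    want <- mpo_oracle(vals, default_lims)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("configured weights and limits propagate into the score", {
  cfg <- mpo_config(weights = c(logp = 2),
                    limits = list(mw = c(400, 600)))
  row <- list(compound_id = "w", mw = 500, tpsa = 65, hbd = 1, logp = 2,
              logd74 = 1, pka_basic = 7)
  # logp weight 2 (T=1), mw T = (600-500)/200 = 0.5
  expect_equal(mpo_score(row, cfg)$score, 2 + 4 + 0.5)
  expect_error(mpo_config(limits = list(mw = c(500, 400))), "ascending")
  expect_error(mpo_config(weights = c(logp = -1)), "positive")
})

test_that("radar coordinates mirror the per-attribute desirabilities", {
  perfect <- mpo_score(list(compound_id = "p", mw = 330, tpsa = 65, hbd = 1,
                            logp = 2, logd74 = 1.5, pka_basic = 7))
  rc <- radar_coordinates(perfect)
  expect_identical(nrow(rc), 6L)
  expect_equal(rc$radius, rep(1, 6))
  expect_equal(sqrt(rc$x^2 + rc$y^2), rep(1, 6), tolerance = 1e-12)

  mixed <- mpo_score(list(compound_id = "m", mw = 420, tpsa = 10, hbd = 2,
                          logp = 4, logd74 = 3, pka_basic = 9))
  rc2 <- radar_coordinates(mixed)
  expect_equal(rc2$radius[rc2$attribute == "tpsa"], 0)  # T = 0 vertex at origin
  # vertices match desirabilities recomputed independently
  for (a in c("logp", "logd74", "mw", "hbd", "pka_basic"))
    expect_equal(rc2$radius[rc2$attribute == a],
                 desirability(a, mixed$values[[a]]))
})
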