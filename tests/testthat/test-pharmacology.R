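make_gtt <- function(ctrl_mean, trt_mean, times = c(0, 15)) {
  rbind(
    data.frame(animal = "c1", group = "control", time_min = times,
               glycemia_mg_dl = ctrl_mean),
    data.frame(animal = "t1", group = "treated", time_min = times,
               glycemia_mg_dl = trt_mean))
}

test_that("percent reduction is the relative drop in group means", {
  d <- make_gtt(c(90, 200), c(90, 150))
  expect_equal(percent_reduction(d, "treated", "control", 15), 25)
  expect_equal(percent_reduction(d, "control", "control", 15), 0)
  d2 <- make_gtt(c(90, 200), c(90, 240))
  expect_lt(percent_reduction(d2, "treated", "control", 15), 0)
  expect_error(percent_reduction(d, "treated", "control", 45),
               "no records at t = 45")
})

test_that("trapezoidal AUC matches hand-computed cases", {
  t5 <- c(0, 30, 60, 90, 120)
  expect_equal(gtt_auc(t5, rep(100, 5), baseline_corrected = TRUE), 0)
  expect_equal(gtt_auc(t5, rep(100, 5), baseline_corrected = FALSE), 12000)
  expect_equal(gtt_auc(c(0, 60, 120), c(100, 200, 100)), 6000)
  # negative excursions contribute negatively
  expect_equal(gtt_auc(c(0, 60, 120), c(100, 50, 100)), -3000)
  expect_error(gtt_auc(c(0, 60, 30), c(1, 2, 3)), "strictly increasing")
})

test_that("AUC is linear in glycemia and additive over adjacent windows", {
  set.seed(5)
  tt <- c(0, 15, 30, 60, 120, 180)
  y1 <- 90 + c(0, runif(5, 0, 200))
  y2 <- 90 + c(0, runif(5, 0, 200))
  raw <- function(y, w) gtt_auc(tt, y, baseline_corrected = FALSE, window = w)
  expect_equal(raw(2 * y1, c(0, 120)), 2 * raw(y1, c(0, 120)), tolerance = 1e-9)
  expect_equal(raw(y1 + y2, c(0, 120)), raw(y1, c(0, 120)) + raw(y2, c(0, 120)),
               tolerance = 1e-9)
  expect_equal(raw(y1, c(0, 60)) + raw(y1, c(60, 120)), raw(y1, c(0, 120)),
               tolerance = 1e-9)
  # endpoint interpolation: window end between samples
  expect_equal(gtt_auc(c(0, 60, 180), c(100, 100, 100),
                       baseline_corrected = FALSE, window = c(0, 120)), 12000)
})

test_that("Kitt recovers the closed-form decay constant", {
  tt <- c(0, 7, 14, 28)
  d <- data.frame(animal = "a1", group = "g",
                  time_min = tt, glycemia_mg_dl = 100 * exp(-0.0231 * tt))
  r <- kitt(d)
  expect_true(r$valid)
  expect_equal(r$t_half, 30.0, tolerance = 1e-3)
  expect_equal(r$kitt, 2.31, tolerance = 1e-3)
  expect_equal(r$kitt, 0.693 * 100 / r$t_half, tolerance = 1e-9)
  expect_gt(r$r_squared, 0.999)

  flat <- data.frame(animal = "a1", group = "g", time_min = tt,
                     glycemia_mg_dl = rep(120, 4))
  expect_false(kitt(flat)$valid)
  expect_true(is.na(kitt(flat)$kitt))
  expect_error(kitt(transform(flat, glycemia_mg_dl = c(-1, 1, 1, 1))),
               "positive")
})

test_that("group-mean Kitt is recovered from noisy simulated animals", {
  spec <- sim_spec(seed = 2129, n_per_group = 8, sigma = 0.02,
                   kitt_true = c(treated = 2.31))
  d <- gen_itt(spec)
  r <- kitt(d)
  expect_lt(abs(r$kitt - 2.31) / 2.31, 0.05)
})

test_that("Kitt recovery error stays below 3% median over 200 animals", {
  set.seed(99)
  k_true <- runif(200, 0.5, 5)
  spec <- sim_spec(seed = 424242, n_per_group = 1, sigma = 0.02,
                   kitt_true = stats::setNames(k_true, sprintf("a%03d", 1:200)))
  d <- gen_itt(spec)
  r <- kitt(d)
  r <- r[match(sprintf("a%03d", 1:200), r$group), ]
  rel_err <- abs(r$kitt - k_true) / k_true
  expect_lt(median(rel_err), 0.03)
})

test_that("fold changes and their failure modes behave", {
  expect_equal(fold_change(c(5, 5), c(5, 5)), 1.0)
  expect_equal(fold_change(18.8, 2.0), 9.4)
  expect_error(fold_change(numeric(0), 2), "empty treated")
  expect_error(fold_change(1, 0), "control mean")
})

test_that("2^-ddCt folds match hand arithmetic and shift invariance", {
  rec <- data.frame(sample = c("c1", "c2", "s1"),
                    group = c("ctl", "ctl", "trt"),
                    ct_target = c(25.0, 25.0, 23.53),
                    ct_ref = c(20.0, 20.0, 20.0))
  r <- ddct(rec, "ctl")
  expect_equal(r$fold[r$group == "ctl"], c(1, 1))
  expect_equal(r$fold[r$group == "trt"], 2^1.47, tolerance = 1e-9)
  expect_equal(2^1.47, 2.77, tolerance = 0.01)

  # ddCt = 0 -> fold 1; ddCt = -1 -> fold 2
  rec2 <- rec; rec2$ct_target[3] <- 24.0
  expect_equal(ddct(rec2, "ctl")$fold[3], 2.0)

  # shifting every Ct by a constant leaves folds unchanged
  rec3 <- rec; rec3$ct_target <- rec3$ct_target + 3; rec3$ct_ref <- rec3$ct_ref + 3
  expect_equal(ddct(rec3, "ctl")$fold, r$fold, tolerance = 1e-12)

  expect_error(ddct(rec, "nope"), "empty control group")
  expect_error(ddct(transform(rec, ct_ref = c(20, 20, 46)), "ctl"), "0, 45")
})

test_that("MTT viability is relative to the control condition", {
  rec <- data.frame(well = sprintf("w%d", 1:6),
                    condition = rep(c("control", "10uM"), each = 3),
                    abs570 = c(1.0, 1.0, 1.0, 0.65, 0.65, 0.65))
  v <- viability(rec, "control")
  expect_equal(v$viability_pct[v$condition == "control"], 100)
  expect_equal(v$viability_pct[v$condition == "10uM"], 65)
  expect_equal(v$reduction_pct[v$condition == "10uM"], 35)
  blank <- rbind(rec, data.frame(well = "w7", condition = "blank", abs570 = 0))
  vb <- viability(blank, "control")
  expect_equal(vb$viability_pct[vb$condition == "blank"], 0)  # blank wells
  expect_error(viability(transform(rec, abs570 = 0), "control"),
               "control mean absorbance")
})
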