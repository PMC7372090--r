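test_that("genome copies follow from mass and the 1C value", {
  expect_identical(copies_from_mass(0.029, 1.43), 20L)
  expect_identical(copies_from_mass(0.00143, 1.43), 1L)
  expect_identical(copies_from_mass(150, 1.43), 104895L)
  expect_error(copies_from_mass(-1, 1.43), "positive")
  expect_error(copies_from_mass(1, 0), "positive")

  series <- petunia_calibration_series()
  expect_identical(nrow(series), 5L)
  # the recomputed and printed series agree exactly at the lowest point
  expect_identical(series$copies_recomputed[5], series$copies_printed[5])
  expect_identical(series$copies_recomputed[5], 20L)
})

test_that("efficiency follows the standard slope formula", {
  expect_lt(abs(efficiency_from_slope(-3.3219) - 100), 0.05)
  expect_lt(abs(efficiency_from_slope(-3.10) - 110.2), 0.1)
  expect_lt(abs(efficiency_from_slope(-3.60) - 89.6), 0.1)
  expect_error(efficiency_from_slope(3.3), "negative")
})

test_that("calibration fit recovers exact lines to machine precision", {
  copies <- c(1e5, 1e4, 1e3, 1e2, 20)
  slope <- -3.3219
  pts <- data.frame(copies = rep(copies, each = 2),
                    cq = rep(38 + slope * log10(copies), each = 2))
  curve <- fit_calibration(pts)
  expect_lt(abs(curve$slope - slope), 1e-9)
  expect_identical(round(curve$r_squared, 12), 1)
  expect_lt(abs(curve$efficiency_percent - 100), 0.01)

  expect_error(fit_calibration(data.frame(copies = c(10, 100),
                                          cq = c(30, 27))),
               "at least 3 distinct copy levels")
})

test_that("noisy calibration recovers the generating efficiency on average", {
  copies <- c(1e5, 1e4, 1e3, 1e2, 20)
  slope <- -3.4 # ~96.8% efficiency
  true_eff <- efficiency_from_slope(slope)
  effs <- vapply(1:200, function(s) {
    cq <- withr::with_seed(7000 + s,
      rep(38 + slope * log10(copies), each = 2) + rnorm(10, 0, 0.2))
    fit_calibration(data.frame(copies = rep(copies, each = 2),
                               cq = cq))$efficiency_percent
  }, 0)
  expect_lt(abs(mean(effs) - true_eff), 2)
})

test_that("the replicate simulator obeys doubling, censoring and seeding", {
  c100 <- simulate_qpcr_replicates(100, 1.0, 37, noise_sd = 0,
                                   n_replicates = 4, seed = 1,
                                   poisson = FALSE)
  c200 <- simulate_qpcr_replicates(200, 1.0, 37, noise_sd = 0,
                                   n_replicates = 4, seed = 1,
                                   poisson = FALSE)
  expect_equal(unique(c100 - c200), 1, tolerance = 1e-12)

  r1 <- simulate_qpcr_replicates(5, seed = 42)
  r2 <- simulate_qpcr_replicates(5, seed = 42)
  expect_identical(r1, r2)

  # single copies at a late intercept get censored at max_cycles
  late <- simulate_qpcr_replicates(1, 1.0, cq_intercept = 50, noise_sd = 0,
                                   n_replicates = 50, max_cycles = 45,
                                   seed = 3)
  expect_true(all(is.na(late)))
})

test_that("no-detection rate at one copy converges to the Poisson zero mass", {
  cq <- simulate_qpcr_replicates(1, n_replicates = 10000, seed = 11)
  p_nd <- mean(is.na(cq))
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 10000)
  expect_lt(abs(p_nd - exp(-1)), 3 * se)
})

test_that("detection probability approaches 1 - exp(-copies)", {
  for (c_ in c(1, 3, 5)) {
    cq <- simulate_qpcr_replicates(c_, n_replicates = 4000,
                                   seed = 100 + c_)
    p <- mean(!is.na(cq))
    expect_lt(abs(p - (1 - exp(-c_))),
              3 * sqrt(p * (1 - p) / 4000) + 1e-3)
  }
})

test_that("LOD rule returns the lowest all-positive level with consistent higher levels", {
  t1 <- detection_table(c(20, 10, 5, 1), c(10, 10, 9, 3))
  r1 <- lod_from_table(t1)
  expect_identical(r1$lod, 10)
  expect_true(r1$reached)
  expect_identical(r1$warning, "")

  t2 <- detection_table(c(20, 10, 5, 1), c(10, 10, 10, 10))
  r2 <- lod_from_table(t2)
  expect_identical(r2$lod, 1)
  expect_match(r2$warning, "below tested range")

  t3 <- detection_table(c(20, 10, 5, 1), c(10, 9, 10, 0))
  r3 <- lod_from_table(t3)
  expect_identical(r3$lod, 20)
  expect_match(r3$warning, "non-monotone")

  t4 <- detection_table(c(20, 10), c(9, 10))
  r4 <- lod_from_table(t4)
  expect_false(r4$reached)
  expect_true(is.na(r4$lod))
})

test_that("LOD is monotone under improving detections", {
  set.seed(401)
  for (rep in 1:50) {
    pos <- sample(0:10, 4, replace = TRUE)
    tab <- detection_table(c(40, 20, 10, 5), pos)
    base <- lod_from_table(tab)$lod
    i <- sample(4, 1)
    if (tab$positives[i] < 10) {
      tab2 <- tab
      tab2$positives[i] <- tab2$positives[i] + 1L
      improved <- lod_from_table(tab2)$lod
      if (!is.na(base)) {
        expect_true(!is.na(improved))
        expect_lte(improved, base)
      }
    }
  }
})

test_that("round trip: simulated dilution series recovers the set efficiency", {
  eff <- 0.95
  copies <- 10^(7:3)
  cq <- unlist(lapply(copies, function(cp)
    simulate_qpcr_replicates(cp, amplification_efficiency = eff,
                             cq_intercept = 40, noise_sd = 0,
                             n_replicates = 2, seed = 5,
                             poisson = FALSE)))
  curve <- fit_calibration(data.frame(copies = rep(copies, each = 2),
                                      cq = cq))
  expect_lt(abs(curve$efficiency_percent - 100 * eff), 0.5)
})

test_that("assay validation applies the acceptance windows", {
  copies <- c(1e5, 1e4, 1e3, 1e2, 20)
  make_curve <- function(eff) {
    slope <- -1 / log10(1 + eff / 100)
    fit_calibration(data.frame(copies = copies,
                               cq = 38 + slope * log10(copies)))
  }
  good <- validate_assay(make_curve(103.3),
                         detection_table(c(20, 10, 5, 1),
                                         c(10, 10, 9, 4)))
  expect_true(good$pass)
  expect_identical(good$lod$lod, 10)

  low_eff <- validate_assay(make_curve(85))
  expect_false(low_eff$pass)
  expect_false(low_eff$checks$efficiency$pass)
  expect_true(low_eff$checks$r_squared$pass)

  # deterministic curvature pushes R^2 below threshold
  bent <- fit_calibration(data.frame(
    copies = copies, cq = 38 - 3.32 * log10(copies) +
      c(1.5, -1.5, 1.5, -1.5, 1.5)))
  bad_r2 <- validate_assay(bent)
  expect_false(bad_r2$checks$r_squared$pass)
  expect_false(bad_r2$pass)
})
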