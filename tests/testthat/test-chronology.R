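flat_curves <- function(mu_t = 1000, mu_m = 1400, s_t = 10, s_m = 10) {
  t <- seq(0, 3000, by = 5)
  list(terrestrial = calcurve(t, rep(mu_t, length(t)), rep(s_t, length(t))),
       marine = calcurve(t, rep(mu_m, length(t)), rep(s_m, length(t))))
}

test_that("calibration curves load, interpolate linearly and validate", {
  path <- file.path(tempdir(), "toy.14c")
  writeLines(c("# toy curve", "0,100,10", "100,200,12", "200,260,10",
               "300,380,11", "400,470,10"), path)
  cv <- load_calcurve(path)
  expect_equal(length(cv$calbp), 5)
  mid <- curve_at(cv, 50)
  expect_equal(mid$mu, 150)   # linear midpoint
  expect_equal(mid$sigma, 11)
  expect_error(curve_at(cv, 1000), "out-of-range")
  # round-trip through write_calcurve
  p2 <- file.path(tempdir(), "toy2.14c")
  write_calcurve(cv, p2)
  cv2 <- load_calcurve(p2)
  expect_equal(cv2$calbp, cv$calbp)
  expect_equal(cv2$mu, cv$mu)
  # format errors
  bad <- file.path(tempdir(), "bad.14c")
  writeLines("0,100", bad)
  expect_error(load_calcurve(bad), "format-error")
  expect_error(calcurve(c(0, 0), c(1, 2), c(1, 1)), "monotone")
  expect_error(calcurve(c(0, 1), c(1, 2), c(1, 0)), "sigma")
})

test_that("curve mixing follows the diet-weighted formulas", {
  cv <- flat_curves()
  # p = 0: terrestrial regardless of deltaR
  m0 <- mixed_curve(cv$terrestrial, cv$marine, 0, -500, 1500)
  expect_equal(m0$mean, 1000)
  expect_equal(m0$sigma, 10)
  # p = 1 with deltaR +100
  m1 <- mixed_curve(cv$terrestrial, cv$marine, 1, 100, 1500)
  expect_equal(m1$mean, 1500)
  # half-and-half with deltaR -270
  mh <- mixed_curve(cv$terrestrial, cv$marine, 0.5, -270, 1500)
  expect_equal(mh$mean, 1065)
  expect_equal(mh$sigma, sqrt(0.25 * 100 + 0.25 * 100))
  expect_error(mixed_curve(cv$terrestrial, cv$marine, 1.4, 0, 100),
               "invalid-argument")
})

test_that("single calibration is a proper, correctly centred posterior", {
  # monotone linear curve: posterior is Normal in calendar time
  t <- seq(0, 3000, by = 5)
  curves <- list(terrestrial = calcurve(t, t, rep(5, length(t))),
                 marine = calcurve(t, t + 400, rep(5, length(t))))
  cal <- calibrate_single(1500, 20, curves)
  step <- diff(cal$calbp[1:2])
  expect_equal(sum(cal$density) * step, 1, tolerance = 1e-6)
  expect_equal(cal$median_bp, 1500, tolerance = 2.5)
  # sd of the posterior approximates sqrt(curve^2 + lab^2)
  m1 <- sum(cal$calbp * cal$density) * step
  v <- sum((cal$calbp - m1)^2 * cal$density) * step
  expect_equal(sqrt(v), sqrt(5^2 + 20^2), tolerance = 0.5)
  # HPD covers ~95 % and is centred
  expect_equal(unname(cal$hpd_bp[1, "hi_bp"] - cal$hpd_bp[1, "lo_bp"]),
               2 * 1.96 * sqrt(425), tolerance = 6)
  expect_equal(cal$median_ce, 1950 - 1500)
})

test_that("family models validate their determination bindings", {
  curves <- synthetic_calcurves()
  dets <- cao_c14_synthetic(curves)
  bad <- dets
  bad$individual[1] <- "nobody"
  expect_error(build_family_model(bad, ages = cao_age_ranges(),
                                  curves = curves), "config-error")
  m <- build_family_model(dets, ped = cao_pedigree(), ages = cao_age_ranges(),
                          deposition_members = c("B1", "B1s", "B2", "B3",
                                                 "B3s"),
                          curves = curves)
  expect_s3_class(m, "family_model")
  expect_equal(nrow(m$dets), 13)  # 5 human + 8 context
  # parent-child generation-gap constraint enforced in the log-posterior
  st <- paleokin:::fm_init(m)
  expect_true(is.finite(paleokin:::fm_logpost(m, st)))
  st2 <- st
  st2["birth_B1s"] <- st2["birth_B1"] + 5  # child born 5 y after parent
  expect_identical(paleokin:::fm_logpost(m, st2), -Inf)
})

test_that("an unconstrained single-date model equals single calibration", {
  curves <- synthetic_calcurves()
  ped1 <- data.frame(id = "A", sex = "F", mother = NA, father = NA,
                     birth_year = 480, age_at_death = 30,
                     mt_lineage = "mt1", sampled = TRUE,
                     stringsAsFactors = FALSE)
  det <- simulate_c14(ped1, c(A = 10), c(A = 0), deltaR = 0, curves,
                      sigma_lab = 20, seed = 5)
  m <- build_family_model(det, ped = NULL, ages = list(A = c(20, 40)),
                          deposition_members = character(0), curves = curves)
  post <- sample_posterior(m, n_iter = 2500, n_chains = 2, seed = 3)
  ev_year <- post$samples[, "birth_A"] + det$tissue_age[1]
  cal <- calibrate_single(det$c14_age[1], det$sigma[1], curves)
  expect_lt(abs(median(ev_year) - cal$median_ce), 12)
})

test_that("the family model recovers deposition year and reservoir offset", {
  curves <- synthetic_calcurves()
  ped <- cao_pedigree()
  mf <- cao_marine_fracs()
  fr <- stats::setNames(mf$marine_frac, mf$id)
  ta <- cao_tissue_ages()
  humans <- c("B1", "B1s", "B2", "B3s", "B4")
  dh <- simulate_c14(ped, ta[humans], fr[humans], deltaR = -270,
                     curves = curves, sigma_lab = 25, seed = 77)
  dh$marine_sd <- stats::setNames(mf$marine_sd, mf$id)[dh$individual]
  dc <- simulate_context_c14(8, 500, curves, 20, seed = 78)
  m <- build_family_model(rbind(dh, dc), ped = ped, ages = cao_age_ranges(),
                          deposition_members = c("B1", "B1s", "B2", "B3",
                                                 "B3s"),
                          curves = curves)
  post <- sample_posterior(m, n_iter = 2000, n_chains = 2, seed = 79)
  s <- post$summary
  expect_lt(abs(s["D", "median"] - 500), 30)
  expect_true(s["D", "lo"] <= 510 && s["D", "hi"] >= 490)
  expect_lt(abs(s["deltaR", "median"] + 270), 90)
  # B4, dated decades earlier, dies before the deposition event
  b4_death <- post$samples[, "birth_B4"] + post$samples[, "age_B4"]
  expect_gt(mean(b4_death < post$samples[, "D"]), 0.75)
  # agreement indices behave like OxCal ratios: high for consistent data
  expect_true(all(is.finite(post$agreement$agreement)))
  expect_gt(mean(post$agreement$agreement), 60)
  # posterior draws respect hard constraints
  gaps <- post$samples[, "birth_B1s"] - post$samples[, "birth_B1"]
  expect_true(all(gaps >= 12 & gaps <= 50))
})

test_that("HPD intervals are shortest intervals at the requested mass", {
  set.seed(91)
  x <- rnorm(20000)
  h <- paleokin:::hpd_interval(x, 0.95)
  expect_equal(unname(h["hi"] - h["lo"]), 2 * 1.96, tolerance = 0.1)
  expect_gt(mean(x >= h["lo"] & x <= h["hi"]), 0.94)
})
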