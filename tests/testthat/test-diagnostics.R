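test_that("threshold ordering flags exactly the non-monotone items", {
  cal <- pcm_calibration(c("ok", "bad", "dich"),
                         list(c(-2, -1, 0, 1), c(0, -1), 0.3))
  ord <- threshold_ordering(cal)
  expect_equal(ord$disordered, c(FALSE, TRUE, FALSE))
  expect_equal(ord$disordered_pairs[[2]], 1L)
  expect_equal(ord$disordered_pairs[[3]], integer(0)) # dichotomous: always ordered
})

test_that("standardized residuals have the documented closed forms", {
  # dichotomous item with P(1) = 0.5 at theta = tau: x = 1 -> z = +1, x = 0 -> z = -1
  cal <- pcm_calibration(c("A", "B"), list(0, c(-20, 20)))
  dat <- tibble::tibble(person_id = c("p1", "p2"),
                        A = c(1L, 0L), B = c(1L, 1L))
  fit <- list(calibration = cal,
              persons = tibble::tibble(person_id = dat$person_id,
                                       theta = c(0, 0), se = 1,
                                       raw_score = c(2, 1), max_raw = 3,
                                       n_answered = 2L, extreme = FALSE),
              scores = dat)
  class(fit) <- "rasch_fit"
  Z <- standardized_residuals(fit)
  expect_equal(unname(Z[1, "A"]), 1, tolerance = 1e-9)
  expect_equal(unname(Z[2, "A"]), -1, tolerance = 1e-9)
  # response equal to the expected score -> z = 0 (B's expected score is 1 at theta 0)
  expect_equal(unname(Z[1, "B"]), 0, tolerance = 1e-6)

  # on model-generated data the mean residual is near zero
  sim <- small_sim(n = 2000, n_items = 8, m = 3, seed = 11)
  fit2 <- rasch_calibrate(sim$responses)
  Z2 <- standardized_residuals(fit2)
  expect_lt(abs(mean(Z2, na.rm = TRUE)), 0.05)
})

test_that("fit residuals separate underfit, overfit and model-consistent items", {
  set.seed(201)
  n <- 1000
  bank <- sim_bank(10, max_score = 3)
  sim <- simulate_responses(sim_config(n_persons = n, bank = bank,
                                       theta_sd = 1.3, seed = 202))
  dat <- sim$responses
  # guessing contamination: randomize 30% of persons on I05 (underfit)
  noisy <- sample(n, 0.3 * n)
  dat$I05[noisy] <- sample(0:3, length(noisy), replace = TRUE)
  # perfect dependence: I08 cloned from I07 (overfit)
  dat$I08 <- dat$I07
  fit <- rasch_calibrate(dat)
  fr <- item_fit_residuals(fit)
  expect_gt(fr$fit_residual[fr$item == "I05"], 2.5)
  expect_lt(fr$fit_residual[fr$item == "I08"], -2.5)
  expect_true(fr$misfit_residual_flag[fr$item == "I05"])
  clean <- setdiff(fr$item, c("I05", "I07", "I08"))
  expect_true(mean(abs(fr$fit_residual[fr$item %in% clean]) <= 2.5) >= 6 / 7)

  # insufficient data -> statistic missing with a warning
  tiny <- simulate_responses(sim_config(
    n_persons = 25, bank = sim_bank(5, max_score = 1, location_range = c(-1, 1)),
    theta_sd = 1.2, seed = 12))
  fit2 <- rasch_calibrate(tiny$responses)
  expect_warning(fr2 <- item_fit_residuals(fit2), "Fit residual not computed")
  expect_true(all(is.na(fr2$fit_residual)))
})

test_that("class intervals respect the minimum size and ordering", {
  sim <- small_sim(n = 300, n_items = 8, m = 3, seed = 13)
  fit <- rasch_calibrate(sim$responses)
  ci <- class_intervals(fit, n_intervals = 10, min_size = 25)
  sizes <- table(ci)
  expect_true(all(sizes >= 25))
  # intervals are ordered by location
  means <- tapply(fit$persons$theta, ci, mean)
  expect_true(all(diff(means) > 0))
  expect_true(all(is.na(ci[fit$persons$extreme])))
})

test_that("item-trait chi-square flags an injected misfitting item", {
  set.seed(41)
  n <- 1000
  sim <- simulate_responses(sim_config(n_persons = n,
                                       bank = sim_bank(10, max_score = 3),
                                       theta_sd = 1.3, seed = 42))
  dat <- sim$responses
  noisy <- sample(n, 0.4 * n)
  dat$I04[noisy] <- sample(0:3, length(noisy), replace = TRUE)
  fit <- rasch_calibrate(dat)
  cs <- item_trait_chisq(fit)
  expect_true(all(cs$chisq >= 0))
  expect_true(all(cs$chisq_df >= 1))
  expect_true(cs$misfit_chisq_flag[cs$item == "I04"])

  # too few persons for two intervals -> explicit error
  tiny <- small_sim(n = 30, n_items = 5, m = 2, seed = 14)
  fit2 <- rasch_calibrate(tiny$responses)
  expect_error(item_trait_chisq(fit2), "at least 2 class intervals")
})

test_that("DIF ANOVA detects an injected uniform shift and validates factors", {
  sim <- simulate_responses(sim_config(
    n_persons = 1000, bank = sim_bank(10, max_score = 3), theta_sd = 1.3,
    dif = list(item = "I05", shift = 0.5, prop_focal = 0.5), seed = 15))
  fit <- rasch_calibrate(sim$responses)
  dif <- dif_anova(fit, sim$persons$group)
  expect_true(dif$flagged[dif$item == "I05"])
  expect_true(all(dif$main_p >= 0 & dif$main_p <= 1))
  # the flagged item should show the largest main effect
  expect_equal(dif$item[which.max(dif$main_F)], "I05")

  # single-level factor -> error; small levels merged with a warning
  expect_error(dif_anova(fit, rep("x", 1000)), "at least 2 levels")
  g <- sim$persons$group
  g[1:10] <- "rare"
  expect_warning(dif_anova(fit, g), "merged into 'other'")
})

test_that("residual correlations flag dependence with a strict criterion", {
  sim <- small_sim(n = 400, n_items = 6, m = 3, seed = 16)
  dat <- sim$responses
  dat$I06 <- dat$I05  # exact duplicate
  fit <- rasch_calibrate(dat)
  rc <- residual_correlations(fit)
  expect_true(isSymmetric(rc$matrix))
  expect_equal(unname(diag(rc$matrix)), rep(1, 6))
  pair <- rc$pairs[rc$pairs$item_a == "I05" & rc$pairs$item_b == "I06", ]
  expect_gt(pair$r, 0.9)
  expect_true(pair$flagged)
  # the criterion is strictly greater-than: a pair exactly at the cut-off
  # is acceptable, one just above it is not
  set.seed(91)
  Z <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  r_obs <- cor(Z[, 1], Z[, 2])
  rc_eq <- residual_correlations(Z, criterion = r_obs)
  expect_false(any(rc_eq$pairs$flagged))
  rc_lt <- residual_correlations(Z, criterion = r_obs - 1e-9)
  expect_true(all(rc_lt$pairs$flagged))
})

test_that("PSI follows its formula and responds to measurement error", {
  p <- tibble::tibble(person_id = 1:100, theta = rnorm(100), se = 0.5,
                      raw_score = 1, max_raw = 10, n_answered = 10L,
                      extreme = FALSE)
  v <- var(p$theta)
  expect_equal(person_separation_index(p), (v - 0.25) / v, tolerance = 1e-12)
  p$se <- 0
  expect_equal(person_separation_index(p), 1)
  p$se <- sqrt(v)
  expect_equal(person_separation_index(p), 0)
  p$se <- 10 * sqrt(v) # floored at zero
  expect_equal(person_separation_index(p), 0)
  # monotone in information: smaller errors -> higher PSI
  p1 <- p; p1$se <- 0.3
  p2 <- p; p2$se <- 0.6
  expect_gt(person_separation_index(p1), person_separation_index(p2))
})

test_that("targeting summarizes coverage, ceiling and binned distributions", {
  cal <- sim_bank(6, max_score = 2, location_range = c(-1.5, 1.5))
  p <- tibble::tibble(person_id = 1:200,
                      theta = seq(-2, 2, length.out = 200), se = 0.4,
                      raw_score = c(rep(6, 50), rep(12, 150)),
                      max_raw = 12, n_answered = 6L, extreme = FALSE)
  targ <- targeting_summary(p, cal)
  expect_equal(targ$threshold_min, min(unlist(cal$thresholds)))
  expect_equal(targ$threshold_max, max(unlist(cal$thresholds)))
  expect_equal(targ$prop_ceiling, 0.75)
  expect_equal(targ$prop_above_highest_threshold,
               mean(p$theta > targ$threshold_max))
  expect_equal(sum(targ$bins$persons), 200)
  expect_equal(sum(targ$bins$thresholds), 12)

  # all persons at the maximum raw score -> ceiling proportion 1
  p2 <- p; p2$raw_score <- 12
  expect_equal(targeting_summary(p2, cal)$prop_ceiling, 1.0)

  # persons drawn inside the threshold range -> above-coverage ~ 0
  sim <- simulate_responses(sim_config(
    n_persons = 500, bank = sim_bank(8, max_score = 3, location_range = c(-3, 3)),
    theta_sd = 0.5, seed = 17))
  persons <- estimate_persons(sim$responses, sim$truth$bank)
  targ2 <- targeting_summary(persons, sim$truth$bank)
  expect_lt(targ2$prop_above_highest_threshold, 0.02)
})

test_that("the full evaluation report covers every item once and composes its parts", {
  sim <- simulate_responses(sim_config(
    n_persons = 600, bank = sim_bank(10, max_score = 3), theta_sd = 1.3,
    dif = list(item = "I03", shift = 0.6),
    dependence = list(item = "I07", source = "I06", copy_prob = 1),
    disorder = "I05", seed = 18))
  instr <- generic_instrument(sim$truth$bank)
  raw <- scores_as_categories(sim$responses, instr)
  report <- evaluate_instrument(raw, instr, dif_factor = sim$persons$group)
  expect_s3_class(report, "vfq_report")
  expect_equal(sort(report$flags$item), sort(sim$truth$bank$item))
  expect_equal(anyDuplicated(report$flags$item), 0L)
  # flags reproduce the component operations
  expect_equal(report$flags$D_r,
               report$threshold_ordering$disordered[
                 match(report$flags$item, report$threshold_ordering$item)])
  expect_equal(report$flags$M_r,
               report$fit_residuals$misfit_residual_flag[
                 match(report$flags$item, report$fit_residuals$item)])
  dep_items <- unique(unlist(report$dependence$pairs[
    report$dependence$pairs$flagged, c("item_a", "item_b")]))
  expect_setequal(report$flags$item[report$flags$D_p], dep_items)
  # the three injections surface in the right sections
  expect_true(report$flags$D_r[report$flags$item == "I05"])
  expect_true(report$flags$D_f[report$flags$item == "I03"])
  expect_true(all(c("I06", "I07") %in% dep_items))
  expect_true(report$psi >= 0 && report$psi <= 1)
  g <- glance(report)
  expect_equal(g$n_items, 10L)
  td <- tidy(report)
  expect_equal(nrow(td), 10)
})
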