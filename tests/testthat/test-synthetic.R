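test_that("stage scripts: profiles honour their score guarantees", {
  for (seed in 1:5) {
    sh <- make_stage_script("stable_high", seed = seed)
    expect_gte(sh$true_score, 10)
    expect_length(sh$stages, 900)
    de <- make_stage_script("declining", seed = seed)
    expect_lte(de$true_score, 6)
  }
  early <- make_stage_script("declining", seed = 3, c_onset_s = 200)
  expect_equal(early$true_score, 1)
  expect_equal(which(early$stages == "C")[1], 201)
  expect_error(make_stage_script("sideways"), "unknown")
  expect_error(make_stage_script("stable_high", duration_s = 30), ">= 60")
})

test_that("generators are deterministic under a fixed seed", {
  s1 <- make_stage_script("fluctuating", duration_s = 120, seed = 9)
  s2 <- make_stage_script("fluctuating", duration_s = 120, seed = 9)
  expect_identical(s1$stages, s2$stages)
  r1 <- synthesize_recording(s1, seed = 10)
  r2 <- synthesize_recording(s1, seed = 10)
  expect_identical(r1$data, r2$data)
  c1 <- generate_cohort(cohort_config(n_non_hypo = 5, n_hypo = 3, seed = 11))
  c2 <- generate_cohort(cohort_config(n_non_hypo = 5, n_hypo = 3, seed = 11))
  expect_identical(c1, c2)
})

test_that("a zero-noise stage-0 recording stays below the alpha threshold", {
  script <- make_stage_script("custom", duration_s = 60, seed = 1,
                              stages = rep("0", 60))
  rec <- synthesize_recording(script, seed = 2, noise_uv = 0)
  pp <- preprocess_recording(rec)
  f <- segment_features(pp$rec)
  cfg <- classifier_config()
  expect_true(all(f$relative_alpha < cfg$alpha_rel_min))
})

test_that("clean recordings round-trip through the classifier at >= 90%", {
  for (case in list(list(prof = "stable_high", seed = 21),
                    list(prof = "fluctuating", seed = 22))) {
    script <- make_stage_script(case$prof, duration_s = 300,
                                seed = case$seed)
    rec <- synthesize_recording(script, seed = case$seed + 100)
    pp <- preprocess_recording(rec)
    sq <- classify_recording(pp$rec, pp$mask)
    keep <- !sq$artifact_mask
    agree <- mean(sq$stages[keep] == script$stages[keep])
    expect_gte(agree, 0.9)
  }
})

test_that("end-to-end stability-score recovery over seeded recordings", {
  profiles <- c("stable_high", "declining", "fluctuating")
  n_rec <- 12
  exact <- 0; within1 <- 0
  for (i in seq_len(n_rec)) {
    script <- make_stage_script(profiles[(i %% 3) + 1], duration_s = 900,
                                seed = 200 + i)
    rec <- synthesize_recording(script, seed = 300 + i)
    pp <- preprocess_recording(rec)
    expect_true(pp$usable)
    est <- stability_score(classify_recording(pp$rec, pp$mask))$score
    exact <- exact + (est == script$true_score)
    within1 <- within1 + (abs(est - script$true_score) <= 1)
  }
  expect_gte(exact / n_rec, 0.8)
  expect_equal(within1, n_rec)
})

test_that("cohort tables respect instrument ranges and group structure", {
  co <- generate_cohort(cohort_config(n_non_hypo = 40, n_hypo = 15,
                                      seed = 13))
  expect_equal(table(co$group)[["non_hypoaroused"]], 40)
  expect_equal(table(co$group)[["hypoaroused"]], 15)
  mfi <- as.matrix(co[, sprintf("mfi_%02d", 1:20)])
  expect_true(all(mfi >= 1 & mfi <= 5))
  bdi <- as.matrix(co[, sprintf("bdi_%02d", 1:21)])
  expect_true(all(bdi >= 0 & bdi <= 3))
  ess <- as.matrix(co[, sprintf("ess_%02d", 1:8)])
  expect_true(all(ess >= 0 & ess <= 3))
  expect_true(all(co$sss >= 1 & co$sss <= 7))
  expect_true(all(co$stability_score[co$group == "hypoaroused"] <= 6))
  expect_true(all(co$stability_score[co$group == "non_hypoaroused"] >= 7))
  # every generated subject is scoreable without exclusions
  sc <- score_cohort(co)
  expect_true(all(sc$included))
  expect_true(all(sc$general_fatigue >= 4 & sc$general_fatigue <= 20))
  # hypoaroused group is drawn with the higher trait-sleepiness mean
  expect_gt(mean(sc$ess_total[co$group == "hypoaroused"]) + 2,
            mean(sc$ess_total[co$group == "non_hypoaroused"]))
})

test_that("large-sample scale means match the configured group targets", {
  co <- generate_cohort(cohort_config(n_non_hypo = 10000, n_hypo = 10000,
                                      seed = 17))
  ess <- rowSums(co[, sprintf("ess_%02d", 1:8)])
  expect_lt(abs(mean(ess[co$group == "hypoaroused"]) - 10.4), 0.1)
  bdi <- rowSums(vapply(sprintf("bdi_%02d", 1:21),
                        function(cn) as.numeric(co[[cn]]),
                        numeric(nrow(co))))
  expect_lt(abs(mean(bdi[co$group == "hypoaroused"]) - 30.3), 0.3)
})

test_that("zero-effect cohorts reject at close to the nominal 5% rate", {
  cfg <- cohort_config(seed = 1)
  quest <- cfg$vars$var != "stability_score"  # group labels stay distinct
  cfg$vars$mean_hypo[quest] <- cfg$vars$mean_non_hypo[quest]
  cfg$vars$sd_hypo[quest] <- cfg$vars$sd_non_hypo[quest]
  n_sim <- 400
  rej <- 0
  for (i in seq_len(n_sim)) {
    cfg$seed <- 5000 + i
    co <- generate_cohort(cfg)
    ess <- rowSums(co[, sprintf("ess_%02d", 1:8)])
    p <- mann_whitney(ess[co$group == "non_hypoaroused"],
                      ess[co$group == "hypoaroused"])$p
    rej <- rej + (p < 0.05)
  }
  # binomial MC tolerance around 0.05 at 400 simulations
  expect_gt(rej / n_sim, 0.02)
  expect_lt(rej / n_sim, 0.09)
})

test_that("infeasible cohort means are rejected", {
  cfg <- cohort_config(seed = 1)
  cfg$vars$mean_hypo[cfg$vars$var == "ess_total"] <- 30
  expect_error(generate_cohort(cfg), "infeasible")
  expect_error(cohort_config(n_hypo = 1), "at least 2")
})
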