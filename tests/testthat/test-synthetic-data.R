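test_that("packaged distribution defaults carry the published group parameters", {
  d <- default_distributions()
  get <- function(g, v, tp) d[d$group == g & d$variable == v &
                                d$time_point == tp, c("mean", "sd")]
  expect_equal(unlist(get("responder", "SVV", "T1"), use.names = FALSE),
               c(5.5, 2.4))
  expect_equal(unlist(get("responder", "SVV", "D12"), use.names = FALSE),
               c(2.3, 1.7))
  expect_equal(unlist(get("nonresponder", "PPV", "D12"), use.names = FALSE),
               c(-0.7, 1.8))
  expect_equal(unlist(get("responder", "SV", "T3"), use.names = FALSE),
               c(63.1, 17.2))
  # keys are unique and sds non-negative (validated on read)
  expect_silent(read_distribution_spec(
    system.file("extdata", "group_distributions.csv",
                package = "peepchallenge")))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(seed = 11)
  b <- generate_cohort(seed = 11)
  expect_identical(a, b)
  c <- generate_cohort(seed = 12)
  expect_false(identical(a$PPV_T1, c$PPV_T1))
})

test_that("zero-sd distributions yield the group means exactly", {
  d <- default_distributions()
  d$sd <- 0
  co <- generate_cohort(seed = 1, dists = d)
  resp <- co[co$group == "responder", ]
  expect_equal(resp$delta_svv, rep(2.3, 18), tolerance = 1e-12)
  expect_equal(resp$delta_ppv, rep(1.9, 18), tolerance = 1e-12)
  expect_equal(resp$SVV_T2, rep(5.5 + 2.3, 18), tolerance = 1e-12)
  nonr <- co[co$group == "nonresponder", ]
  expect_equal(nonr$delta_ppv, rep(-0.7, 22), tolerance = 1e-12)
  # all patients within a group identical
  expect_equal(nrow(unique(resp[setdiff(names(resp), "patient_id")])), 1)
})

test_that("sample moments recover the configured distributions (law of large numbers)", {
  co <- generate_cohort(n_responders = 10000, n_nonresponders = 10000,
                        seed = 2)
  dppv <- co$delta_ppv[co$group == "responder"]
  se <- 1.7 / sqrt(10000)
  expect_lt(abs(mean(dppv) - 1.9), 3 * se)
  expect_lt(abs(sd(dppv) - 1.7), 0.1)
  # deltas are computed from the drawn levels, never drawn independently
  expect_equal(co$delta_svv, co$SVV_T2 - co$SVV_T1, tolerance = 1e-12)
})

test_that("generated responder delta-SVV passes a KS screen against its normal target", {
  set.seed(303)
  co <- generate_cohort(n_responders = 2000, n_nonresponders = 1,
                        seed = 303)
  x <- co$delta_svv[co$group == "responder"]
  ks <- suppressWarnings(ks.test(x, "pnorm", 2.3, 1.7))
  expect_gt(ks$p.value, 0.01)
})

test_that("group separation matches the closed-form binormal AUC at large n", {
  # expected AUC of delta-SVV under the published group parameters
  expected <- binormal_auc(2.3, 1.7, -0.5, 1.8)
  expect_equal(expected, 0.871, tolerance = 0.001)
  co <- generate_cohort(n_responders = 50000, n_nonresponders = 50000,
                        seed = 4)
  auc <- peepchallenge:::auc_statistic(co$delta_svv, co$responder)
  expect_lt(abs(auc - expected), 0.005)
})

test_that("beat simulation recovers the target indices under dense noise-free sampling", {
  # 64 beats per cycle: discretization error below half a percentage point
  for (sd in 1:5) {
    b <- generate_beats(target_ppv = 40, target_svv = 25, heart_rate = 640,
                        resp_rate = 10, n_cycles = 4, seed = sd)
    r <- averaged_reading(b, k = 3)
    expect_lt(abs(r$ppv - 40), 0.5)
    expect_lt(abs(r$svv - 25), 0.5)
  }
  # zero modulation gives exactly zero indices
  b0 <- generate_beats(target_ppv = 0, target_svv = 0, heart_rate = 80,
                       resp_rate = 10, n_cycles = 4, seed = 1)
  r0 <- averaged_reading(b0, k = 3)
  expect_equal(r0$ppv, 0)
  expect_equal(r0$svv, 0)
})

test_that("parameter recovery holds on average over many simulated patients", {
  set.seed(99)
  err <- replicate(200, {
    target <- runif(1, 2, 20)
    b <- generate_beats(target_ppv = target, target_svv = target,
                        heart_rate = 320, resp_rate = 10, n_cycles = 4)
    abs(averaged_reading(b, k = 3)$ppv - target)
  })
  expect_lt(mean(err), 0.5)
})

test_that("coarse sampling under-reads the envelope within the predictable band", {
  # 6 beats per respiratory cycle (typical HR/RR ratio during OLV)
  for (sd in 1:10) {
    b <- generate_beats(target_ppv = 6, target_svv = 6, heart_rate = 72,
                        resp_rate = 12, n_cycles = 4, seed = sd)
    r <- averaged_reading(b, k = 3)
    expect_gte(r$ppv, 4.5)
    expect_lte(r$ppv, 6 + 1e-9)
  }
})

test_that("beat simulation rejects configs that cannot resolve a cycle", {
  expect_error(generate_beats(5, 5, heart_rate = 60, resp_rate = 40),
               "at least 2")
  expect_error(generate_beats(-1, 5), "\\[0, 100\\)")
})

test_that("end-to-end cohort indices match the drawn targets under dense sampling", {
  co <- end_to_end_cohort(n_responders = 6, n_nonresponders = 6, seed = 8,
                          beat_template = list(heart_rate = 640,
                                               resp_rate = 10,
                                               phase = "aligned"))
  targets <- attr(co, "index_targets")
  rel <- abs(co$PPV_T1 - targets$PPV_T1) / targets$PPV_T1
  expect_lt(max(rel), 0.01)
  rel2 <- abs(co$SVV_T2 - targets$SVV_T2) / targets$SVV_T2
  expect_lt(max(rel2), 0.01)
  # deltas recomputed from the computed values
  expect_equal(co$delta_ppv, co$PPV_T2 - co$PPV_T1, tolerance = 1e-12)
  # determinism
  co2 <- end_to_end_cohort(n_responders = 6, n_nonresponders = 6, seed = 8,
                           beat_template = list(heart_rate = 640,
                                                resp_rate = 10,
                                                phase = "aligned"))
  expect_identical(co, co2)
})

test_that("derived labels reproduce the stroke-volume rule", {
  co <- end_to_end_cohort(seed = 21, label_mode = "derived",
                          beat_template = list(heart_rate = 320,
                                               resp_rate = 10))
  expect_equal(co$responder,
               percent_sv_change(co$SV_T3, co$SV_T4) >= 10)
})

test_that("cohort CSV round-trips through the writer/reader", {
  co <- generate_cohort(seed = 31)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(back$delta_svv, co$delta_svv, tolerance = 1e-9)
  expect_identical(back$responder, co$responder)
})

test_that("missing distribution keys are reported by name", {
  d <- default_distributions()
  d <- d[!(d$variable == "PPV"), ]
  expect_error(end_to_end_cohort(dists = d), "PPV")
})
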