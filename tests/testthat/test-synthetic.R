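test_that("modular time series hit their correlation targets", {
  memb <- sort(rep_len(1:4, 40))
  # independence case: all off-diagonal correlations near 0
  ts0 <- generate_modular_timeseries(40, 5000, memb, 0, 0, seed = 1)
  R0 <- cor(t(ts0$values))
  expect_lt(max(abs(R0[upper.tri(R0)])), 0.1)

  # planted structure: empirical within/between means near targets
  ts1 <- generate_modular_timeseries(40, 5000, memb, 0.6, 0.1, seed = 2)
  R1 <- cor(t(ts1$values))
  same <- outer(memb, memb, "==") & upper.tri(R1)
  diff <- !outer(memb, memb, "==") & upper.tri(R1)
  expect_lt(abs(mean(R1[same]) - 0.6), 0.05)
  expect_lt(abs(mean(R1[diff]) - 0.1), 0.05)

  # determinism
  ts2 <- generate_modular_timeseries(40, 5000, memb, 0.6, 0.1, seed = 2)
  expect_identical(ts1$values, ts2$values)

  # degenerate targets rejected with a diagnostic
  expect_error(generate_modular_timeseries(40, 100, memb, 0.2, 0.5,
                                           seed = 1),
               "positive")
})

test_that("community detection recovers the planted partition", {
  skip_if_not_installed("mclust")
  memb <- sort(rep_len(1:4, 40))
  ts <- generate_modular_timeseries(40, 2000, memb, 0.6, 0.1, seed = 3)
  C <- pearson_matrix(ts)
  G <- threshold_proportional(C, 0.2)
  part <- graph_modularity(G, seed = 4)$partition
  ari <- mclust::adjustedRandIndex(part, memb)
  expect_gt(ari, 0.9)
})

test_that("motion spikes behave as designed and are visible to DVARS", {
  ts <- generate_modular_timeseries(10, 300, rep(1, 10), 0.3, 0, seed = 5)
  ts$values <- ts$values + 15
  # zero rate is the identity
  same <- inject_motion_spikes(ts, 0, 5, seed = 1)
  expect_identical(same$values, ts$values)
  expect_length(attr(same, "spike_volumes"), 0)

  # a single large spike dominates the DVARS series at its volume
  one <- ts
  k <- 150
  amp <- 10 * sd(ts$values)
  one$values[, k] <- one$values[, k] + amp
  dv <- compute_dvars(one)$dvars_series
  expect_true(which.max(dv) %in% c(k - 1, k))
  # direct formula oracle at the spiked transition
  d <- one$values[, k] - one$values[, k - 1]
  expect_equal(compute_dvars(one, scale = "raw")$dvars_series[k - 1],
               sqrt(mean(d^2)), tolerance = 1e-12)

  # full-rate spiking strictly inflates mean DVARS
  allsp <- inject_motion_spikes(ts, 1, 3, seed = 2)
  expect_gt(compute_dvars(allsp)$dvars_mean, compute_dvars(ts)$dvars_mean)
  expect_error(inject_motion_spikes(ts, 1.5, 3), "spike_rate")
})

test_that("cohorts are deterministic with valid structure and clinical table", {
  sp <- cohort_spec(n_subjects = 4, n_nodes = 20, n_timepoints = 60,
                    n_modules = 4, effect_beta = 0, seed = 11)
  coh1 <- suppressWarnings(generate_cohort(sp))
  coh2 <- suppressWarnings(generate_cohort(sp))
  expect_identical(coh1$timeseries[[3]]$post$values,
                   coh2$timeseries[[3]]$post$values)
  expect_identical(coh1$clinical, coh2$clinical)

  # membership partitions all nodes
  expect_length(coh1$membership, 20)
  expect_setequal(unique(coh1$membership), 1:4)

  # clinical table: one row per subject, no missing primary outcome
  expect_equal(nrow(coh1$clinical), 4)
  expect_false(anyNA(coh1$clinical$ybocs_pre))
  expect_false(anyNA(coh1$clinical$ybocs_followup))
  expect_true(all(coh1$clinical$ybocs_pre >= 0 &
                    coh1$clinical$ybocs_pre <= 40))
  expect_true(all(coh1$clinical$months_followup > 0))

  # seed is mandatory
  expect_error(cohort_spec(n_subjects = 2), "seed")
})

test_that("clinical score distributions match their calibration targets", {
  sp <- cohort_spec(n_subjects = 5000, n_nodes = 4, n_timepoints = 50,
                    n_modules = 2, effect_beta = 0,
                    motion_spike_rate = 0, seed = 21)
  coh <- suppressWarnings(generate_cohort(sp))
  cl <- coh$clinical
  expect_lt(abs(mean(cl$ybocs_pre) - 23.12), 0.2)
  expect_lt(abs(mean(cl$ybocs_post) - 13.76), 0.25)
  expect_lt(abs(sd(cl$ybocs_pre) - 3.04), 0.25)
  # mean percent improvement lands in the clinically observed range
  out <- classify_outcomes(cl)
  expect_gt(mean(out$flags$pct_change), 30)
  expect_lt(mean(out$flags$pct_change), 50)
  expect_gt(out$rates[["response"]], 35)
  expect_gt(out$rates[["remission"]], 40)
})

test_that("pre-to-post connectivity delta raises clustering and modularity
          tracks the planted contrast", {
  sp <- cohort_spec(n_subjects = 6, n_nodes = 40, n_timepoints = 300,
                    n_modules = 4, within_r = 0.4, between_r = 0.1,
                    post_within_r_delta = 0.25, effect_beta = 0,
                    motion_spike_rate = 0, seed = 31)
  coh <- suppressWarnings(generate_cohort(sp))
  cm <- cohort_metrics(coh, grid = c(0.15, 0.3), n_rand = 0,
                       metrics = "C", seed = 1)
  a <- cm$auc
  pre <- a$auc[a$session == "pre"]
  post <- a$auc[a$session == "post"]
  expect_gt(mean(post - pre), 0)

  # modularity of the estimated network rises with within - between
  qs <- vapply(c(0.2, 0.4, 0.6), function(w) {
    ts <- generate_modular_timeseries(40, 800, sort(rep_len(1:4, 40)), w,
                                      0.1, seed = 41)
    C <- partial_correlation_matrix(ts)
    G <- threshold_proportional(C, 0.2)
    graph_modularity(G, seed = 5)$Q
  }, 1.0)
  expect_true(all(diff(qs) > 0))
})

test_that("cohort files round-trip to disk with provenance", {
  sp <- cohort_spec(n_subjects = 2, n_nodes = 10, n_timepoints = 60,
                    n_modules = 2, effect_beta = 0, seed = 51)
  coh <- suppressWarnings(generate_cohort(sp))
  d <- file.path(tempdir(), "cohtest")
  write_cohort(coh, d)
  expect_true(file.exists(file.path(d, "sub001_pre.tsv")))
  expect_true(file.exists(file.path(d, "clinical.csv")))
  prov <- jsonlite::read_json(file.path(d, "cohort.json"))
  expect_equal(prov$seed, 51)
  back <- read_timeseries(file.path(d, "sub002_post.tsv"))
  expect_equal(back$values, coh$timeseries[[2]]$post$values,
               tolerance = 1e-9, ignore_attr = TRUE)
  unlink(d, recursive = TRUE)
})
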