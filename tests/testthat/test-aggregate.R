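test_that("trapezoidal AUC: closed forms and refinement oracle", {
  g <- seq(0.1, 0.5, by = 0.05)
  expect_equal(auc(rep(3, length(g)), g), 0.4 * 3, tolerance = 1e-12)
  expect_equal(auc(g, g), (0.5^2 - 0.1^2) / 2, tolerance = 1e-12)
  # smooth curve: trapezoid on the coarse grid near fine-grid integral
  f <- function(s) sin(4 * s) + s^2
  fine <- seq(0.1, 0.5, length.out = 4001)
  expect_lt(abs(auc(f(g), g) - auc(f(fine), fine)), 1e-3)
  expect_error(auc(1, 0.3), "length >= 2")
})

test_that("motion residualization removes DVARS association", {
  set.seed(1)
  n <- 20
  dv <- data.frame(subject_id = rep(sprintf("s%02d", 1:n), each = 2),
                   session = rep(c("pre", "post"), n),
                   dvars = runif(2 * n, 8, 12))
  at <- data.frame(subject_id = dv$subject_id, session = dv$session,
                   metric = "C", auc = 0.5 + 0.03 * dv$dvars +
                     rnorm(2 * n, 0, 0.01))
  class(at) <- c("auc_table", "data.frame")
  adj <- residualize_on_motion(at, dv)
  expect_lt(abs(cor(adj$auc, dv$dvars)), 1e-10)
  expect_equal(mean(adj$auc), mean(at$auc), tolerance = 1e-12)

  # AUC perfectly linear in DVARS -> residual variance 0
  at2 <- at
  at2$auc <- 1 + 2 * dv$dvars
  adj2 <- residualize_on_motion(at2, dv)
  expect_lt(var(adj2$auc), 1e-20)

  # orthogonal DVARS leaves the table (essentially) unchanged
  at3 <- at
  at3$auc <- rnorm(2 * n)
  at3$auc <- at3$auc - lm(at3$auc ~ dv$dvars)$fitted + mean(at3$auc)
  adj3 <- residualize_on_motion(at3, dv)
  expect_equal(adj3$auc, at3$auc, tolerance = 1e-10)

  dv0 <- dv
  dv0$dvars <- 9
  expect_warning(residualize_on_motion(at, dv0), "zero variance")
})

test_that("paired change test: degenerate, exhaustive and branch logic", {
  x <- c(3, 5, 2, 8, 4)
  r0 <- paired_change_test(x, x)
  expect_equal(r0$p, 1)
  expect_match(r0$method, "degenerate")

  # exhaustive sign-flip at n = 5 matches hand enumeration
  pre <- c(10, 12, 9, 14, 11)
  post <- c(14, 13, 15, 18, 10)
  d <- post - pre
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
  perm_means <- abs(as.numeric(signs %*% d) / 5)
  p_hand <- mean(perm_means >= abs(mean(d)) - 1e-12)
  r <- paired_change_test(pre, post, normality_alpha = 1)  # force perm branch
  expect_match(r$method, "exhaustive")
  expect_equal(r$p, p_hand, tolerance = 1e-12)

  # normal-looking differences use the paired t branch
  set.seed(2)
  a <- rnorm(30); b <- a + rnorm(30, 0.5)
  rt <- paired_change_test(a, b)
  expect_match(rt$method, "paired t")
  expect_equal(rt$p, t.test(b, a, paired = TRUE)$p.value)

  # heavy-tailed differences fall through to permutation
  set.seed(3)
  dd <- rcauchy(15)
  rp <- paired_change_test(rep(0, 15), dd)
  expect_match(rp$method, "permutation")
})

test_that("paired change p values are calibrated under the Gaussian null", {
  set.seed(4)
  ps <- vapply(1:1000, function(i) {
    pre <- rnorm(17); post <- pre + rnorm(17)
    paired_change_test(pre, post, seed = i)$p
  }, 1.0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lte(mean(ps < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("partial correlation matches the recursive formula", {
  set.seed(5)
  n <- 200
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.3 * z + rnorm(n)
  r <- partial_corr(x, y, cbind(z))
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(r$effect, oracle, tolerance = 1e-10)
  expect_equal(r$df, n - 3)

  # no covariates reduces to the plain Pearson test
  r2 <- partial_corr(x, y)
  ct <- cor.test(x, y)
  expect_equal(r2$effect, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r2$p, ct$p.value, tolerance = 1e-12)

  # y = x gives r = 1 whatever the (non-collinear) covariates
  expect_equal(partial_corr(x, x, cbind(z))$effect, 1, tolerance = 1e-12)
})

test_that("follow-up regression: interpolation, null, normal equations", {
  set.seed(6)
  n <- 17
  cl <- data.frame(subject_id = sprintf("s%02d", 1:n),
                   ybocs_post = round(rnorm(n, 14, 4)),
                   months_followup = pmax(1, round(rnorm(n, 7, 4))),
                   medication_months = rbinom(n, 6, 0.3),
                   cbt_sessions = rpois(n, 5),
                   dvars_pre = rnorm(n, 9.7, 1.5))
  aucv <- rnorm(n, 1.1, 0.1)
  # noiseless planted linear outcome is interpolated exactly
  cl$ybocs_followup <- cl$ybocs_post + 2 + 30 * aucv -
    0.5 * cl$months_followup + 0.2 * cl$medication_months +
    0.1 * cl$cbt_sessions + 0.3 * cl$dvars_pre
  fit <- suppressWarnings(fit_followup_regression(cl, aucv))
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["auc"]), 30, tolerance = 1e-6)

  # coefficients match the normal-equation oracle on a noisy fixture
  cl$ybocs_followup <- cl$ybocs_post + round(rnorm(n, 2, 5))
  fit2 <- fit_followup_regression(cl, aucv)
  X <- cbind(1, aucv, cl$months_followup, cl$medication_months,
             cl$cbt_sessions, cl$dvars_pre)
  y <- cl$ybocs_followup - cl$ybocs_post
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(coef(fit2)), as.numeric(beta), tolerance = 1e-10)
  expect_equal(unname(fit2$df), c(5, n - 6))
  # adjusted R^2 identity
  expect_equal(fit2$adj_r_squared,
               1 - (1 - fit2$r_squared) * (n - 1) / (n - 5 - 1),
               tolerance = 1e-12)

  # independent outcome at n = 200: adjusted R^2 near zero on average
  set.seed(7)
  vals <- vapply(1:100, function(i) {
    m <- 200
    cl2 <- data.frame(subject_id = seq_len(m),
                      ybocs_post = round(rnorm(m, 14, 4)),
                      ybocs_followup = round(rnorm(m, 15, 6)),
                      months_followup = pmax(1, round(rnorm(m, 7, 4))),
                      medication_months = rbinom(m, 6, 0.3),
                      cbt_sessions = rpois(m, 5),
                      dvars_pre = rnorm(m, 9.7, 1.5))
    fit_followup_regression(cl2, rnorm(m))$adj_r_squared
  }, 1.0)
  expect_lt(abs(mean(vals)), 0.05)

  # collinear design is rejected with a diagnostic
  cl$medication_months <- cl$cbt_sessions
  expect_error(fit_followup_regression(cl, aucv), "collinear")
})

test_that("corrected thresholds reproduce conventional printed values", {
  expect_equal(attr(bonferroni_alpha(0.05, 3), "printed"), 0.017)
  expect_equal(as.numeric(bonferroni_alpha(0.05, 3)), 0.05 / 3)
  expect_equal(attr(bonferroni_alpha(0.05, 6, digits = 4), "printed"),
               0.0083)
  expect_equal(attr(bonferroni_alpha(0.05, 4, digits = 4), "printed"),
               0.0125)
  expect_equal(attr(bonferroni_alpha(0.05, 12), "printed"), 0.004)
  expect_equal(as.numeric(bonferroni_alpha(0.05, 1)), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "m")
})

test_that("BH FDR matches the step-up definition", {
  expect_length(fdr_bh(rep(1, 10), 0.05)$rejected, 0)
  expect_equal(fdr_bh(0.01, 0.0125)$rejected, 1L)
  expect_identical(fdr_bh(numeric(0))$rejected, integer(0))

  set.seed(8)
  p <- c(runif(15), runif(5, 0, 0.002))
  q <- 0.05
  got <- fdr_bh(p, q)
  # direct step-up oracle: largest i with p_(i) <= i q / m
  m <- length(p)
  o <- order(p)
  i_max <- max(c(0, which(p[o] <= seq_len(m) * q / m)))
  oracle_rej <- if (i_max == 0) integer(0) else sort(o[seq_len(i_max)])
  expect_identical(sort(got$rejected), oracle_rej)
})

test_that("outcome classification applies the clinical definitions", {
  cl <- data.frame(subject_id = c("a", "b", "c"),
                   ybocs_pre = c(23, 20, 25),
                   ybocs_post = c(14, 13, 13),
                   ybocs_followup = c(15, 14, 18),
                   cgi_post = c(2, 3, 1))
  out <- classify_outcomes(cl)
  # a: 39.1% reduction + CGI 2 -> responder and remitter, +1 not worsened
  expect_true(out$flags$responder[1] && out$flags$remitter[1])
  expect_false(out$flags$worsened[1])
  # b: 35% reduction but CGI 3 -> not a responder, still remitter
  expect_false(out$flags$responder[2])
  expect_true(out$flags$remitter[2])
  # c: +5 points post -> follow-up is clinically significant worsening
  expect_true(out$flags$worsened[3])
  expect_equal(unname(out$rates["worsening"]), 100 / 3, tolerance = 1e-12)
  expect_error(classify_outcomes(transform(cl, ybocs_pre = c(0, 20, 25))),
               "ybocs_pre")
})

test_that("node-level change analysis rejects planted shifts, controls FDR", {
  set.seed(9)
  n_sub <- 40; n_node <- 25
  pre <- matrix(rnorm(n_sub * n_node), n_sub, n_node)
  post <- pre + matrix(rnorm(n_sub * n_node, 0, 0.6), n_sub, n_node)
  post[, 7] <- post[, 7] + 1.5          # planted shift at node 7
  colnames(pre) <- colnames(post) <- sprintf("n%03d", 1:n_node)
  res <- node_level_change_analysis(pre, post, q = 0.0125)
  expect_true(res$rejected[7])

  # identical sessions: nothing rejected
  res0 <- node_level_change_analysis(pre, pre)
  expect_false(any(res0$rejected))

  # handoff equals manual fdr_bh composition
  bh <- fdr_bh(res$p, 0.0125)
  expect_identical(which(res$rejected), bh$rejected)
  expect_equal(res$p_adjusted, bh$adjusted)

  # false-positive control under the null, averaged over seeds
  fp <- vapply(1:10, function(s) {
    set.seed(100 + s)
    a <- matrix(rnorm(n_sub * n_node), n_sub, n_node)
    b <- a + matrix(rnorm(n_sub * n_node, 0, 0.6), n_sub, n_node)
    colnames(a) <- colnames(b) <- sprintf("n%03d", 1:n_node)
    sum(node_level_change_analysis(a, b, q = 0.0125)$rejected)
  }, 1.0)
  expect_lte(mean(fp), 0.0125 * n_node + 0.15)

  expect_error(node_level_change_analysis(pre, post[, 1:10]), "shape")
})
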