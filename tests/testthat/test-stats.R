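test_that("two-level within designs reduce to the paired t-test", {
  set.seed(20)
  for (i in 1:30) {
    n <- sample(5:15, 1)
    d <- data.frame(participant = rep(seq_len(n), each = 2),
                    cond = rep(c("a", "b"), n),
                    amplitude = rnorm(2 * n))
    an <- rm_anova(d, "amplitude", "participant", within = "cond")
    tt <- t.test(d$amplitude[d$cond == "a"], d$amplitude[d$cond == "b"],
                 paired = TRUE)
    expect_equal(an$F[1], unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(an$p[1], tt$p.value, tolerance = 1e-8)
    expect_equal(an$epsilon[1], 1)
  }
})

test_that("mixed designs agree with the aov error-strata oracle", {
  set.seed(21)
  d <- expand.grid(participant = 1:10, w1 = c("c", "n"),
                   w2 = c("x", "y", "z"))
  d$group <- ifelse(d$participant <= 5, "g1", "g2")
  d$amplitude <- rnorm(nrow(d)) + as.numeric(factor(d$w2)) * 0.4 +
    ifelse(d$group == "g1", 0.3, 0)
  an <- rm_anova(d, "amplitude", "participant", within = c("w1", "w2"),
                 between = "group")
  dd <- d
  for (col in c("participant", "w1", "w2", "group"))
    dd[[col]] <- factor(dd[[col]])
  ao <- summary(stats::aov(amplitude ~ group * w1 * w2 +
                             Error(participant / (w1 * w2)), data = dd))
  get_f <- function(stratum, term) {
    tab <- ao[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  expect_equal(an$F[an$effect == "group"], get_f("Error: participant", "group"),
               tolerance = 1e-8)
  expect_equal(an$F[an$effect == "w1"], get_f("Error: participant:w1", "w1"),
               tolerance = 1e-8)
  expect_equal(an$F[an$effect == "w2"], get_f("Error: participant:w2", "w2"),
               tolerance = 1e-8)
  expect_equal(an$F[an$effect == "w2:group"],
               get_f("Error: participant:w2", "group:w2"), tolerance = 1e-8)
  expect_equal(an$F[an$effect == "w1:w2"],
               get_f("Error: participant:w1:w2", "w1:w2"), tolerance = 1e-8)
  ## partial eta squared stays in [0, 1]; epsilon in (0, 1]
  expect_true(all(an$partial_eta_sq >= 0 & an$partial_eta_sq <= 1))
  expect_true(all(is.na(an$epsilon) | (an$epsilon > 0 & an$epsilon <= 1)))
})

test_that("degenerate and malformed ANOVA inputs are handled", {
  d <- expand.grid(participant = 1:6, cond = c("a", "b"))
  d$amplitude <- 1
  an <- rm_anova(d, "amplitude", "participant", within = "cond")
  expect_equal(an$F, 0)
  expect_equal(an$partial_eta_sq, 0)
  expect_error(rm_anova(d[-1, ], "amplitude", "participant", within = "cond"),
               "balanced")
  expect_error(rm_anova(d, "nope", "participant", within = "cond"),
               "not found")
})

test_that("Greenhouse-Geisser correction engages under sphericity violation", {
  set.seed(22)
  n <- 20
  ## construct strongly non-spherical within-subject data (4 levels)
  base <- rnorm(n)
  d <- do.call(rbind, lapply(1:4, function(l) data.frame(
    participant = seq_len(n), cond = letters[l],
    amplitude = base * l + rnorm(n, sd = ifelse(l == 1, 0.05, 2 * l)))))
  an <- rm_anova(d, "amplitude", "participant", within = "cond")
  expect_lt(an$epsilon[1], 0.9)
  expect_lt(an$mauchly_p[1], 0.05)
  expect_true(an$gg_applied[1])
  expect_lt(an$df_num[1], 3)
})

test_that("BH-FDR adjustment matches the brute-force definition", {
  expect_equal(fdr_adjust(0.42), 0.42)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(23)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("paired contrasts flag degenerate cells and adjust jointly", {
  set.seed(24)
  cells <- cbind(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10))
  out <- paired_contrasts(cells, list(c("a", "b"), c("a", "c"),
                                      c("b", "c")))
  expect_equal(out$p_fdr, fdr_adjust(out$p))
  ## identical vectors -> t = 0, p = 1
  same <- cbind(a = rnorm(6), b = 0)
  same[, "b"] <- same[, "a"]
  o2 <- paired_contrasts(same, list(c("a", "b")))
  expect_equal(o2$t, 0)
  expect_equal(o2$p, 1)
  ## constant nonzero difference -> degenerate flag
  shift <- cbind(a = 1:6, b = 1:6 + 2)
  o3 <- paired_contrasts(shift, list(c("a", "b")))
  expect_true(o3$degenerate)
  expect_true(is.na(o3$t))
})

test_that("JZS Bayes factors behave sensibly", {
  make_d <- function(effect, seed) {
    set.seed(seed)
    noise <- rnorm(32)
    ## remove the chance condition difference so the injected effect is exact
    noise[seq(1, 32, 2)] <- noise[seq(1, 32, 2)] - mean(noise[seq(1, 32, 2)])
    noise[seq(2, 32, 2)] <- noise[seq(2, 32, 2)] - mean(noise[seq(2, 32, 2)])
    data.frame(participant = rep(1:16, each = 2),
               cond = rep(c("a", "b"), 16),
               amplitude = noise + rep(c(0, effect), 16))
  }
  ## deterministic given the seed
  b1 <- bayes_rm_anova(make_d(0.8, 1), "cond", iterations = 2000, seed = 9)
  b2 <- bayes_rm_anova(make_d(0.8, 1), "cond", iterations = 2000, seed = 9)
  expect_identical(b1$bf10, b2$bf10)
  ## monotone in effect size
  bfs <- vapply(c(0, 0.5, 1.5), function(e)
    bayes_rm_anova(make_d(e, 2), "cond", iterations = 3000, seed = 4)$bf10,
    numeric(1))
  expect_true(all(diff(bfs) > 0))
  ## approximate reciprocity across independent Monte Carlo runs
  ba <- bayes_rm_anova(make_d(0.3, 3), "cond", iterations = 5000, seed = 5)
  bb <- bayes_rm_anova(make_d(0.3, 3), "cond", iterations = 5000, seed = 6)
  expect_equal(ba$bf10 * (1 / bb$bf10), 1, tolerance = 0.2)
  expect_true(ba$error_pct > 0)
})

test_that("null cohorts give Bayes factors favouring the null", {
  set.seed(26)
  bfs <- vapply(1:10, function(i) {
    d <- data.frame(participant = rep(1:40, each = 2),
                    cond = rep(c("a", "b"), 40), amplitude = rnorm(80))
    bayes_rm_anova(d, "cond", iterations = 2000, seed = i)$bf10
  }, numeric(1))
  ## evidence should lean toward the null in the typical replicate (our JZS
  ## variant's null asymptote sits near 0.3; occasional chance effects yield
  ## larger values)
  expect_lt(median(bfs), 0.6)
  expect_gte(mean(bfs < 1), 0.6)
})

test_that("split-half reliability handles the edge cases", {
  x <- rnorm(12)
  expect_equal(split_half_reliability(x, x)$r, 1)
  set.seed(27)
  big <- split_half_reliability(rnorm(1000), rnorm(1000))
  expect_lt(abs(big$r), 0.1)
  expect_error(split_half_reliability(rep(1, 8), rnorm(8)), "variance")
  expect_error(split_half_reliability(rnorm(3), rnorm(3)), "4")
})

test_that("dependent-correlation comparison reduces correctly", {
  eq <- compare_dependent_correlations(0.6, 0.6, 0.4, 30)
  expect_equal(eq$fisher_z_statistic, 0)
  expect_equal(eq$p, 1)
  ind <- compare_dependent_correlations(0.8, 0.5, 0, 40)
  expect_equal(ind$fisher_z_statistic,
               (atanh(0.8) - atanh(0.5)) / sqrt(2 / 37), tolerance = 1e-12)
  expect_error(compare_dependent_correlations(1, 0.5, 0, 40), "< 1")
  expect_error(compare_dependent_correlations(0.5, 0.4, 0.2, 5), ">= 10")
})

test_that("dependent-correlation test is approximately level under the null", {
  ## two correlated pairs with equal population correlation
  set.seed(28)
  n <- 80; rho_pair <- 0.5; rho_cross <- 0.3
  ## covariance with r(x1,y1)=r(x2,y2)=rho_pair, cross-links rho_cross
  S <- matrix(rho_cross, 4, 4)
  S[1, 2] <- S[2, 1] <- rho_pair
  S[3, 4] <- S[4, 3] <- rho_pair
  diag(S) <- 1
  L <- chol(S)
  rej <- 0; n_sim <- 800
  for (i in seq_len(n_sim)) {
    X <- matrix(rnorm(4 * n), n) %*% L
    r1 <- cor(X[, 1], X[, 2]); r2 <- cor(X[, 3], X[, 4])
    r12 <- (cor(X[, 1], X[, 3]) + cor(X[, 2], X[, 4])) / 2
    out <- compare_dependent_correlations(r1, r2, r12, n)
    rej <- rej + (out$p < 0.05)
  }
  expect_lt(abs(rej / n_sim - 0.05), 0.03)
})

test_that("effect-size conversion and sample-size search follow G*Power", {
  es <- effect_size_and_power(partial_eta_sq = 0.29)
  expect_equal(es$cohens_f, 0.639, tolerance = 5e-4)
  expect_equal(effect_size_and_power(partial_eta_sq = 0.5)$cohens_f, 1)
  e0 <- effect_size_and_power(partial_eta_sq = 0)
  expect_equal(e0$cohens_f, 0)
  expect_true(is.na(e0$n_required))
  ## achieved power exceeds the target; larger effects need fewer subjects
  expect_gte(es$power, 0.95)
  n_small <- effect_size_and_power(f = 0.25)$n_required
  n_large <- effect_size_and_power(f = 0.8)$n_required
  expect_gt(n_small, n_large)
  expect_error(effect_size_and_power(partial_eta_sq = 0.2, f = 0.5),
               "exactly one")
})
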