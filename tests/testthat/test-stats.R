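# noninferiority statistics layer

test_that("paired_noninferiority matches the closed-form t-interval", {
  # frozen oracle: d = (1,2,3,4), mean 2.5, sd = sqrt(5/3),
  # t_{3,0.975} = 3.182446, half-width 2.054 -> CI (0.4457, 4.5543)
  r <- paired_noninferiority(c(1, 2, 3, 4), c(0, 0, 0, 0), margin = 5)
  expect_equal(r$mean_diff, 2.5)
  expect_equal(r$ci_lower, 0.446, tolerance = 1e-3)
  expect_equal(r$ci_upper, 4.554, tolerance = 1e-3)
  expect_true(r$noninferior)
  # closed-form agreement to 1e-10 on random data
  set.seed(71)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    ec <- rnorm(n, sd = 3); suh <- rnorm(n, sd = 2)
    r <- paired_noninferiority(ec, suh, margin = 5)
    d <- abs(ec) - abs(suh)
    half <- qt(0.975, n - 1) * sd(d) / sqrt(n)
    expect_equal(r$ci_lower, mean(d) - half, tolerance = 1e-10)
    expect_equal(r$ci_upper, mean(d) + half, tolerance = 1e-10)
    # and against the t.test oracle
    tt <- t.test(d)
    expect_equal(unname(tt$conf.int[1]), r$ci_lower, tolerance = 1e-10)
  }
  # degenerate: zero variance
  r0 <- paired_noninferiority(rep(2, 5), rep(2, 5), margin = 5)
  expect_true(r0$degenerate)
  expect_equal(r0$ci_lower, 0)
  expect_true(r0$noninferior)
})

test_that("noninferiority decision rule and monotonicity in the margin", {
  # published-summary decision checks: volar tilt mean 2.3 (CI 0.6-4.0),
  # margin 5 deg; ulnar variance mean 0.38 (CI 0.11-0.66), margin 2 mm
  expect_true(noninferiority_decision(2.3, 0.6, 5))
  expect_true(noninferiority_decision(0.38, 0.11, 2))
  # inferior example: lower limit below -margin
  expect_false(noninferiority_decision(-4, -6.2, 5))
  # monotone in margin
  set.seed(72)
  for (i in 1:100) {
    m <- runif(1, 0.5, 6); lo <- runif(1, -8, 2)
    if (noninferiority_decision(lo + 1, lo, m))
      expect_true(noninferiority_decision(lo + 1, lo, m + runif(1, 0, 4)))
  }
})

# brute-force enumeration oracle, independent of the implementation:
# all assignments of pooled midranks to group a
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled)
  na <- length(a)
  combs <- combn(length(pooled), na)
  us <- apply(combs, 2, function(ix) sum(rk[ix]) - na * (na + 1) / 2)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  centre <- na * length(b) / 2
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-12)
}

test_that("mann_whitney_u: exact enumeration, ties, approximation", {
  r <- mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 1 / 3, tolerance = 1e-12)
  # identical samples -> all tied, p = 1
  expect_equal(mann_whitney_u(c(1, 1, 1), c(1, 1), "exact")$p_two_sided, 1)
  # exact mode equals the brute-force oracle for n_a + n_b <= 10,
  # including tied data
  set.seed(73)
  for (i in 1:40) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- sample(1:6, na, replace = TRUE)  # coarse grid forces ties
    b <- sample(1:6, nb, replace = TRUE)
    if (length(unique(c(a, b))) == 1) next
    expect_equal(mann_whitney_u(a, b, "exact")$p_two_sided,
                 mw_exact_oracle(a, b), tolerance = 1e-12)
  }
  # normal approximation close to exact at n = 7/7
  set.seed(74)
  for (i in 1:20) {
    a <- rnorm(7); b <- rnorm(7, mean = 0.5)
    pe <- mann_whitney_u(a, b, "exact")$p_two_sided
    pn <- mann_whitney_u(a, b, "normal_approx")$p_two_sided
    expect_lt(abs(pe - pn), 0.03)
  }
  # exact mode refuses large samples
  expect_error(mann_whitney_u(rnorm(8), rnorm(8), "exact"), "<= 14")
})

test_that("shapiro_wilk: closed-form n = 3, bimodal rejection, guards", {
  # perfectly linear normal order statistics at n = 3 -> W = 1
  expect_equal(shapiro_wilk(c(-1, 0, 1))$W, 1, tolerance = 1e-6)
  # strongly bimodal fixture: clusters at +/- 5
  set.seed(75)
  x <- c(rnorm(10, -5, 0.3), rnorm(10, 5, 0.3))
  expect_lt(shapiro_wilk(x)$p, 0.01)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("posthoc_power_mw: null floor, monotonicity, simulation oracle", {
  # identical means -> power collapses to the alpha-level floor
  p0 <- posthoc_power_mw(group_summary(13, 0.1, 0.01),
                         group_summary(18, 0.1, 0.01))
  expect_lt(p0, 0.06)
  # monotone in |mean difference|
  grid <- seq(0, 0.01, by = 0.002)  # Cohen d 0..1, below saturation
  pow <- vapply(grid, function(d)
    posthoc_power_mw(group_summary(13, 0.085, 0.01),
                     group_summary(18, 0.085 + d, 0.01)), numeric(1))
  expect_true(all(diff(pow) > 0))
  expect_error(posthoc_power_mw(group_summary(5, 1, 0),
                                group_summary(5, 1, 0)), "pooled SD")

  # simulation oracle at the study's printed group summaries:
  # n = 13 vs 18, means 0.085 / 0.091, SDs 0.007 / 0.013
  approx_pow <- posthoc_power_mw(group_summary(13, 0.085, 0.007),
                                 group_summary(18, 0.091, 0.013))
  set.seed(76)
  nrep <- 20000
  rej <- logical(nrep)
  for (i in seq_len(nrep)) {
    a <- rnorm(13, 0.085, 0.007)
    b <- rnorm(18, 0.091, 0.013)
    rej[i] <- mann_whitney_u(a, b, "normal_approx")$p_two_sided < 0.05
  }
  expect_lt(abs(approx_pow - mean(rej)), 0.10)
})

test_that("study_table: summaries, noninferiority and pairing checks", {
  # symmetric arms: mean difference ~ 0, both decisions noninferior
  pc <- simulate_study_errors(16, list(
    in_house = residual_error_spec(c(3, 2, 3), c(1, 1, 1)),
    external = residual_error_spec(c(3, 2, 3), c(1, 1, 1))), seed = 5)
  tab <- study_table(pc)
  expect_true(tab$noninferiority$volar_tilt$noninferior)
  expect_true(tab$noninferiority$ulnar_variance$noninferior)
  expect_equal(nrow(tab$summary), 12)  # 6 parameters x 2 arms

  # folded-normal closed form: abs-error means within 3 SE of
  # sigma * sqrt(2/pi) over a large synthetic study
  sig <- 4
  pc2 <- simulate_study_errors(400, list(
    in_house = residual_error_spec(rep(sig, 3), rep(1, 3)),
    external = residual_error_spec(rep(sig, 3), rep(1, 3))), seed = 6)
  tab2 <- study_table(pc2)
  rx <- tab2$summary[tab2$summary$parameter == "rot_x", ]
  mu_fold <- sig * sqrt(2 / pi)
  sd_fold <- sig * sqrt(1 - 2 / pi)
  for (i in 1:2)
    expect_lt(abs(rx$mean_abs[i] - mu_fold), 3 * sd_fold / sqrt(400))

  # missing arm -> pairing error naming the case
  bad <- pc[!(pc$case_id == 7 & pc$guide_arm == "external"), ]
  expect_error(study_table(bad), "pairing error.*7")
  expect_error(study_table(pc[, 1:4]), "lacks columns")
})
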