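#' Paired absolute-error noninferiority analysis
#'
#' For paired error measurements from two planning arms, computes
#' `d_i = |errors_ec_i| - |errors_suh_i|` (external company minus in-house,
#' in absolute values, so a positive mean favours the in-house arm) and the
#' two-sided `1 - alpha` t-interval `mean(d) +/- t_{n-1} sd(d)/sqrt(n)`.
#' Noninferiority of the in-house arm is claimed when the lower confidence
#' limit exceeds `-margin`.
#'
#' @param errors_ec,errors_suh equal-length numeric vectors of signed or
#'   absolute errors, paired by patient (external company; in-house).
#' @param margin positive noninferiority margin (5 degrees for volar tilt,
#'   2 mm for ulnar variance in the default study configuration).
#' @param alpha significance level (two-sided CI; one-sided test level
#'   `alpha/2`).
#' @return list of class `noninferiority_result`: `n`, `mean_diff`,
#'   `ci_lower`, `ci_upper`, `margin`, `alpha`, `noninferior`,
#'   `degenerate` (TRUE when the differences have zero variance).
#' @export
paired_noninferiority <- function(errors_ec, errors_suh, margin,
                                  alpha = 0.05) {
  stopifnot(length(errors_ec) == length(errors_suh), margin > 0)
  n <- length(errors_ec)
  if (n < 2) stop("need at least 2 pairs")
  d <- abs(errors_ec) - abs(errors_suh)
  m <- mean(d)
  s <- sd(d)
  degenerate <- s == 0
  half <- qt(1 - alpha / 2, n - 1) * s / sqrt(n)
  res <- noninferiority_decision(m, m - half, margin)
  structure(list(n = n, mean_diff = m, ci_lower = m - half,
                 ci_upper = m + half, margin = margin, alpha = alpha,
                 noninferior = res, degenerate = degenerate),
            class = "noninferiority_result")
}

#' Noninferiority decision rule
#'
#' The decision applied to a (possibly externally computed) summary: the
#' null hypothesis of inferiority is rejected -- noninferiority claimed --
#' when the lower confidence limit of the mean absolute-error difference
#' lies above `-margin`.
#'
#' @param mean_diff mean of `|error EC| - |error SUH|`.
#' @param ci_lower lower confidence limit of the mean difference.
#' @param margin positive noninferiority margin.
#' @return logical: TRUE when noninferiority can be claimed.
#' @export
noninferiority_decision <- function(mean_diff, ci_lower, margin) {
  stopifnot(margin > 0, ci_lower <= mean_diff)
  ci_lower > -margin
}

#' @export
print.noninferiority_result <- function(x, ...) {
  cat(sprintf(
    "noninferiority (n = %d): mean diff %.3f, %d%% CI (%.3f, %.3f), margin %.1f -> %s\n",
    x$n, x$mean_diff, round(100 * (1 - x$alpha)), x$ci_lower, x$ci_upper,
    x$margin,
    if (x$noninferior) "noninferiority claimed" else "inconclusive"))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U from rank sums with midranks for ties. Exact mode enumerates all
#' `choose(n_a + n_b, n_a)` group labelings of the pooled values (feasible
#' for `n_a + n_b <= 14`) and returns the two-sided tail probability of U at
#' least as extreme as observed (`|U - n_a n_b / 2|` at least the observed
#' one). The normal approximation applies the tie correction and a 0.5
#' continuity correction.
#'
#' @param a,b numeric samples.
#' @param mode `"exact"` or `"normal_approx"`.
#' @return list with `U` (for sample `a`), `p_two_sided`, `mode`,
#'   `all_tied` (TRUE when every pooled value is identical; p is then 1).
#' @export
mann_whitney_u <- function(a, b, mode = c("exact", "normal_approx")) {
  mode <- match.arg(mode)
  na <- length(a); nb <- length(b)
  stopifnot(na >= 1, nb >= 1)
  pooled <- c(a, b)
  n <- na + nb
  rk <- rank(pooled)  # midranks
  u_stat <- function(idx_a) sum(rk[idx_a]) - length(idx_a) *
    (length(idx_a) + 1) / 2
  u <- u_stat(seq_len(na))
  if (length(unique(pooled)) == 1L)
    return(list(U = u, p_two_sided = 1, mode = mode, all_tied = TRUE))
  if (mode == "exact") {
    if (n > 14) stop("exact mode requires n_a + n_b <= 14")
    combs <- combn(n, na)
    us <- apply(combs, 2, u_stat)
    centre <- na * nb / 2
    p <- mean(abs(us - centre) >= abs(u - centre) - 1e-12)
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- na * nb / 12 * ((n + 1) - tie_corr)
    if (sig2 <= 0)
      return(list(U = u, p_two_sided = 1, mode = mode, all_tied = FALSE))
    z <- (abs(u - mu) - 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-max(z, 0))
  }
  list(U = u, p_two_sided = min(1, p), mode = mode, all_tied = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation (AS R94) for 3 <= n <= 5000, delegated to the
#' reference implementation in the stats package; the contract adds the
#' degenerate-input guard.
#'
#' @param x numeric sample, 3 to 5000 values, not all identical.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) stop("shapiro_wilk requires 3 <= n <= 5000")
  if (length(unique(x)) == 1L)
    stop("W is undefined for a constant sample")
  st <- shapiro.test(x)
  list(W = unname(st$statistic), p = unname(st$p.value))
}

#' Group summary (n, mean, sd)
#' @param n sample size (>= 2). @param mean group mean. @param sd group
#'   standard deviation (>= 0).
#' @return list of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Approximate post-hoc power of a Mann-Whitney comparison
#'
#' Approximation built from the two-sample t-test power at Cohen's d from
#' the pooled SD, with each sample size deflated by the asymptotic relative
#' efficiency 3/pi of the Mann-Whitney test under normal parents. This is an
#' explicit approximation: desktop power tools implement their own variants,
#' so values are comparable only to within the approximation error.
#'
#' @param summary_a,summary_b [group_summary()] objects.
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
posthoc_power_mw <- function(summary_a, summary_b, alpha = 0.05) {
  n1 <- summary_a$n; n2 <- summary_b$n
  sp2 <- ((n1 - 1) * summary_a$sd^2 + (n2 - 1) * summary_b$sd^2) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled SD: effect size undefined")
  d <- abs(summary_a$mean - summary_b$mean) / sqrt(sp2)
  are <- 3 / pi
  m1 <- n1 * are; m2 <- n2 * are
  df <- m1 + m2 - 2
  ncp <- d * sqrt(m1 * m2 / (m1 + m2))
  tc <- qt(1 - alpha / 2, df)
  1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
}

#' Study-level summary and noninferiority analyses from per-case errors
#'
#' Takes the per-case error table emitted by the measurement pipeline (one
#' row per case and guide arm, columns `case_id`, `guide_arm` with values
#' `"in_house"` / `"external"`, and `rot_x`, `rot_y`, `rot_z`, `trans_x`,
#' `trans_y`, `trans_z`) and produces the mean (SD) of absolute errors per
#' parameter per arm, plus the two noninferiority analyses: volar tilt
#' (`rot_x`, margin 5 degrees) and ulnar variance (`trans_z`, margin 2 mm).
#'
#' @param per_case data frame (or path to a CSV) as above.
#' @param margin_rotx,margin_transz noninferiority margins.
#' @param alpha significance level.
#' @return list with `summary` (data frame: parameter, arm, n, mean_abs,
#'   sd_abs) and `noninferiority` (list with elements `volar_tilt` and
#'   `ulnar_variance`).
#' @export
study_table <- function(per_case, margin_rotx = 5, margin_transz = 2,
                        alpha = 0.05) {
  if (is.character(per_case)) per_case <- read.csv(per_case)
  needed <- c("case_id", "guide_arm", "rot_x", "rot_y", "rot_z",
              "trans_x", "trans_y", "trans_z")
  missing_cols <- setdiff(needed, names(per_case))
  if (length(missing_cols))
    stop("per-case table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  arms <- c("in_house", "external")
  split_arm <- split(per_case, per_case$guide_arm)
  if (!all(arms %in% names(split_arm)))
    stop("per-case table must contain both guide arms")
  ih <- split_arm$in_house; ec <- split_arm$external
  bad <- union(setdiff(ih$case_id, ec$case_id),
               setdiff(ec$case_id, ih$case_id))
  if (length(bad))
    stop("pairing error: case(s) missing one arm: ",
         paste(bad, collapse = ", "))
  ih <- ih[order(ih$case_id), ]
  ec <- ec[order(ec$case_id), ]
  pars <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  summ <- do.call(rbind, lapply(pars, function(p) {
    do.call(rbind, lapply(arms, function(a) {
      x <- abs(split_arm[[a]][[p]])
      data.frame(parameter = p, arm = a, n = length(x),
                 mean_abs = mean(x), sd_abs = sd(x))
    }))
  }))
  list(summary = summ,
       noninferiority = list(
         volar_tilt = paired_noninferiority(ec$rot_x, ih$rot_x,
                                            margin_rotx, alpha),
         ulnar_variance = paired_noninferiority(ec$trans_z, ih$trans_z,
                                                margin_transz, alpha)))
}
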