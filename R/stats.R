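## orthonormal sum-to-zero contrasts for k levels (normalized Helmert)
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

## Greenhouse-Geisser epsilon and Mauchly test from per-subject scores on an
## effect's orthonormal contrasts. `scores`: N x d matrix, `groups`: factor
## (between groups; covariance pooled within groups).
gg_epsilon <- function(scores, groups = NULL) {
  d <- ncol(scores)
  if (is.null(groups)) groups <- factor(rep(1, nrow(scores)))
  a <- nlevels(groups)
  centered <- scores
  for (g in levels(groups)) {
    sel <- groups == g
    centered[sel, ] <- sweep(scores[sel, , drop = FALSE], 2,
                             colMeans(scores[sel, , drop = FALSE]))
  }
  n_err <- nrow(scores) - a
  S <- crossprod(centered) / n_err
  eps <- sum(diag(S))^2 / (d * sum(S * S))
  ## Mauchly sphericity test (chi-square approximation)
  W <- det(S) / (sum(diag(S)) / d)^d
  mauchly_p <- NA_real_
  if (d > 1 && is.finite(W) && W > 0) {
    rho <- 1 - (2 * d^2 + d + 2) / (6 * d * n_err)
    chi2 <- -n_err * rho * log(W)
    df <- d * (d + 1) / 2 - 1
    mauchly_p <- pchisq(chi2, df, lower.tail = FALSE)
  }
  list(epsilon = min(1, eps), mauchly_p = mauchly_p)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical balanced repeated-measures decomposition for designs with one or
#' two within-subject factors and an optional between-subject factor (equal
#' group sizes required). F ratios use the subject-by-effect error strata;
#' partial eta squared is `SS_effect / (SS_effect + SS_error)`. For within
#' effects with three or more levels, Mauchly's sphericity test is run and
#' Greenhouse-Geisser epsilon is applied to the degrees of freedom when its
#' p < 0.05 (with two levels sphericity holds trivially and epsilon is 1).
#' Multiple observations per design cell (trials) are averaged first.
#'
#' @param data Long-format data.frame.
#' @param dv Name of the numeric response column (e.g. amplitude in
#'   microvolts).
#' @param participant Name of the participant id column.
#' @param within Character vector (length 1 or 2) of within-factor columns.
#' @param between Optional name of a between-factor column.
#' @return An `fpvs_anova` data.frame with one row per effect: `effect`, `F`,
#'   `df_num`, `df_den`, `p` (sphericity-corrected where applied),
#'   `partial_eta_sq`, `epsilon`, `mauchly_p`, `gg_applied`.
#' @export
rm_anova <- function(data, dv = "amplitude", participant = "participant",
                     within, between = NULL) {
  for (col in c(dv, participant, within, between))
    if (!col %in% names(data)) stop_fpvs("column '%s' not found", col)
  agg <- aggregate(data[[dv]],
                   by = c(stats::setNames(list(data[[participant]]), "s"),
                          lapply(within, function(w) data[[w]]),
                          if (!is.null(between)) list(data[[between]])),
                   FUN = mean)
  wnames <- paste0("w", seq_along(within))
  names(agg) <- c("s", wnames, if (!is.null(between)) "b", "y")
  agg$s <- factor(agg$s)
  for (wn in wnames) agg[[wn]] <- factor(agg[[wn]])
  two_w <- length(within) == 2
  if (!two_w) agg$w2 <- factor("1") else agg$w2 <- agg[[wnames[2]]]
  agg$w1 <- agg[[wnames[1]]]
  if (is.null(between)) agg$b <- factor("1") else agg$b <- factor(agg$b)

  p <- nlevels(agg$w1); q <- nlevels(agg$w2); a <- nlevels(agg$b)
  N <- nlevels(agg$s)
  if (nrow(agg) != N * p * q)
    stop_fpvs("design is not balanced over within cells (missing cells?)")
  grp_of <- tapply(as.character(agg$b), agg$s, function(v) v[1])
  if (length(unique(table(grp_of))) > 1)
    stop_fpvs("between-participant groups must have equal sizes")
  n <- N / a
  if (n < 2) stop_fpvs("need at least 2 participants per group")

  ## cell array Y[s, i, j]
  Y <- array(NA_real_, c(N, p, q))
  si <- as.integer(agg$s); wi <- as.integer(agg$w1); wj <- as.integer(agg$w2)
  for (r in seq_len(nrow(agg))) Y[si[r], wi[r], wj[r]] <- agg$y[r]
  g_idx <- as.integer(factor(grp_of[levels(agg$s)], levels = levels(agg$b)))

  m <- mean(Y)
  m_s <- apply(Y, 1, mean)
  m_g <- as.numeric(tapply(m_s, g_idx, mean))
  m_i <- apply(Y, 2, mean); m_j <- apply(Y, 3, mean)
  m_ij <- apply(Y, c(2, 3), mean)
  m_si <- apply(Y, c(1, 2), mean); m_sj <- apply(Y, c(1, 3), mean)
  m_gi <- matrix(0, a, p); m_gj <- matrix(0, a, q)
  m_gij <- array(0, c(a, p, q))
  for (g in seq_len(a)) {
    sel <- g_idx == g
    m_gi[g, ] <- apply(Y[sel, , , drop = FALSE], 2, mean)
    m_gj[g, ] <- apply(Y[sel, , , drop = FALSE], 3, mean)
    m_gij[g, , ] <- apply(Y[sel, , , drop = FALSE], c(2, 3), mean)
  }

  rows <- list()
  add_row <- function(effect, ss, df, ss_err, df_err, eps = NA, mp = NA,
                      gg = FALSE) {
    Fv <- if (ss <= 1e-300) 0 else (ss / df) / (ss_err / df_err)
    d1 <- df; d2 <- df_err
    if (gg) { d1 <- d1 * eps; d2 <- d2 * eps }
    rows[[length(rows) + 1]] <<- data.frame(
      effect = effect, F = Fv, df_num = d1, df_den = d2,
      p = pf(Fv, d1, d2, lower.tail = FALSE),
      partial_eta_sq = if (ss <= 1e-300) 0 else ss / (ss + ss_err),
      epsilon = eps, mauchly_p = mp, gg_applied = gg,
      stringsAsFactors = FALSE)
  }

  ## between-subject stratum
  ss_subj <- p * q * sum((m_s - m_g[g_idx])^2)
  df_subj <- N - a
  if (a > 1) {
    ss_b <- p * q * n * sum((m_g - m)^2)
    add_row(between, ss_b, a - 1, ss_subj, df_subj)
  }

  ## helper for within strata
  eff_w <- function(label, Mw, ss_eff, df_eff, ss_int, ss_err, df_err,
                    levels_ge3) {
    scores <- t(apply(Y, 1, function(ys) as.vector(t(Mw) %*% as.vector(ys))))
    if (ncol(Mw) == 1) scores <- matrix(scores, ncol = 1)
    gg <- gg_epsilon(scores, factor(g_idx))
    use_gg <- levels_ge3 && !is.na(gg$mauchly_p) && gg$mauchly_p < 0.05
    add_row(label, ss_eff, df_eff, ss_err, df_err,
            eps = if (levels_ge3) gg$epsilon else 1,
            mp = if (levels_ge3) gg$mauchly_p else NA, gg = use_gg)
    if (a > 1)
      add_row(paste0(label, ":", between), ss_int, df_eff * (a - 1),
              ss_err, df_err,
              eps = if (levels_ge3) gg$epsilon else 1,
              mp = if (levels_ge3) gg$mauchly_p else NA, gg = use_gg)
  }

  ## W1
  Cp <- orthonormal_contrasts(p)
  jq <- matrix(1 / sqrt(q), q, 1)
  ss_w1 <- N * q * sum((m_i - m)^2)
  ss_w1b <- q * n * sum((m_gi - outer(m_g, rep(1, p)) -
                           outer(rep(1, a), m_i) + m)^2)
  err_w1 <- q * sum((m_si - m_gi[g_idx, , drop = FALSE] -
                       (m_s - m_g[g_idx]))^2)
  ## kron(Cp, jq) maps vec(t(Y[s,,])): build M for vec of (i,j) flattened as
  ## as.vector(ys) with i fastest? as.vector(Y[s,,]) flattens i fastest.
  Mw1 <- kronecker(jq, Cp)  # acts on vec with w1 fastest
  eff_w(within[1], Mw1, ss_w1, p - 1, ss_w1b,
        err_w1, (N - a) * (p - 1), p >= 3)

  if (two_w) {
    Cq <- orthonormal_contrasts(q)
    jp <- matrix(1 / sqrt(p), p, 1)
    ss_w2 <- N * p * sum((m_j - m)^2)
    ss_w2b <- p * n * sum((m_gj - outer(m_g, rep(1, q)) -
                             outer(rep(1, a), m_j) + m)^2)
    err_w2 <- p * sum((m_sj - m_gj[g_idx, , drop = FALSE] -
                         (m_s - m_g[g_idx]))^2)
    Mw2 <- kronecker(Cq, jp)
    eff_w(within[2], Mw2, ss_w2, q - 1, ss_w2b,
          err_w2, (N - a) * (q - 1), q >= 3)

    int_ij <- m_ij - outer(m_i, rep(1, q)) - outer(rep(1, p), m_j) + m
    ss_w12 <- N * sum(int_ij^2)
    ss_w12b <- 0
    for (g in seq_len(a)) {
      int_g <- m_gij[g, , ] - outer(m_gi[g, ], rep(1, q)) -
        outer(rep(1, p), m_gj[g, ]) + m_g[g]
      ss_w12b <- ss_w12b + n * sum((int_g - int_ij)^2)
    }
    err_w12 <- 0
    for (s in seq_len(N)) {
      g <- g_idx[s]
      int_s <- Y[s, , ] - outer(m_si[s, ], rep(1, q)) -
        outer(rep(1, p), m_sj[s, ]) + m_s[s]
      int_g <- m_gij[g, , ] - outer(m_gi[g, ], rep(1, q)) -
        outer(rep(1, p), m_gj[g, ]) + m_g[g]
      err_w12 <- err_w12 + sum((int_s - int_g)^2)
    }
    Mw12 <- kronecker(Cq, Cp)
    eff_w(paste(within, collapse = ":"), Mw12, ss_w12,
          (p - 1) * (q - 1), ss_w12b, err_w12,
          (N - a) * (p - 1) * (q - 1), (p - 1) * (q - 1) >= 2)
  }

  out <- do.call(rbind, rows)
  class(out) <- c("fpvs_anova", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in the sorted order and capped at 1.
#'
#' @param p_values Numeric vector of p-values in 0..1.
#' @return Adjusted p-values in the original order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_fpvs("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Paired post-hoc contrasts with FDR correction
#'
#' Two-tailed paired t-tests between condition cells, with p-values jointly
#' FDR-adjusted. If all paired differences are exactly zero, t = 0 and p = 1;
#' a nonzero constant difference (zero variance) leaves t undefined and is
#' flagged.
#'
#' @param cell_values Matrix participants x cells (named columns).
#' @param comparisons List of 2-element character vectors naming cells.
#' @return data.frame `comparison`, `t`, `df`, `p`, `p_fdr`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_contrasts <- function(cell_values, comparisons) {
  if (nrow(cell_values) < 2) stop_fpvs("need at least 2 participants")
  res <- lapply(comparisons, function(cmp) {
    d <- cell_values[, cmp[1]] - cell_values[, cmp[2]]
    n <- length(d)
    if (sd(d) == 0) {
      if (all(d == 0))
        return(data.frame(comparison = paste(cmp, collapse = " vs "),
                          t = 0, df = n - 1, p = 1, mean_diff = 0,
                          degenerate = FALSE))
      return(data.frame(comparison = paste(cmp, collapse = " vs "),
                        t = NA_real_, df = n - 1, p = NA_real_,
                        mean_diff = mean(d), degenerate = TRUE))
    }
    tt <- t.test(cell_values[, cmp[1]], cell_values[, cmp[2]], paired = TRUE)
    data.frame(comparison = paste(cmp, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- fdr_adjust(out$p)
  out[, c("comparison", "t", "df", "p", "p_fdr", "mean_diff", "degenerate")]
}

#' Split-half reliability
#'
#' Pearson correlation between estimates from odd and even trials, indexing
#' internal consistency.
#'
#' @param odd_trial_values,even_trial_values Paired numeric vectors (one value
#'   per participant, n >= 4).
#' @return List with `r`, `p` (two-tailed), `n`.
#' @export
split_half_reliability <- function(odd_trial_values, even_trial_values) {
  ok <- complete.cases(odd_trial_values, even_trial_values)
  x <- odd_trial_values[ok]; y <- even_trial_values[ok]
  if (length(x) < 4) stop_fpvs("need at least 4 paired values")
  if (sd(x) == 0 || sd(y) == 0)
    stop_fpvs("zero variance in one half")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare two dependent correlations (Fisher Z, non-overlapping variables)
#'
#' Tests whether two correlation coefficients measured on the same
#' participants but between different variable pairs (e.g. odd-even
#' reliability within condition A vs within condition B) differ. Both are
#' Fisher-transformed and their difference divided by its standard error,
#' which accounts for the dependence through the cross-correlation `r12`
#' between the two variable pairs (Dunn-Clark / Steiger family,
#' Pearson-Filon covariance). Cross-correlations between non-corresponding
#' halves are modeled as `r12 * (r1 + r2) / 2` (see the methods vignette).
#'
#' @param r1,r2 The two correlations to compare.
#' @param r12 Cross-correlation between corresponding variables of the two
#'   pairs.
#' @param n Sample size (>= 10).
#' @return List with `fisher_z_statistic`, `p` (two-tailed), `r1`, `r2`,
#'   `r12`, `n`.
#' @export
compare_dependent_correlations <- function(r1, r2, r12, n) {
  if (n < 10) stop_fpvs("n must be >= 10")
  if (any(abs(c(r1, r2, r12)) >= 1)) stop_fpvs("|r| must be < 1")
  z1 <- atanh(r1); z2 <- atanh(r2)
  rho <- r12
  rho_s <- r12 * (r1 + r2) / 2
  psi <- r1 * r2 * (rho^2 + rho_s^2) + rho^2 + rho_s^2 -
    2 * rho * rho_s * (r1 + r2)
  c_z <- psi / ((1 - r1^2) * (1 - r2^2))
  c_z <- max(-0.999, min(0.999, c_z))
  se <- sqrt(2 * (1 - c_z) / (n - 3))
  z <- (z1 - z2) / se
  list(fisher_z_statistic = z, p = 2 * pnorm(-abs(z)),
       r1 = r1, r2 = r2, r12 = r12, n = n)
}

#' Effect size and required sample size for a within-subject ANOVA
#'
#' Converts partial eta squared to Cohen's f (`f = sqrt(eta2 / (1 - eta2))`,
#' e.g. eta2 = 0.29 gives f = 0.639) and, G*Power-style, finds the smallest
#' sample size whose noncentral-F power reaches the target under the
#' repeated-measures (within-factor) convention: noncentrality
#' `lambda = f^2 * n * m * epsilon / (1 - rho)` with degrees of freedom
#' `(m - 1) * epsilon` and `(n - 1) * (m - 1) * epsilon`. The within-cell
#' correlation `rho` and nonsphericity `epsilon` are explicit parameters
#' because power conventions differ between tools.
#'
#' @param partial_eta_sq Partial eta squared (exactly one of this or `f`).
#' @param f Cohen's f.
#' @param alpha Significance level.
#' @param power Target power (0..1).
#' @param m_levels Number of within-factor levels.
#' @param rho Assumed correlation among repeated measures (default 0.5).
#' @param epsilon Nonsphericity correction (default 1).
#' @param max_n Search bound.
#' @return List with `partial_eta_sq`, `cohens_f`, `alpha`, `power`
#'   (achieved at `n_required`), `n_required`.
#' @export
effect_size_and_power <- function(partial_eta_sq = NULL, f = NULL,
                                  alpha = 0.05, power = 0.95, m_levels = 2,
                                  rho = 0.5, epsilon = 1.0, max_n = 10000) {
  if (is.null(partial_eta_sq) == is.null(f))
    stop_fpvs("give exactly one of partial_eta_sq or f")
  if (!is.null(partial_eta_sq)) {
    if (partial_eta_sq >= 1 || partial_eta_sq < 0)
      stop_fpvs("partial_eta_sq must be in [0, 1)")
    f <- sqrt(partial_eta_sq / (1 - partial_eta_sq))
  } else {
    partial_eta_sq <- f^2 / (1 + f^2)
  }
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, m_levels >= 2)
  pow_at <- function(n) {
    lambda <- f^2 * n * m_levels * epsilon / (1 - rho)
    df1 <- (m_levels - 1) * epsilon
    df2 <- (n - 1) * (m_levels - 1) * epsilon
    crit <- qf(1 - alpha, df1, df2)
    pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
  }
  n_req <- NA_integer_; achieved <- NA_real_
  if (f > 0) {
    for (n in 2:max_n) {
      pw <- pow_at(n)
      if (pw >= power) { n_req <- n; achieved <- pw; break }
    }
  }
  list(partial_eta_sq = partial_eta_sq, cohens_f = f, alpha = alpha,
       power = achieved, target_power = power, n_required = n_req,
       m_levels = m_levels, rho = rho, epsilon = epsilon)
}
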