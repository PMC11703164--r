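#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Rank-based omnibus test across groups with tie correction, followed by
#' Dunn's pairwise z-tests on the pooled rank means with tie-corrected
#' variance. For small untied samples (combined n at most `exact_limit`)
#' both the omnibus p and the pairwise p are computed exactly by full
#' enumeration of group-label permutations; otherwise the chi-square and
#' normal approximations are used.
#'
#' @param values numeric observations.
#' @param groups group labels, same length as `values`.
#' @param exact_limit combined-n cutoff for exact permutation p-values.
#' @return List: `H`, `df`, `p`, `method`, and `pairwise` data frame
#'   (`group1`, `group2`, `z`, `p`).
#' @export
kruskal_dunn <- function(values, groups, exact_limit = 10) {
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) stop("each group needs at least 2 values",
                           call. = FALSE)
  N <- length(values)
  r <- rank(values)
  H_obs <- kw_statistic(r, groups)
  k <- length(sizes)

  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  dunn_var_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  gl <- names(sizes)
  pairs <- utils::combn(gl, 2)
  rbar <- tapply(r, groups, mean)
  z <- p_pair <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(dunn_var_base * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[j] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
  }

  exact <- N <= exact_limit
  if (exact) {
    perms <- label_permutations(groups)
    H_all <- apply(perms, 2, function(g) kw_statistic(r, g))
    p_omni <- mean(H_all >= H_obs - 1e-12)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      d_obs <- abs(rbar[[a]] - rbar[[b]])
      d_all <- apply(perms, 2, function(g)
        abs(mean(r[g == a]) - mean(r[g == b])))
      p_pair[j] <- mean(d_all >= d_obs - 1e-12)
    }
    method <- "exact permutation"
  } else {
    p_omni <- pchisq(H_obs, df = k - 1, lower.tail = FALSE)
    p_pair <- 2 * pnorm(-abs(z))
    method <- "chi-square / normal approximation"
  }
  list(H = H_obs, df = k - 1, p = p_omni, method = method,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = z, p = p_pair))
}

# tie-corrected Kruskal-Wallis H from pooled ranks
kw_statistic <- function(r, groups) {
  N <- length(r)
  rbar <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(n_g * rbar^2) - 3 * (N + 1)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C > 0) H / C else 0
}

# all distinct assignments of the multiset of group labels to positions,
# one column per assignment
label_permutations <- function(groups) {
  recurse <- function(remaining) {
    if (length(remaining) == 1) return(matrix(remaining, nrow = 1))
    out <- list()
    for (g in unique(remaining)) {
      rest <- remaining[-match(g, remaining)]
      sub <- recurse(rest)
      out[[length(out) + 1]] <- rbind(g, sub)
    }
    do.call(cbind, out)
  }
  recurse(sort(groups))
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up false-discovery-rate control: adjusted p is
#' `min over k' >= k of m * p_(k') / k'`, clipped at 1; hypotheses with
#' adjusted p at most `q` are rejected.
#'
#' @param p raw p-values in [0, 1].
#' @param q FDR level.
#' @return List: `adjusted`, `reject` (logical), `q`.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adjusted <- p.adjust(p, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q, q = q)
}

#' Mann-Whitney U test
#'
#' Exact two-sided p for small untied samples (combined n at most
#' `exact_limit`), normal approximation with tie and continuity correction
#' otherwise.
#'
#' @param a,b numeric samples.
#' @param exact_limit combined-n cutoff for the exact distribution.
#' @return List: `U` (number of (a, b) pairs with a ahead of b), `p`,
#'   `method`.
#' @export
mann_whitney <- function(a, b, exact_limit = 12) {
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(c(a, b))) == 1)       # fully tied: no evidence either way
    return(list(U = length(a) * length(b) / 2, p = 1, method = "degenerate"))
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= exact_limit && !has_ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Per-syllable group comparison with FDR correction
#'
#' Runs [kruskal_dunn()] on one metric (velocity or usage) for every
#' syllable, then applies Benjamini-Hochberg across syllables to the
#' omnibus p-values (the per-figure correction scope); Dunn pairwise p
#' remain uncorrected and are attached for the significant syllables'
#' follow-up contrasts.
#'
#' @param stats a [syllable_stats()] table.
#' @param metric `"velocity"` or `"usage"`.
#' @param q FDR level.
#' @param syllables syllable ids to test (e.g. a [filter_by_usage()]
#'   `retained` set); defaults to all.
#' @param exact_limit passed to [kruskal_dunn()].
#' @return A `comparison_result` data frame (one row per syllable: group
#'   means/SEMs, `H`, `p`, `p_adj`, `significant`) with the pairwise table
#'   as attribute `"pairwise"`.
#' @export
compare_syllables <- function(stats, metric = c("velocity", "usage"),
                              q = 0.05, syllables = NULL,
                              exact_limit = 10) {
  metric <- match.arg(metric)
  if (is.null(syllables)) syllables <- sort(unique(stats$syllable))
  groups_all <- sort(unique(stats$group))
  rows <- list(); pw <- list()
  for (s in syllables) {
    sub <- stats[stats$syllable == s, , drop = FALSE]
    vals <- sub[[metric]]
    cnt <- table(factor(sub$group, levels = groups_all))
    if (any(cnt < 2)) {
      warning("syllable ", s, " skipped: a group has fewer than 2 values")
      next
    }
    kd <- kruskal_dunn(vals, sub$group, exact_limit = exact_limit)
    sm <- summarize_groups(vals, sub$group)
    row <- data.frame(syllable = s, metric = metric,
                      H = kd$H, p = kd$p)
    for (g in groups_all) {
      row[[paste0("mean_", g)]] <- sm$mean[sm$group == g]
      row[[paste0("sem_", g)]] <- sm$sem[sm$group == g]
    }
    rows[[length(rows) + 1]] <- row
    pw[[length(pw) + 1]] <- cbind(syllable = s, kd$pairwise)
  }
  if (!length(rows)) stop("no syllable could be tested", call. = FALSE)
  out <- do.call(rbind, rows)
  bh <- bh_adjust(out$p, q = q)
  out$p_adj <- bh$adjusted
  out$significant <- bh$reject
  rownames(out) <- NULL
  attr(out, "pairwise") <- do.call(rbind, pw)
  attr(out, "q") <- q
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Regression of group differences on control velocity
#'
#' The "is the lesion effect velocity-dependent?" analysis: per-syllable
#' delta = control group mean minus lesion group mean (of velocity or
#' usage), regressed by ordinary least squares on the control-group mean
#' velocity.
#'
#' @param stats a [syllable_stats()] table.
#' @param metric `"velocity"` or `"usage"`.
#' @param control_group,lesion_group group labels contrasted.
#' @param syllables syllable ids to include (>= 3 required); defaults to
#'   all syllables present in both groups.
#' @return A `delta_regression` list: `slope`, `intercept`, `r_squared`,
#'   `p_value` (two-sided slope test), `n`, `metric`, and the per-syllable
#'   `data`.
#' @export
delta_regression <- function(stats, metric = c("velocity", "usage"),
                             control_group = "control",
                             lesion_group = "lesion",
                             syllables = NULL) {
  metric <- match.arg(metric)
  ctl <- stats[stats$group == control_group, , drop = FALSE]
  les <- stats[stats$group == lesion_group, , drop = FALSE]
  m_ctl <- tapply(ctl[[metric]], ctl$syllable, mean)
  m_les <- tapply(les[[metric]], les$syllable, mean)
  v_ctl <- tapply(ctl$velocity, ctl$syllable, mean)
  common <- intersect(names(m_ctl), names(m_les))
  if (!is.null(syllables))
    common <- intersect(common, as.character(syllables))
  if (length(common) < 3)
    stop("need at least 3 syllables for the delta regression",
         call. = FALSE)
  df <- data.frame(syllable = as.integer(common),
                   control_velocity = as.numeric(v_ctl[common]),
                   delta = as.numeric(m_ctl[common] - m_les[common]))
  df <- df[order(df$syllable), , drop = FALSE]
  fit <- lm(delta ~ control_velocity, data = df)
  sf <- summary(fit)
  pv <- if (nrow(sf$coefficients) >= 2) sf$coefficients[2, 4] else NA_real_
  r2 <- sf$r.squared
  if (var(df$delta) == 0) { r2 <- 0; pv <- 1 }   # flat response: no fit
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, p_value = pv,
                 n = nrow(df), metric = metric, data = df),
            class = "delta_regression")
}

#' @export
print.delta_regression <- function(x, ...) {
  cat(sprintf(
    "delta_regression (%s): slope = %.4f, intercept = %.4f, R^2 = %.3f, p = %.3g, n = %d\n",
    x$metric, x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Mean and standard error by group
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @return Data frame: `group`, `n`, `mean`, `sd`, `sem` (= sd / sqrt(n)).
#' @export
summarize_groups <- function(values, groups) {
  groups <- as.character(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  s <- tapply(values, groups, sd)         # NA for n = 1: SEM undefined
  out <- data.frame(group = names(n), n = as.integer(n),
                    mean = as.numeric(m), sd = as.numeric(s),
                    sem = as.numeric(s) / sqrt(as.integer(n)))
  rownames(out) <- NULL
  out
}
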