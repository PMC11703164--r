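# rank-based group comparisons -----------------------------------------

test_that("Kruskal-Wallis H is tie-corrected and translation-invariant", {
  v <- c(3.1, 5.2, 4.4, 8.0, 6.1, 9.3, 2.2, 7.5)
  g <- c("a", "a", "a", "b", "b", "b", "c", "c")
  kd <- kruskal_dunn(v, g)
  expect_equal(kd$H, unname(kruskal.test(v, factor(g))$statistic),
               tolerance = 1e-12)
  kd_shift <- kruskal_dunn(v + 100, g)
  expect_equal(kd$H, kd_shift$H)
  expect_equal(kd$p, kd_shift$p)
  # all groups identical: no rank separation
  kd0 <- kruskal_dunn(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(kd0$H, 0)
  expect_equal(kd0$p, 1)
})

test_that("small-sample KW and Dunn p equal exhaustive permutation oracles", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  kd <- kruskal_dunn(v, g)
  expect_equal(kd$p, perm_kw(v, g), tolerance = 1e-12)
  for (j in seq_len(nrow(kd$pairwise)))
    expect_equal(kd$pairwise$p[j],
                 perm_rankdiff(v, g, kd$pairwise$group1[j],
                               kd$pairwise$group2[j]),
                 tolerance = 1e-12)
  # a second, non-separated configuration
  set.seed(8)
  v2 <- rnorm(8)
  g2 <- rep(c("x", "y"), each = 4)
  kd2 <- kruskal_dunn(v2, g2)
  expect_equal(kd2$p, perm_kw(v2, g2), tolerance = 1e-12)
  expect_equal(kd2$pairwise$p[1], perm_rankdiff(v2, g2, "x", "y"),
               tolerance = 1e-12)
})

test_that("BH step-up matches hand-worked examples", {
  b1 <- bh_adjust(c(0.001, 0.012, 0.03, 0.04), q = 0.05)
  expect_true(all(b1$reject))
  expect_equal(b1$adjusted, c(0.004, 0.024, 0.04, 0.04))
  b2 <- bh_adjust(c(0.04, 0.5, 0.9), q = 0.05)
  expect_false(any(b2$reject))
  b3 <- bh_adjust(rep(0, 4))
  expect_true(all(b3$reject))
  expect_equal(b3$adjusted, rep(0, 4))
  # monotone in rank order and never below raw
  set.seed(2)
  p <- runif(20)
  b <- bh_adjust(p)
  expect_true(all(b$adjusted >= p))
  expect_true(all(diff(b$adjusted[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Mann-Whitney U matches enumeration and is symmetric", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$p, perm_mwu(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  set.seed(31)
  a <- rnorm(5); b <- rnorm(4)
  expect_equal(mann_whitney(a, b)$p, perm_mwu(a, b), tolerance = 1e-12)
  mw_swap <- mann_whitney(b, a)
  expect_equal(mw_swap$U, length(a) * length(b) - mann_whitney(a, b)$U)
  expect_equal(mw_swap$p, mann_whitney(a, b)$p)
  expect_gt(mann_whitney(c(2, 2, 2), c(2, 2, 2))$p, 0.99)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("delta regression recovers exact linear and flat relations", {
  mk_stats <- function(delta_fun) {
    v <- seq(3, 17, length.out = 8)
    rbind(
      data.frame(animal_id = "c1", group = "control", syllable = 0:7,
                 velocity = v, usage = 1 / 8),
      data.frame(animal_id = "l1", group = "lesion", syllable = 0:7,
                 velocity = v - delta_fun(v), usage = 1 / 8))
  }
  r <- delta_regression(mk_stats(function(v) 0.4 * v), "velocity")
  expect_equal(r$slope, 0.4, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  r0 <- delta_regression(mk_stats(function(v) rep(1.5, length(v))),
                         "velocity")
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_equal(r0$r_squared, 0)
  two <- mk_stats(function(v) 0.4 * v)
  expect_error(delta_regression(two[two$syllable < 2, ], "velocity"),
               "at least 3 syllables")
})

test_that("group summaries report mean and SEM", {
  s1 <- summarize_groups(c(2, 2, 2, 1, 3), c("a", "a", "a", "b", "b"))
  expect_equal(s1$mean, c(2, 2))
  expect_equal(s1$sem[s1$group == "a"], 0)
  expect_equal(s1$sem[s1$group == "b"], 1)   # SD = sqrt(2), n = 2
  s2 <- summarize_groups(3 * c(2, 2, 2, 1, 3), c("a", "a", "a", "b", "b"))
  expect_equal(s2$mean, 3 * s1$mean)
  expect_equal(s2$sem, 3 * s1$sem)
})

test_that("per-syllable comparison flags effects and skips tiny groups", {
  set.seed(44)
  mk <- function(group, shift) do.call(rbind, lapply(1:6, function(a)
    data.frame(animal_id = paste0(group, a), group = group, syllable = 0:3,
               velocity = c(10, 10, 10, 10) - shift * c(4, 4, 0, 0) +
                 rnorm(4, 0, 0.3),
               usage = 0.25)))
  st <- rbind(mk("control", 0), mk("lesion", 1))
  cr <- compare_syllables(st, "velocity", q = 0.05)
  expect_true(all(cr$significant[cr$syllable %in% 0:1]))
  expect_false(any(cr$significant[cr$syllable %in% 2:3]))
  expect_true(all(cr$p_adj >= cr$p))
  expect_s3_class(attr(cr, "pairwise"), "data.frame")
  # a group with a single animal for one syllable is skipped with a warning
  st_bad <- rbind(st, data.frame(animal_id = "x", group = "control",
                                 syllable = 9, velocity = 1, usage = 0))
  expect_warning(compare_syllables(st_bad, "velocity"), "skipped")
})
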