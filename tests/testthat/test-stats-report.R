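test_that("exact Mann-Whitney matches full enumeration on small tie-free samples", {
  # the spec case: a entirely below b
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / 6, tolerance = 1e-12)
  expect_match(res$method_detail, "exact")
  # random tie-free samples across all pooled sizes up to 10
  set.seed(42)
  for (n in 4:10) for (na in 2:(n - 2)) {
    x <- sample(seq_len(200), n)
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    res <- mann_whitney(a, b, mode = "exact")
    expect_equal(res$p_value, mw_enumeration_p(a, b), tolerance = 1e-12,
                 label = sprintf("n=%d na=%d", n, na))
  }
})

test_that("Mann-Whitney handles ties and identical samples via midranks", {
  res <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)
  expect_match(res$method_detail, "midranks")
  # all values tied is degenerate but must not return NaN
  res2 <- mann_whitney(c(5, 5), c(5, 5))
  expect_equal(res2$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Kruskal-Wallis H matches the hand rank-sum formula", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- kruskal_wallis_dunn(g)
  expect_equal(res$test$statistic, kw_hand_h(g), tolerance = 1e-12)
  expect_equal(res$test$statistic, 7.2, tolerance = 1e-12)
  # random tie-free groups
  set.seed(7)
  for (i in 1:5) {
    g <- split(sample(1000, 15), rep(1:3, each = 5))
    res <- kruskal_wallis_dunn(g)
    expect_equal(res$test$statistic, kw_hand_h(g), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis is invariant to group order and degenerate-safe", {
  g <- list(a = c(1, 5, 9), b = c(2, 6, 7), c = c(3, 4, 8))
  r1 <- kruskal_wallis_dunn(g)
  r2 <- kruskal_wallis_dunn(g[c(3, 1, 2)])
  expect_equal(r1$test$statistic, r2$test$statistic, tolerance = 1e-12)
  key1 <- with(r1$pairwise, paste(pmin(group1, group2), pmax(group1, group2)))
  key2 <- with(r2$pairwise, paste(pmin(group1, group2), pmax(group1, group2)))
  expect_equal(r1$pairwise$p_value[order(key1)], r2$pairwise$p_value[order(key2)],
               tolerance = 1e-12)
  # three identical constant groups: H degenerate, reported as 0 with p = 1
  dg <- kruskal_wallis_dunn(list(rep(2, 3), rep(2, 4), rep(2, 5)))
  expect_equal(dg$test$statistic, 0)
  expect_equal(dg$test$p_value, 1)
  expect_error(kruskal_wallis_dunn(list(1:3, numeric(0), 1:2)), "empty")
})

test_that("Dunn pairwise adjustment never decreases p and two groups delegate", {
  set.seed(11)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2), d = rnorm(8))
  res <- kruskal_wallis_dunn(g)
  expect_equal(nrow(res$pairwise), choose(4, 2))
  expect_true(all(res$pairwise$adjusted_p >= res$pairwise$p_value - 1e-15))
  expect_true(all(res$pairwise$adjusted_p <= 1))
  two <- kruskal_wallis_dunn(list(x = c(1, 2), y = c(3, 4)))
  expect_equal(two$test$test_name, "mann_whitney")
  expect_null(two$pairwise)
})

test_that("two-proportion z-test matches the closed form and is antisymmetric", {
  res <- two_proportion_ztest(10, 100, 20, 100)
  # pooled p = 0.15, z = -0.1 / sqrt(0.15*0.85*0.02)
  expect_equal(res$statistic, -0.1 / sqrt(0.15 * 0.85 * 0.02), tolerance = 1e-12)
  expect_equal(res$statistic, -1.9803, tolerance = 1e-4)
  swap <- two_proportion_ztest(20, 100, 10, 100)
  expect_equal(swap$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(swap$p_value, res$p_value, tolerance = 1e-12)
  eq <- two_proportion_ztest(5, 50, 10, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  degenerate <- two_proportion_ztest(0, 10, 0, 20)
  expect_equal(degenerate$p_value, 1)
  expect_match(degenerate$method_detail, "degenerate")
  expect_error(two_proportion_ztest(11, 10, 1, 5), "x must satisfy")
})

test_that("implantation table arithmetic reproduces the printed counts", {
  tab <- implantation_table(
    group = c("control", "XER"),
    n_mice_injected = c(5, 7),
    n_mice_with_embryos = c(5, 4),
    n_mice_with_IS = c(5, 0),
    n_embryos_total = c(36, 17),
    n_embryos_implanted = c(36, 0))
  expect_equal(embryos_per_mouse(tab, "control"), 7.2)
  expect_equal(embryos_per_mouse(tab, "XER"), 4.25)
  rescue <- implantation_table(
    group = c("intraluminal", "ip"),
    n_mice_injected = c(7, 10),
    n_mice_with_embryos = c(4, 6),
    n_mice_with_IS = c(3, 4),
    n_embryos_total = c(12, 27),
    n_embryos_implanted = c(7, 11))
  il <- rescue_percentages(rescue, "intraluminal")
  ip <- rescue_percentages(rescue, "ip")
  expect_equal(il$mouse_level_display, 75)
  expect_equal(il$embryo_level_display, 58)
  expect_equal(ip$mouse_level_display, 67)
  expect_equal(ip$embryo_level_display, 41)
  # full precision retained underneath the display rounding
  expect_equal(il$embryo_level_pct, 100 * 7 / 12, tolerance = 1e-12)
  # trivial edges
  zero <- implantation_table("z", 3, 1, 0, 0, 0)
  expect_error(embryos_per_mouse(zero, "z"), NA)
  expect_equal(embryos_per_mouse(zero, "z"), 0)
  expect_error(rescue_percentages(zero, "z"), "denominator")
  # invariants enforced
  expect_error(implantation_table("g", 2, 3, 1, 5, 2), "exceed")
  expect_error(implantation_table("g", 3, 2, 3, 5, 2), "exceed")
  expect_error(implantation_table("g", 3, 2, 1, 5, 6), "exceed")
})
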