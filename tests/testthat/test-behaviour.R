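test_that("naming responses score against canonical names and synonyms", {
  targets <- data.frame(item = c("i1", "i2", "i3"),
                        name = c("apple", "mug", "wolf"),
                        synonyms = c("", "cup", ""),
                        stringsAsFactors = FALSE)
  resp <- data.frame(participant = "p1", group = "control",
                     item = c("i1", "i2", "i3"),
                     response = c("Apple", "cup", "dog"),
                     stringsAsFactors = FALSE)
  sc <- score_naming(resp, targets)
  expect_equal(sc$correct, c(1L, 1L, 0L))
  # missing response scores 0 and is logged
  resp$response[3] <- NA
  sc2 <- score_naming(resp, targets)
  expect_equal(sc2$correct[3], 0L)
  expect_equal(attr(sc2, "n_missing"), 1L)
  resp$item[1] <- "i99"
  expect_error(score_naming(resp, targets), "unknown item")
})

test_that("accuracy summaries use participant means then between-participant SEM", {
  acc <- data.frame(
    participant = rep(c("p1", "p2"), each = 10),
    group = "g",
    correct = c(rep(c(1L, 0L), 5),            # p1: 50%
                rep(1L, 7), rep(0L, 3)))      # p2: 70%
  s <- accuracy_summary(acc, by = "group")
  expect_equal(s$mean_pct, (50 + 70) / 2)
  expect_equal(s$sem_pct, 10)    # SD(50,70)/sqrt(2)
  allcorrect <- data.frame(participant = "p1", group = "g",
                           correct = rep(1L, 6))
  one <- accuracy_summary(allcorrect, by = "group")
  expect_equal(one$mean_pct, 100)
  expect_equal(one$sem_pct, 0)
})

test_that("fixture group means reproduce every printed naming cell", {
  t4 <- load_fixture("table4_naming")
  printed <- load_fixture("table4_naming", rows = "all")
  printed <- printed[printed$row_type == "group_mean" &
                       printed$group != "Controls", ]
  cols <- c("all", "living", "nonliving", "animal", "tool", "fruit_veg",
            "vehicle")
  # the printed rows were rounded from unrounded data, the fixture rows are
  # themselves rounded, so recomputation can land one integer step away
  for (g in printed$group) {
    sub <- t4[t4$group == g, cols]
    expect_true(all(abs(round(colMeans(sub)) -
                          unlist(printed[printed$group == g, cols])) <= 1))
  }
})

test_that("mixed ANOVA recovers a pure group effect and matches one-way ANOVA", {
  set.seed(21)
  ids <- sprintf("p%02d", 1:8)
  grp <- rep(c("a", "b"), each = 4)
  base <- rnorm(8) + ifelse(grp == "a", 0, 2)
  d <- data.frame(participant = rep(ids, each = 2),
                  group = rep(grp, each = 2),
                  cond = rep(c("w1", "w2"), 8),
                  acc = rep(base, each = 2))     # no within effect at all
  res <- mixed_anova(d, "acc", "participant", "group", "cond")
  fg <- res[res$effect == "group", ]
  ow <- summary(stats::aov(base ~ factor(grp)))[[1]]
  expect_equal(fg$F, ow[1, "F value"], tolerance = 1e-10)
  expect_equal(fg$df1, ow[1, "Df"])
  expect_equal(fg$df2, ow[2, "Df"])
  within_rows <- res[res$effect %in% c("cond", "group:cond"), ]
  expect_true(all(within_rows$degenerate))  # zero within variance
  # one-level within factor reduces to the classical one-way ANOVA
  d1 <- d[d$cond == "w1", ]
  res1 <- mixed_anova(d1, "acc", "participant", "group", "cond")
  expect_equal(res1$F, ow[1, "F value"], tolerance = 1e-10)
})

test_that("mixed ANOVA validates its design", {
  d <- data.frame(participant = rep(1:4, each = 2), group = rep(c("a", "b"), each = 4),
                  cond = rep(c("w1", "w2"), 4), acc = rnorm(8))
  expect_error(mixed_anova(d[-1, ], "acc", "participant", "group", "cond"),
               "unbalanced")
  d$group <- "a"
  expect_error(mixed_anova(d, "acc", "participant", "group", "cond"),
               "2 groups")
  d2 <- data.frame(participant = rep(1:3, each = 2),
                   group = c("a", "a", "a", "a", "b", "b"),
                   cond = rep(c("w1", "w2"), 3), acc = rnorm(6))
  expect_error(mixed_anova(d2, "acc", "participant", "group", "cond"),
               "2 participants")
  dc <- data.frame(participant = rep(1:6, each = 2),
                   group = rep(c("a", "b"), each = 6),
                   cond = rep(c("w1", "w2"), 6), acc = 1)
  resc <- mixed_anova(dc, "acc", "participant", "group", "cond")
  expect_true(all(resc$degenerate))
  expect_true(all(resc$F == 0 | !is.finite(resc$p) | is.na(resc$p)))
})

test_that("t tests reproduce the printed group comparisons", {
  vols <- load_fixture("table1_volumes")
  vd <- vols$lesion_volume_cm3[vols$group == "vATL-damaged"]
  vi <- vols$lesion_volume_cm3[vols$group == "vATL-intact"]
  tr <- t_test(vd, vi)
  expect_equal(tr$df, 12)
  expect_equal(round(tr$statistic, 2), 0.16)
  t8 <- load_fixture("table8_wpm")
  intact <- t8[t8$group == "vATL-intact", ]
  trp <- t_test(intact$close, intact$distant, paired = TRUE)
  expect_equal(trp$df, 3)
  expect_equal(abs(trp$statistic), 3.67, tolerance = 0.02)
})

test_that("Welch equals pooled when variances and sizes are equal, and zero-variance is handled", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)   # equal variance, equal n
  tp <- t_test(x, y, welch = FALSE)
  tw <- t_test(x, y, welch = TRUE)
  expect_equal(tp$statistic, tw$statistic, tolerance = 1e-12)
  expect_equal(tp$df, tw$df, tolerance = 1e-12)
  z <- t_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(z$statistic, 0)
  expect_equal(z$p, 1)
  expect_true("zero_variance" %in% z$flags)
  expect_error(t_test(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  # one-tailed p is half the two-tailed p in the hypothesised direction
  set.seed(4)
  a <- rnorm(10, 1); b <- rnorm(10)
  t2 <- t_test(a, b, tail = "two")
  t1 <- t_test(a, b, tail = "one",
               direction = if (mean(a) > mean(b)) "greater" else "less")
  expect_equal(t1$p, t2$p / 2, tolerance = 1e-12)
})

test_that("item-wise ANCOVA interaction behaves under null and constructed effects", {
  set.seed(31)
  n <- 60
  cov <- rnorm(n)
  items <- sprintf("i%03d", 1:n)
  # identical covariate effect across groups (shared item noise, different
  # intercepts) -> interaction sum of squares is exactly zero
  e <- rnorm(n, 0, 0.05)
  base <- 0.5 + 0.1 * cov + e
  d0 <- data.frame(item = rep(items, 3),
                   group = rep(c("g1", "g2", "g3"), each = n),
                   accuracy = c(base, base + 0.1, base - 0.2))
  tr0 <- itemwise_ancova_interaction(d0, setNames(cov, items))
  expect_lt(tr0$statistic, 1e-10)
  expect_gt(tr0$p, 0.999)
  # matches a normal-equations fit on a small table
  set.seed(32)
  d1 <- data.frame(item = rep(items[1:10], 2),
                   group = rep(c("g1", "g2"), each = 10),
                   accuracy = runif(20))
  cv <- setNames(cov[1:10], items[1:10])
  tr1 <- itemwise_ancova_interaction(d1, cv)
  X <- model.matrix(~ factor(group) * cv[as.character(item)], data = d1)
  b <- solve(t(X) %*% X, t(X) %*% d1$accuracy)
  rss1 <- sum((d1$accuracy - X %*% b)^2)
  X0 <- X[, 1:3]
  b0 <- solve(t(X0) %*% X0, t(X0) %*% d1$accuracy)
  rss0 <- sum((d1$accuracy - X0 %*% b0)^2)
  Fo <- ((rss0 - rss1) / 1) / (rss1 / (20 - 4))
  expect_equal(tr1$statistic, Fo, tolerance = 1e-10)
  expect_equal(tr1$df, c(1, 16))
  expect_error(itemwise_ancova_interaction(d1, setNames(rep(1, 10), items[1:10])),
               "constant")
})

test_that("Fisher transform is odd, increasing, and inverts tanh", {
  z <- seq(-5, 5, length.out = 41)
  expect_equal(fisher_z(tanh(z)), z, tolerance = 1e-12)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_true(all(diff(fisher_z(seq(-0.99, 0.99, 0.01))) > 0))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(0), 0)
})

test_that("accuracy-covariate correlations flag perfect participant correlations", {
  items <- sprintf("i%02d", 1:8)
  cov <- setNames(c(0, 0, 0, 0, 1, 1, 1, 1), items)
  acc <- data.frame(participant = "p1", group = "g", item = items,
                    correct = c(0, 0, 0, 0, 1, 1, 1, 1))
  pc <- accuracy_covariate_correlations(acc, list(cv = cov),
                                        level = "participant")
  expect_equal(pc$r, 1)
  expect_true(is.infinite(pc$z))
  expect_true(pc$flagged)
  # group level correlates item means and difference scores with covariates
  set.seed(41)
  acc2 <- do.call(rbind, lapply(c("p1", "p2", "p3", "p4"), function(p)
    data.frame(participant = p,
               group = if (p %in% c("p1", "p2")) "g1" else "g2",
               item = items, correct = rbinom(8, 1, 0.7))))
  gc <- accuracy_covariate_correlations(acc2, list(cv = cov), level = "group")
  expect_true(all(c("g1", "g2", "g1 - g2") %in% gc$contrast))
  im <- aggregate(correct ~ item + group, acc2, mean)
  g1 <- im$correct[im$group == "g1"][match(items, im$item[im$group == "g1"])]
  expect_equal(gc$r[gc$contrast == "g1"], oracle_pearson(cov, g1)$r,
               tolerance = 1e-12)
})
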