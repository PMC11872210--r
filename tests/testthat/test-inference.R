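test_that("Box-Cox fixed-lambda transforms match their closed forms and invert exactly", {
  y <- c(0.5, 1, 2, 7.3)
  expect_equal(boxcox_transform(y, lambda = 1)$transformed, y - 1)
  expect_equal(boxcox_transform(y, lambda = 0)$transformed, log(y))
  for (l in c(-1.5, -0.3, 0, 0.5, 1, 2)) {
    z <- boxcox_transform(y, lambda = l)$transformed
    expect_equal(inv_boxcox(z, l), y, tolerance = 1e-12)
  }
  expect_error(boxcox_transform(c(1, 0, 2)), "positive")
  expect_error(boxcox_transform(c(1, -4)), "positive")
})

test_that("profile-likelihood lambda recovers 0 for lognormal data and agrees with MASS", {
  set.seed(20)
  y <- exp(rnorm(10000, sd = 0.6))
  bc <- boxcox_transform(y)
  expect_lt(abs(bc$lambda), 0.1)

  set.seed(21)
  y2 <- (rnorm(400, 10, 1))^2
  bc2 <- boxcox_transform(y2)
  ref <- MASS::boxcox(y2 ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_lt(abs(bc2$lambda - ref$x[which.max(ref$y)]), 0.011)
})

balanced_records <- function(seed, effects = c(A = 0, B = 0, C = 0), reps = 3,
                             sd = 1, mu = 10) {
  set.seed(seed)
  g <- expand.grid(replicate = seq_len(reps),
                   cytotype = c("hybrid", "allopolyploid"),
                   water = c("well-watered", "drought"),
                   co2 = c("ambient", "elevated"),
                   stringsAsFactors = FALSE)
  g$individual <- paste0(substr(g$cytotype, 1, 1), g$replicate)
  g$y <- mu + effects["A"] * (g$cytotype == "hybrid") +
    effects["B"] * (g$water == "drought") +
    effects["C"] * (g$co2 == "elevated") + rnorm(nrow(g), sd = sd)
  g
}

test_that("sequential sums of squares match the balanced-design contrast oracle", {
  d <- balanced_records(1, effects = c(A = 2, B = -1, C = 0.5))
  a <- factorial_anova(d, "y", transform = FALSE, aggregate = FALSE)
  oracle <- oracle_balanced_ss(d$y, d$cytotype, d$water, d$co2)
  got <- stats::setNames(a$terms$sumsq, a$terms$term)
  expect_equal(unname(got["cytotype"]), unname(oracle["A"]), tolerance = 1e-9)
  expect_equal(unname(got["water"]), unname(oracle["B"]), tolerance = 1e-9)
  expect_equal(unname(got["co2"]), unname(oracle["C"]), tolerance = 1e-9)
  expect_equal(unname(got["cytotype:water"]), unname(oracle["AB"]), tolerance = 1e-9)
  expect_equal(unname(got["cytotype:co2"]), unname(oracle["AC"]), tolerance = 1e-9)
  expect_equal(unname(got["water:co2"]), unname(oracle["BC"]), tolerance = 1e-9)
  expect_equal(unname(got["cytotype:water:co2"]), unname(oracle["ABC"]),
               tolerance = 1e-9)
  # term + residual df account for N - 1
  expect_equal(sum(a$terms$df) + a$residual$df, nrow(d) - 1)
})

test_that("balanced designs are order-invariant and sequential SS always sum to the total", {
  d <- balanced_records(2, effects = c(A = 1, B = 1, C = 1))
  a <- factorial_anova(d, "y", transform = FALSE, aggregate = FALSE)
  # swap the roles of the water and co2 factors: on a balanced design the
  # per-term SS set is unchanged (orthogonality)
  d2 <- d
  d2$water <- ifelse(d$co2 == "ambient", "well-watered", "drought")
  d2$co2 <- ifelse(d$water == "well-watered", "ambient", "elevated")
  a2 <- factorial_anova(d2, "y", transform = FALSE, aggregate = FALSE)
  expect_equal(sort(a$terms$sumsq), sort(a2$terms$sumsq), tolerance = 1e-9)

  # unbalanced: delete rows; sequential SS still decompose the total
  d3 <- d[-c(1, 5, 9, 10), ]
  a3 <- factorial_anova(d3, "y", transform = FALSE, aggregate = FALSE)
  total <- sum((d3$y - mean(d3$y))^2)
  expect_equal(sum(a3$terms$sumsq) + a3$residual$sumsq, total,
               tolerance = 1e-9)
})

test_that("a constant response carries no variance and empty cells warn", {
  d <- balanced_records(3, sd = 0)
  d$y <- 5
  a <- factorial_anova(d, "y", transform = FALSE, aggregate = FALSE)
  expect_equal(sum(a$terms$sumsq), 0, tolerance = 1e-12)
  d4 <- balanced_records(4)
  d4 <- d4[!(d4$cytotype == "hybrid" & d4$water == "drought" &
               d4$co2 == "elevated"), ]
  expect_warning(factorial_anova(d4, "y", transform = FALSE, aggregate = FALSE),
                 "empty")
})

test_that("pot-level records aggregate to individual x treatment means before testing", {
  rec <- generate_greenhouse(design_spec(seed = 31), spartina_trait_model())
  a <- factorial_anova(rec, "biomass", transform = FALSE)
  expect_equal(nrow(a$data), 24)  # 6 individuals x 4 treatment cells
  agg <- tapply(rec$biomass[rec$survived],
                list(rec$individual[rec$survived],
                     interaction(rec$water, rec$co2)[rec$survived]),
                mean, na.rm = TRUE)
  expect_equal(sort(a$data$y), sort(as.numeric(agg)), tolerance = 1e-12)
})

test_that("Tukey HSD reduces to the pooled t-test at two groups and is conservative beyond", {
  set.seed(8)
  g2 <- data.frame(y = rnorm(20, rep(c(0, 1), each = 10)),
                   group = rep(c("a", "b"), each = 10))
  a2 <- one_way_anova(g2$y, g2$group)
  tk <- tukey_hsd(a2)
  tt <- t.test(y ~ group, data = g2, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-9)

  # two groups with identical values: difference 0, adjusted p = 1
  same_groups <- one_way_anova(rep(c(2, 5, 9, 2, 5, 9), 2),
                               rep(c("g1", "g2"), each = 6))
  tk_same <- tukey_hsd(same_groups)
  expect_equal(tk_same$diff, 0, tolerance = 1e-12)
  expect_equal(tk_same$p_adj, 1, tolerance = 1e-9)

  set.seed(9)
  g3 <- data.frame(y = rnorm(30, rep(c(0, 0.8, 1.6), each = 10)),
                   group = rep(c("a", "b", "c"), each = 10))
  a3 <- one_way_anova(g3$y, g3$group)
  tk3 <- tukey_hsd(a3)
  ms_res <- a3$residual$meansq; df_res <- a3$residual$df
  means <- tapply(g3$y, g3$group, mean)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    tstat <- abs(diff(means[pair])) / sqrt(ms_res * (1 / 10 + 1 / 10))
    p_unadj <- 2 * pt(-tstat, df_res)
    p_adj <- tk3$p_adj[tk3$pair == paste(rev(pair), collapse = "-") |
                         tk3$pair == paste(pair, collapse = "-")]
    expect_gte(p_adj + 1e-9, p_unadj)  # studentized-range conservativeness
  }

  set.seed(10)
  far <- data.frame(y = rnorm(30, rep(c(0, 10, 20), each = 10), sd = 0.1),
                    group = rep(c("a", "b", "c"), each = 10))
  expect_true(all(tukey_hsd(one_way_anova(far$y, far$group))$p_adj < 0.001))
})

test_that("one-way ANOVA has the expected degrees of freedom and zero F for identical groups", {
  set.seed(12)
  v6 <- rnorm(30); g6 <- rep(paste0("I", 1:6), each = 5)
  a6 <- one_way_anova(v6, g6)
  expect_equal(a6$terms$df, 5)
  v2 <- rnorm(12); g2 <- rep(c("hybrid", "allopolyploid"), each = 6)
  expect_equal(one_way_anova(v2, g2)$terms$df, 1)
  flat <- one_way_anova(rep(c(1, 2, 3), 3), rep(c("x", "y", "z"), each = 3))
  expect_equal(flat$terms$F, 0)
  expect_error(one_way_anova(1:5, rep("only", 5)), "2 groups")
})

test_that("assumption checks behave on their canonical inputs", {
  # identical groups -> Levene statistic 0
  r <- rep(c(-1, 0, 1), 4)
  g <- rep(c("a", "b", "c", "d"), each = 3)
  chk <- assumption_checks(r, g)
  expect_equal(chk$statistic[chk$check == "levene_brown_forsythe"], 0,
               tolerance = 1e-12)

  # exact normal quantiles -> Shapiro-Wilk W near 1
  qn <- qnorm(ppoints(50))
  chk2 <- assumption_checks(qn, rep(c("a", "b"), 25))
  expect_gt(chk2$statistic[chk2$check == "shapiro_wilk"], 0.99)
  expect_error(assumption_checks(c(1, 2), c("a", "b")), "3 <= n")
})

test_that("the Levene test detects a doubled spread with high power", {
  set.seed(500)
  hits <- 0
  for (s in 1:200) {
    y <- c(rnorm(200, sd = 1), rnorm(200, sd = 2))
    g <- rep(c("a", "b"), each = 200)
    p <- assumption_checks(y, g)$p[2]
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.9)
})

test_that("relative change reproduces the reported drought biomass decreases", {
  expect_equal(as.numeric(relative_decrease(13.8, 5.9)), -57)
  expect_equal(as.numeric(relative_decrease(9.5, 5.0)), -47)
  expect_equal(as.numeric(relative_decrease(7.7, 7.7)), 0)
  expect_equal(attr(relative_decrease(10, 5), "raw"), -50)
  expect_error(relative_decrease(0, 5), "positive")
})
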