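test_that("barycenter tables are built and integrity-checked", {
  results <- list()
  for (s in sprintf("S%02d", 1:10))
    for (tk in paste0("task", 1:7))
      results <- c(results, list(fakeResult(s, tk, 20, runif(1), runif(1))))
  tab <- buildBarycenterTable(results)
  expect_equal(nrow(tab), 70L)
  expect_named(tab, c("subject", "task", "level_pct_mvc", "X", "Y"))

  expect_equal(nrow(buildBarycenterTable(list())), 0L)

  dup <- c(results, results[1])
  expect_error(buildBarycenterTable(dup), "duplicate")

  bad <- fakeResult("S01", "t", 20, 0.1, 0.2)
  bad@meta$subject <- NULL
  expect_error(buildBarycenterTable(list(bad)), "metadata")
})

test_that("two-way ANOVA matches the closed-form 2x2 sums of squares", {
  tab <- data.frame(subject = c("a", "a", "b", "b"),
                    task = c("t1", "t2", "t1", "t2"),
                    level_pct_mvc = 20,
                    X = c(1.0, 2.0, 1.5, 3.1), Y = 0)
  out <- twowayAnova(tab, "X")
  # independent closed-form oracle
  y <- tab$X
  gm <- mean(y)
  ssSubj <- 2 * sum((tapply(y, tab$subject, mean) - gm)^2)
  ssTask <- 2 * sum((tapply(y, tab$task, mean) - gm)^2)
  ssTot <- sum((y - gm)^2)
  ssRes <- ssTot - ssSubj - ssTask
  expect_equal(out$sumsq, c(ssSubj, ssTask, ssRes))
  expect_equal(out$df, c(1, 1, 1))
  expect_equal(out$F[2], (ssTask / 1) / (ssRes / 1))
  expect_equal(out$p[2], pf(out$F[2], 1, 1, lower.tail = FALSE))
})

test_that("sums of squares partition total variance in balanced designs", {
  set.seed(61)
  tab <- simulateTable(8, setNames(rnorm(5, 0, 0.05), paste0("t", 1:5)))
  for (axis in c("X", "Y")) {
    out <- twowayAnova(tab, axis)
    y <- tab[[axis]]
    expect_equal(sum(out$sumsq), sum((y - mean(y))^2))
  }
})

test_that("a strong task effect is detected with high power", {
  set.seed(62)
  hits <- 0L
  for (rep in 1:200) {
    tab <- simulateTable(10, c(t1 = 0, t2 = 0.04, t3 = 0.08), sd = 0.02)
    out <- twowayAnova(tab, "X")
    if (out$p[out$term == "task"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("unbalanced or deficient designs are rejected with explanation", {
  tab <- simulateTable(4, c(t1 = 0, t2 = 0.1))
  expect_error(twowayAnova(tab[-1, ], "X"), "balanced")
  expect_error(twowayAnova(tab[tab$task == "t1", ], "X"), "at least 2")
})

test_that("three-way ANOVA separates direction from force level", {
  set.seed(63)
  rows <- expand.grid(subject = sprintf("S%02d", 1:10),
                      task = c("ext", "rad", "uln"),
                      level_pct_mvc = c(20, 50, 80),
                      stringsAsFactors = FALSE)
  shift <- c(ext = 0, rad = 0.1, uln = -0.1)
  rows$X <- shift[rows$task] + rnorm(nrow(rows), 0, 0.02)
  rows$Y <- rnorm(nrow(rows), 0, 0.02)
  out <- threewayAnova(rows, "X")
  expect_setequal(out$term, c("subject", "task", "level", "residual"))
  expect_lt(out$p[out$term == "task"], 0.05)
  expect_gt(out$p[out$term == "level"], 0.05)

  # orthogonality in a balanced design: relabelling force levels leaves the
  # direction F unchanged
  perm <- rows
  perm$level_pct_mvc <- c(`20` = 80, `50` = 20, `80` = 50)[
    as.character(perm$level_pct_mvc)]
  out2 <- threewayAnova(perm, "X")
  expect_equal(out2$F[out2$term == "task"], out$F[out$term == "task"])

  # null data: nothing should be strongly significant in a fixed seeded run
  rows$X <- rnorm(nrow(rows), 0, 0.02)
  out3 <- threewayAnova(rows, "X")
  expect_true(all(out3$p[out3$term != "residual"] > 0.01))
})

test_that("Holm-Sidak matches a hand-evaluated step-down", {
  # single p: identity at m = 1
  one <- holmSidak(0.04)
  expect_equal(one$p_adjusted, 0.04)
  expect_true(one$reject)

  expect_false(any(holmSidak(rep(1, 5))$reject))

  # manual step-down for p = {0.001, 0.02, 0.04}:
  #   1 - (1 - 0.001)^3 = 0.002997001
  #   1 - (1 - 0.02)^2  = 0.0396
  #   1 - (1 - 0.04)^1  = 0.04      (cummax keeps monotonicity)
  hs <- holmSidak(c(0.04, 0.001, 0.02))
  expect_equal(hs$p_adjusted, c(0.04, 1 - 0.999^3, 1 - 0.98^2))
  expect_true(all(hs$reject))

  expect_error(holmSidak(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Holm-Sidak is monotone and permutation invariant", {
  set.seed(64)
  for (rep in 1:20) {
    p <- runif(sample(2:10, 1))
    hs <- holmSidak(p)
    expect_true(all(diff(hs$p_adjusted[order(p)]) >= 0))
    perm <- sample(length(p))
    hs2 <- holmSidak(p[perm])
    expect_equal(hs2$p_adjusted, hs$p_adjusted[perm])
  }
})

test_that("pairwise discrimination reports C(n,2) pairs per axis", {
  set.seed(65)
  tab <- simulateTable(10, setNames(seq(0, 0.3, length.out = 7) ,
                                    paste0("t", 1:7)))
  rep <- pairwiseDiscrimination(tab)
  expect_equal(sum(rep$axis == "X"), 21L)
  expect_equal(sum(rep$axis == "Y"), 21L)
})

test_that("identical generating centres are not called separable", {
  set.seed(66)
  tab <- simulateTable(10, c(a = 0.1, b = 0.1), sd = 0.02)
  rep <- pairwiseDiscrimination(tab)
  expect_false(any(rep$separable))
})

test_that("a pure longitudinal separation is found on Y but not X", {
  set.seed(67)
  hitsY <- hitsX <- 0L
  for (rep in 1:20) {
    tab <- simulateTable(10, c(a = 0.1, b = 0.1),
                         taskMeansY = c(a = 0.20, b = 0.287), sd = 0.012)
    out <- pairwiseDiscrimination(tab)
    if (out$separable[out$axis == "Y"]) hitsY <- hitsY + 1L
    if (out$separable[out$axis == "X"]) hitsX <- hitsX + 1L
  }
  expect_gte(hitsY / 20, 0.9)
  expect_lte(hitsX / 20, 0.2)
})
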