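mkTable <- function(...) {
  groups <- list(...)
  do.call(rbind, lapply(names(groups), function(g)
    data.frame(group = g, ai = groups[[g]])))
}

# seeded AI-like draws clipped into [0, 1]
rAI <- function(n, mean, sd) pmin(pmax(stats::rnorm(n, mean, sd), 0), 1)

test_that("group summaries report n, mean and sample SD", {
  tbl <- mkTable(a = c(0.25, 0.5, 0.75), b = rep(0.5, 3), single = 0.4)
  s <- summarizeGroups(tbl)
  expect_equal(s$n, c(3, 3, 1))
  expect_equal(s$mean, c(0.5, 0.5, 0.4))
  expect_equal(s$sd[1], sd(c(0.25, 0.5, 0.75)))
  expect_equal(s$sd[2], 0)
  expect_true(is.na(s$sd[3]))

  set.seed(31)
  x <- rAI(12, 0.62, 0.05)
  s2 <- summarizeGroups(data.frame(group = "4dpf", ai = x))
  expect_equal(s2$mean, mean(x), tolerance = 1e-12)
  expect_equal(s2$sd, sd(x), tolerance = 1e-12)
})

test_that("star assignment follows the conventional ladder exactly", {
  p <- c(0.2, 0.05, 0.049, 0.01, 0.0099, 0.001, 0.00099, 1e-4, 9.9e-5, NA)
  expect_equal(pStars(p),
               c("ns", "ns", "*", "*", "**", "**", "***", "***", "****", NA))
})

test_that("the omnibus ANOVA holds its size under the null", {
  set.seed(101)
  rejected <- 0L
  for (r in 1:100) {
    tbl <- mkTable(g1 = rAI(15, 0.5, 0.1), g2 = rAI(15, 0.5, 0.1),
                   g3 = rAI(15, 0.5, 0.1))
    rep <- anovaTukey(tbl)
    if (rep$p.value[rep$test == "anova"] <= 0.05) rejected <- rejected + 1L
  }
  expect_lte(rejected, 10L)  # > 90% of null replicates not rejected
})

test_that("a development-sized effect is detected at p < 0.0001", {
  set.seed(102)
  hits <- 0L
  for (r in 1:100) {
    tbl <- mkTable(early = rAI(12, 0.2, 0.08), late = rAI(12, 0.6, 0.08))
    rep <- anovaTukey(tbl)
    if (rep$p.value[rep$test == "anova"] < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("Tukey comparisons of identical groups are non-significant", {
  set.seed(103)
  x <- rAI(10, 0.5, 0.1)
  tbl <- rbind(mkTable(a = x, b = x), mkTable(c = rAI(10, 0.9, 0.02)))
  rep <- anovaTukey(tbl)
  pAB <- rep$p.value[rep$comparison %in% c("b-a", "a-b")]
  expect_gt(pAB, 0.99)
})

test_that("Tukey adjustment never reports below the unadjusted p", {
  set.seed(104)
  for (r in 1:20) {
    tbl <- mkTable(a = rAI(8, 0.4, 0.1), b = rAI(8, 0.5, 0.1),
                   c = rAI(8, 0.55, 0.1), d = rAI(8, 0.7, 0.1))
    rep <- anovaTukey(tbl)
    pairs <- rep[rep$test == "tukey", ]
    expect_true(all(pairs$p.value >= pairs$p.unadjusted - 1e-12))
  }
})

test_that("degenerate zero-variance input yields a report, not a crash", {
  tbl <- mkTable(a = rep(0.4, 3), b = rep(0.4, 3))
  rep <- anovaTukey(tbl)
  expect_true(is.na(rep$p.value))
  tbl2 <- mkTable(a = rep(0.4, 3), b = rep(0.6, 3))
  rep2 <- anovaTukey(tbl2)
  expect_equal(rep2$p.value, 0)
  expect_error(anovaTukey(mkTable(a = c(0.1, 0.2))), "2 groups")
  expect_error(anovaTukey(mkTable(a = c(0.1, 0.2), b = 0.3)), "n >= 2")
})

wTable <- function(tp, wounded, unwounded) {
  rbind(data.frame(timepoint = tp, condition = "wounded", ai = wounded),
        data.frame(timepoint = tp, condition = "unwounded", ai = unwounded))
}

test_that("identical samples give t = 0, p = 1", {
  x <- c(0.5, 0.5, 0.5)
  rep <- woundedVsUnwoundedTTests(wTable("5dpi", x, x))
  expect_equal(rep$statistic, 0)
  expect_equal(rep$p.value, 1)
  expect_equal(rep$stars, "ns")
})

test_that("an early-repair effect is detected, a recovered one is not", {
  # early-repair group separation (0.34 +/- 0.15 vs 0.60 +/- 0.11, n = 10):
  # the exact noncentrality is ~4.4, so power is ~0.99 at alpha = 0.05 and
  # ~0.68 at alpha = 0.001; the simulation is checked against both
  set.seed(105)
  early05 <- early001 <- 0L
  late <- 0L
  for (r in 1:100) {
    e <- woundedVsUnwoundedTTests(
      wTable("5dpi", rAI(10, 0.34, 0.15), rAI(10, 0.60, 0.11)))
    if (e$p.value < 0.05) early05 <- early05 + 1L
    if (e$p.value < 1e-3) early001 <- early001 + 1L
    l <- woundedVsUnwoundedTTests(
      wTable("16dpi", rAI(10, 0.50, 0.13), rAI(10, 0.54, 0.10)))
    if (l$p.value > 0.05) late <- late + 1L
  }
  expect_gte(early05, 90L)
  expect_gte(early001, 50L)
  expect_gte(late, 80L)
})

test_that("the t test holds its size under a seeded null simulation", {
  set.seed(106)
  rejected <- 0L
  for (r in 1:2000) {
    rep <- woundedVsUnwoundedTTests(
      wTable("t0", rAI(10, 0.5, 0.08), rAI(10, 0.5, 0.08)))
    if (rep$p.value <= 0.05) rejected <- rejected + 1L
  }
  expect_gte(rejected / 2000, 0.03)
  expect_lte(rejected / 2000, 0.07)
})

test_that("a timepoint missing one condition is skipped with a warning", {
  tbl <- rbind(wTable("5dpi", c(0.3, 0.35, 0.4), c(0.55, 0.6, 0.65)),
               data.frame(timepoint = "9dpi", condition = "wounded",
                          ai = c(0.4, 0.45)))
  expect_warning(rep <- woundedVsUnwoundedTTests(tbl), "9dpi")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$timepoint, "5dpi")
  expect_error(suppressWarnings(
    woundedVsUnwoundedTTests(tbl[tbl$timepoint == "9dpi", ])),
    "no testable")
})
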