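test_that("battery PCA matches an independent eigendecomposition", {
  set.seed(12)
  b <- simulateTestBattery(matrix(rnorm(18 * 4), 18, 4), seed = 12)
  p <- pcaBattery(b, nKeep = 4)
  # proportions sum to one over all components
  expect_equal(sum(p@proportionOfVariance), 1)
  # oracle: direct eigendecomposition of the correlation matrix
  e <- eigen(stats::cor(as.matrix(b)), symmetric = TRUE)
  expect_equal(p@eigenvalues, e$values, tolerance = 1e-10)
  for (j in 1:4) {
    v <- e$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v  # same orientation rule
    expect_equal(unname(p@loadings[, j]), v, tolerance = 1e-8)
  }
  # row-permutation invariance and per-column affine invariance
  perm <- sample(nrow(b))
  p2 <- pcaBattery(b[perm, ], nKeep = 4)
  expect_equal(p2@proportionOfVariance, p@proportionOfVariance,
               tolerance = 1e-12)
  b3 <- sweep(sweep(as.matrix(b), 2, runif(13, 0.5, 3), "*"),
              2, rnorm(13), "+")
  p3 <- pcaBattery(as.data.frame(b3, check.names = FALSE), nKeep = 4)
  expect_equal(p3@proportionOfVariance, p@proportionOfVariance,
               tolerance = 1e-12)
  # degenerate inputs
  bc <- b; bc[["OF distance"]] <- 1
  expect_error(pcaBattery(bc), "OF distance")
  expect_error(pcaBattery(b[1, , drop = FALSE]), "subjects")
})

test_that("salient-loading assignment follows the two-sided 0.4 rule", {
  ref <- read.csv(refPath("reference_pca_loadings.csv"), check.names = FALSE)
  L <- as.matrix(ref[, -1])
  rownames(L) <- ref$item
  sal <- salientAssignment(L[, 1:4], cutoff = 0.4)
  pick <- function(item) sal$component[sal$item == item]
  # a loading just above the cutoff assigns the item to that component
  expect_equal(pick("NO center area entry"), 1L)
  # an item salient on two components goes to the larger |loading|
  expect_equal(pick("OF center area entry"), 3L)
  expect_equal(sal$loading[sal$item == "OF center area entry"], -0.492)
  # an item under the cutoff everywhere stays unassigned
  expect_true(is.na(pick("TC animal area entry")))
  # negative loadings count (two-sided rule)
  expect_equal(pick("OF distance"), 3L)
  # idempotent and independent of item order
  perm <- sample(nrow(L))
  sal2 <- salientAssignment(L[perm, 1:4], cutoff = 0.4)
  sal2 <- sal2[match(sal$item, sal2$item), ]
  expect_equal(sal2$component, sal$component)
  expect_error(salientAssignment(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("Kaiser count uses a strict eigenvalue threshold", {
  expect_equal(kaiserCount(c(2.0, 1.5, 0.9)), 2L)
  expect_equal(kaiserCount(c(0.9, 0.5)), 0L)
  expect_equal(kaiserCount(c(1.0, 0.5)), 0L)  # exactly 1 is not counted
})

test_that("icc3k reproduces the two-way ANOVA oracle and classifies bands", {
  # pure subject + occasion structure: zero residual, ICC exactly 1
  m <- outer(c(1, 3, 7, 2), rep(1, 5)) + outer(rep(1, 4), c(0, 2, 1, 5, 3))
  r <- icc3k(m)
  expect_equal(r@value, 1.0)
  expect_equal(r@consistency, "substantial")
  # identical rows: no between-subject variance, undefined, classed low
  m2 <- matrix(rep(c(1, 2, 3, 4, 5), each = 4), 4, 5)
  r2 <- icc3k(m2)
  expect_true(is.na(r2@value))
  expect_equal(r2@consistency, "low")
  # random matrices match the independently coded oracle to 1e-10
  set.seed(42)
  for (i in 1:25) {
    mr <- matrix(rnorm(28), 4, 7)
    expect_equal(icc3k(mr)@value, aovICC3k(mr), tolerance = 1e-10)
  }
  # occasions with missing values are dropped and k adjusted
  mm <- cbind(m, NA)
  rm_ <- icc3k(mm)
  expect_equal(rm_@k, 5L)
  expect_equal(rm_@value, 1.0)
  expect_error(icc3k(m[, 1, drop = FALSE]), "2 complete occasions")
  # classification bands at the published worked values
  expect_equal(iccClass(0.760), "substantial")
  expect_equal(iccClass(0.447), "moderate")
  expect_equal(iccClass(0.000), "low")
  expect_equal(iccClass(0.4), "moderate")
  expect_equal(iccClass(0.7), "moderate")
  expect_equal(iccClass(-0.3), "low")
})

test_that("familiarity LRT handles planted, null and degenerate effects", {
  mk_data <- function(beta, seed) {
    set.seed(seed)
    subjects <- sprintf("s%02d", 1:12)
    df <- expand.grid(subject = subjects, partner = 1:3)
    df$familiar <- df$partner == 1
    b <- rnorm(12, 0, 1)
    df$proximity <- b[as.integer(factor(df$subject))] +
      beta * df$familiar + rnorm(nrow(df))
    df
  }
  # a 3-SD planted effect is detected
  r <- lmmFamiliarityLrt(mk_data(3, 1))
  expect_lt(r$p, 0.01)
  expect_equal(r$df, 1L)
  # the statistic is non-negative on null fits
  for (s in 2:6) {
    r0 <- lmmFamiliarityLrt(mk_data(0, s))
    expect_gte(r0$chi2, 0)
    expect_true(r0$p >= 0 && r0$p <= 1)
  }
  # constant familiarity: degenerate predictor
  d <- mk_data(0, 7); d$familiar <- TRUE
  rd <- lmmFamiliarityLrt(d)
  expect_equal(rd$chi2, 0)
  expect_equal(rd$p, 1)
  # a subject with a single row is rejected (drop two of s01's three rows)
  d2 <- mk_data(0, 8)
  d2 <- d2[-which(d2$subject == "s01")[1:2], ]
  expect_error(lmmFamiliarityLrt(d2), "at least 2 partner rows")
})

test_that("correlation panel matches the closed-form r and flags cells", {
  set.seed(21)
  n <- 12
  scores <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("PC1", "PC3")))
  idx <- data.frame(copy = scores[, 1], noise = rnorm(n))
  panel <- correlationPanel(scores, idx, cutoff = 0.4)
  r_copy <- panel[panel$component == "PC1" & panel$index == "copy", ]
  expect_equal(r_copy$r, 1)
  expect_true(r_copy$flagged)
  # brute-force covariance formula on a 12-point cell
  x <- scores[, 2]; y <- idx$noise
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- panel[panel$component == "PC3" & panel$index == "noise", ]
  expect_equal(got$r, brute, tolerance = 1e-12)
  # PC3 display inversion flips the sign of display values only
  expect_equal(got$display_r, -got$r)
  expect_equal(got$display_lo, -got$ci_hi)
  # Fisher CI covers the point estimate
  expect_true(got$ci_lo < got$r && got$r < got$ci_hi)
  # zero-variance column flagged undefined
  idx2 <- data.frame(flat = rep(1, n))
  expect_warning(expect_warning(p2 <- correlationPanel(scores, idx2),
                                "zero-variance"))
  expect_true(is.na(p2$r[1]))
})

test_that("Fisher intervals cover zero at the nominal rate", {
  set.seed(31)
  n <- 12
  cover <- vapply(1:400, function(i) {
    x <- rnorm(n); y <- rnorm(n)
    r <- cor(x, y)
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    lo <- tanh(z - 1.959964 * se); hi <- tanh(z + 1.959964 * se)
    lo <= 0 && 0 <= hi
  }, TRUE)
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("similarity analysis relates |score differences| to proximity", {
  set.seed(9)
  ids <- sprintf("s%d", 1:8)
  scores <- matrix(rnorm(8 * 2), 8, 2,
                   dimnames = list(ids, c("PC1", "PC2")))
  dy <- t(combn(ids, 2))
  d1 <- abs(scores[dy[, 1], 1] - scores[dy[, 2], 1])
  # proximity as an exact negative affine function of |dPC1|
  prox <- 5 - 2 * d1
  sim <- similarityAnalysis(scores, data.frame(a = dy[, 1], b = dy[, 2],
                                               proximity = prox))
  expect_equal(sim$r[sim$component == "PC1"], -1)
  # brute-force formula for the other component
  d2 <- abs(scores[dy[, 1], 2] - scores[dy[, 2], 2])
  brute <- cor(d2, prox)
  expect_equal(sim$r[sim$component == "PC2"], brute, tolerance = 1e-12)
  # identical scores: zero similarity variance, undefined and flagged
  same <- matrix(1, 8, 1, dimnames = list(ids, "PC1"))
  expect_warning(
    s2 <- similarityAnalysis(same, data.frame(a = dy[, 1], b = dy[, 2],
                                              proximity = prox)),
    "zero-variance")
  expect_true(is.na(s2$r[1]))
  expect_error(
    similarityAnalysis(scores, data.frame(a = dy[1:3, 1], b = dy[1:3, 2],
                                          proximity = prox[1:3])),
    "at least 4 dyads")
})
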