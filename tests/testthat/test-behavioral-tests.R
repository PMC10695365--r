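test_that("path length sums consecutive valid segments", {
  expect_equal(pathLength(rep(3, 10), rep(4, 10)), 0)
  # square of side 10 traversed once
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  expect_equal(pathLength(sq[, 1], sq[, 2]), 40)
  # random track equals an independent re-summation
  set.seed(4)
  x <- cumsum(rnorm(100)); y <- cumsum(rnorm(100))
  brute <- 0
  for (i in 2:100)
    brute <- brute + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  expect_equal(pathLength(x, y), brute)
  # invalid frames are skipped, consecutive valid frames bridged
  xv <- c(0, NA, 3); yv <- c(0, NA, 4)
  expect_equal(pathLength(xv, yv), 5)
  expect_error(pathLength(1, 1), "at least 2")
  # rigid rotation + translation leaves path length unchanged
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 12
  yr <- sin(th) * x + cos(th) * y - 3
  expect_equal(pathLength(xr, yr), brute, tolerance = 1e-10)
})

test_that("zone entries are outside-to-inside transitions only", {
  z <- zoneRect(10, 20, 10, 20)
  # never in zone
  expect_equal(zoneEntries(rep(1, 10), rep(1, 10), z), 0L)
  # in -> out -> in: one entry (start-inside does not count)
  x <- c(15, 15, 25, 25, 15, 15); y <- rep(15, 6)
  expect_equal(zoneEntries(x, y, z), 1L)
  # 6-frame boundary oscillation starting outside: 3 entries
  xo <- c(25, 15, 25, 15, 25, 15); yo <- rep(15, 6)
  expect_equal(zoneEntries(xo, yo, z), 3L)
  # entry counts stable under uniform 2x temporal upsampling
  xs <- c(25, 25, 15, 15, 25, 25, 15, 15, 25, 25, 15, 15)
  expect_equal(zoneEntries(xs, rep(15, 12), z), 3L)
})

test_that("apparatus zone maps tile as specified", {
  ofz <- openFieldZones()
  expect_equal(ofz$block_cm, 16)
  # central nine blocks span [16, 64]^2; object zone the central block
  expect_true(pointInZone(40, 40, ofz$center))
  expect_true(pointInZone(17, 17, ofz$center))
  expect_false(pointInZone(15, 40, ofz$center))
  expect_true(pointInZone(40, 40, ofz$object))
  expect_false(pointInZone(30, 40, ofz$object))
  tcz <- threeChamberZones()
  expect_true(pointInZone(10, 40, tcz$left))
  expect_true(pointInZone(40, 40, tcz$center))
  expect_true(pointInZone(70, 40, tcz$right))
  ez <- epmZones()
  expect_true(pointInZone(0, 30, ez$open))    # north open arm
  expect_true(pointInZone(-30, 0, ez$closed)) # west closed arm
  expect_true(pointInZone(0, 0, ez$hub))
  expect_false(pointInZone(30, 30, ez$open))
})

test_that("normalization, deltas and preference follow their definitions", {
  expect_equal(perTimeNormalize(300, 300), 1.0)
  expect_equal(perTimeNormalize(9, 300), 0.03)
  expect_equal(perTimeNormalize(100, 324), 100 / 324)
  expect_error(perTimeNormalize(5, 0), "positive")
  expect_equal(habituationDelta(5, 5), 0)
  expect_equal(habituationDelta(8, 5), 3)
  expect_equal(habituationDelta(2.1, 3.4), -1.3)
  expect_error(habituationDelta(NA, 3), "both phases")
  expect_equal(chamberPreference(6, 2), 0.75)
  expect_equal(chamberPreference(3, 3), 0.5)
  expect_equal(habituationDelta(0.75, 0.5), 0.25)
  expect_warning(p <- chamberPreference(0, 0), "undefined")
  expect_true(is.na(p))
})

test_that("glove durations merge overlapping same-label intervals", {
  log1 <- data.frame(label = "handling", start_s = 10, end_s = 25)
  expect_equal(gloveDurations(log1)[["handling"]], 15)
  log2 <- data.frame(label = c("approach", "approach"),
                     start_s = c(0, 5), end_s = c(10, 15))
  expect_equal(gloveDurations(log2)[["approach"]], 15)
  empty <- data.frame(label = character(), start_s = numeric(),
                      end_s = numeric())
  expect_equal(unname(gloveDurations(empty)), c(0, 0, 0))
  bad <- data.frame(label = "avoid", start_s = 5, end_s = 5)
  expect_error(gloveDurations(bad), "positive length")
  # disjoint intervals sum; other labels unaffected
  log3 <- data.frame(label = c("avoid", "avoid", "handling"),
                     start_s = c(0, 20, 1), end_s = c(5, 30, 2))
  d <- gloveDurations(log3)
  expect_equal(d[["avoid"]], 15)
  expect_equal(d[["handling"]], 1)
  expect_equal(d[["approach"]], 0)
})

test_that("scoreTestBattery assembles the 13 named columns", {
  mk_trial <- function(seed, dur = 300) {
    set.seed(seed)
    n <- 60
    list(track = data.frame(x = runif(n, 1, 79), y = runif(n, 1, 79)),
         duration_s = dur)
  }
  mk_epm <- function(seed) {
    set.seed(seed)
    n <- 60
    # wander the maze cross shape
    arm <- sample(c("n", "s", "e", "w", "c"), n, replace = TRUE)
    x <- ifelse(arm == "e", runif(n, 6, 54),
                ifelse(arm == "w", runif(n, -54, -6), runif(n, -4, 4)))
    y <- ifelse(arm == "n", runif(n, 6, 54),
                ifelse(arm == "s", runif(n, -54, -6), runif(n, -4, 4)))
    list(track = data.frame(x = x, y = y), duration_s = 300)
  }
  glove <- data.frame(label = c("approach", "handling", "avoid"),
                      start_s = c(0, 30, 100), end_s = c(12, 75, 130))
  trials <- lapply(setNames(nm = c("s1", "s2")), function(id) {
    s <- if (id == "s1") 1 else 2
    list(of = mk_trial(s), no_hab = mk_trial(s + 10),
         no_test = mk_trial(s + 20), tc_hab = mk_trial(s + 30),
         tc_test = mk_trial(s + 40), epm = mk_epm(s + 50),
         glove = glove, tc_animal_side = "left")
  })
  tab <- scoreTestBattery(trials)
  expect_equal(names(tab), batteryItems())
  expect_equal(nrow(tab), 2L)
  expect_equal(tab[["GL handling"]], c(45, 45))
  expect_true(all(is.finite(as.matrix(tab))))
})
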