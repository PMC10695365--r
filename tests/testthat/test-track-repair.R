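test_that("speed gate flags exactly the implausible frames", {
  tt <- (0:19) / 5
  # constant position: nothing flagged
  expect_true(all(flagImplausible(rep(10, 20), rep(10, 20), tt)))
  # single 200 cm jump at 5 Hz implies 1000 cm/s: exactly that frame flagged
  x <- rep(10, 20); x[8] <- 210
  ok <- flagImplausible(x, rep(10, 20), tt, maxSpeed = 100)
  expect_equal(which(!ok), 8L)
  # monotone 1 cm/frame drift is 5 cm/s: nothing flagged
  expect_true(all(flagImplausible(seq(0, 19), rep(5, 20), tt,
                                  maxSpeed = 100)))
  # speed is measured from the last *valid* frame
  x2 <- c(0, NA, 0.5, 300)
  ok2 <- flagImplausible(x2, rep(1, 4), (0:3) / 5,
                         valid = c(TRUE, FALSE, TRUE, TRUE), maxSpeed = 100)
  expect_equal(ok2, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(flagImplausible(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("resolveSwaps corrects labelled exchanges and stays put otherwise", {
  n <- 120
  # two parallel straight-line tracks 30 cm apart
  xa <- seq(5, 85, length.out = n); ya <- rep(10, n)
  xb <- seq(5, 85, length.out = n); yb <- rep(40, n)
  clean <- mkTS(list(xa, xb), list(ya, yb))
  r0 <- resolveSwaps(clean)
  expect_identical(coordsX(r0$tracks), coordsX(clean))
  expect_equal(r0$nSwapFrames, 0L)
  # exchange labels over frames 50-80
  x <- coordsX(clean); y <- coordsY(clean)
  idx <- 50:80
  x[idx, ] <- x[idx, 2:1]; y[idx, ] <- y[idx, 2:1]
  swapped <- mkTS(list(x[, 1], x[, 2]), list(y[, 1], y[, 2]))
  r1 <- resolveSwaps(swapped)
  expect_equal(coordsX(r1$tracks), coordsX(clean))
  expect_equal(coordsY(r1$tracks), coordsY(clean))
  # output is a per-frame permutation of input positions
  for (f in c(1, 49, 60, 100)) {
    expect_setequal(unname(coordsX(r1$tracks)[f, ]),
                    unname(coordsX(swapped)[f, ]))
  }
})

test_that("crossing tracks keep label continuity without oscillation", {
  n <- 101
  # two tracks crossing once at the midpoint
  xa <- seq(0, 80, length.out = n); ya <- seq(0, 50, length.out = n)
  xb <- seq(0, 80, length.out = n); yb <- seq(50, 0, length.out = n)
  ts <- mkTS(list(xa, xb), list(ya, yb))
  r <- resolveSwaps(ts)
  expect_equal(coordsY(r$tracks)[, 1], ya)
  expect_equal(coordsY(r$tracks)[, 2], yb)
  expect_equal(r$nSwapFrames, 0L)
})

test_that("gap interpolation is linear, bounded and never extrapolates", {
  # 3-frame gap between (0,0) and (4,0)
  x <- c(0, NA, NA, NA, 4); y <- c(0, NA, NA, NA, 0)
  g <- interpolateGaps(x, y, maxGap = 5)
  expect_equal(g$x, c(0, 1, 2, 3, 4))
  expect_equal(g$y, rep(0, 5))
  expect_equal(which(g$imputed), 2:4)
  # gap longer than maxGap untouched
  x2 <- c(0, rep(NA, 10), 11)
  g2 <- interpolateGaps(x2, x2 * 0, maxGap = 5)
  expect_true(all(is.na(g2$x[2:11])))
  expect_false(any(g2$valid[2:11]))
  # leading-edge gap has no left flank: remains invalid
  x3 <- c(NA, NA, 2, 3)
  g3 <- interpolateGaps(x3, c(NA, NA, 0, 0), maxGap = 5)
  expect_false(any(g3$valid[1:2]))
  expect_error(interpolateGaps(c(NA, NA), c(NA, NA), maxGap = 2),
               "no valid frames")
})

test_that("estimationAccuracy counts within-tolerance animal-frames", {
  n <- 50
  ref <- mkTS(list(seq(1, 50), seq(1, 50)), list(rep(10, n), rep(40, n)))
  expect_equal(estimationAccuracy(ref, ref), 1.0)
  # displace exactly 4 of 100 animal-frames beyond tolerance
  x <- coordsX(ref)
  x[c(3, 9), 1] <- x[c(3, 9), 1] + 10
  x[c(20, 30), 2] <- x[c(20, 30), 2] + 10
  rep_ts <- mkTS(list(x[, 1], x[, 2]), list(rep(10, n), rep(40, n)))
  expect_equal(estimationAccuracy(rep_ts, ref, tol = 5), 0.96)
  # degenerate inputs rejected
  allinv <- mkTS(list(rep(NA_real_, n), rep(NA_real_, n)),
                 list(rep(NA_real_, n), rep(NA_real_, n)))
  expect_error(estimationAccuracy(rep_ts, allinv), "no valid")
  small <- mkTS(list(1:3), list(rep(1, 3)))
  expect_error(estimationAccuracy(small, ref), "same shape")
})

test_that("repair leaves clean in-speed frames untouched and hits the floor", {
  cfg <- arenaConfig(sessionDuration = 600, nDays = 1, seed = 31)
  ts <- simulateGroup(zeroTraits(), cfg, famMap())[[1]]
  # dropout-only corruption leaves every surviving frame clean and in-speed;
  # repair must reproduce those frames bit-identically
  cr_d <- corruptTracks(ts, dropoutRate = 0.05, seed = 9)
  rp_d <- repairTracks(cr_d$tracks, reference = ts)
  keep <- validMask(cr_d$tracks)
  expect_identical(coordsX(rp_d$tracks)[keep], coordsX(cr_d$tracks)[keep])
  expect_identical(coordsY(rp_d$tracks)[keep], coordsY(cr_d$tracks)[keep])

  accs <- vapply(1:3, function(s) {
    cr <- corruptTracks(ts, dropoutRate = 0.05, swapRate = 0.02,
                        jumpRate = 0.002, seed = s)
    repairTracks(cr$tracks, reference = ts)$report@accuracy
  }, 0)
  expect_true(all(accs >= 0.96))
})
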