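test_that("proximity series follows the threshold and start-state rules", {
  n <- 500  # 100 s at 5 Hz
  # two agents fixed 5 cm apart plus two parked far away
  ts <- mkTS(list(rep(10, n), rep(15, n), rep(80, n), rep(80, n)),
             list(rep(10, n), rep(10, n), rep(10, n), rep(50, n)),
             ids = c("a", "b", "c", "d"))
  ps <- proximitySeries(ts, thresholdCm = 20, minBoutS = 2)
  pt <- proximityTime(ps)
  expect_equal(unname(pt["a-b"]), 100)
  ev <- detectEvents(ps, ts)
  expect_equal(nrow(ev[ev$dyad_a == "a" & ev$dyad_b == "b", ]), 0L)
  # fixed 50 cm apart: zero proximity
  ts2 <- mkTS(list(rep(10, n), rep(60, n)), list(rep(10, n), rep(10, n)),
              ids = c("a", "b"))
  expect_equal(unname(proximityTime(proximitySeries(ts2))["a-b"]), 0)
})

test_that("sub-bout dips are absorbed by the debounce", {
  n <- 200
  xb <- rep(15, n)
  xb[100] <- 40  # single-frame (0.2 s) separation dip
  ts <- mkTS(list(rep(10, n), xb), list(rep(10, n), rep(10, n)),
             ids = c("a", "b"))
  ps <- proximitySeries(ts, thresholdCm = 20, minBoutS = 2)
  expect_true(all(ps@series[, "a-b"]))
  expect_equal(nrow(detectEvents(ps, ts)), 0L)
  # without debouncing the dip splits the bout
  ps0 <- proximitySeries(ts, thresholdCm = 20, minBoutS = 0)
  expect_false(all(ps0@series[, "a-b"]))
})

test_that("events are attributed to the animal that moved", {
  n <- 100
  stationary <- rep(10, n)
  # focal walks in from 60 cm to contact, then stays
  walk_in <- c(seq(70, 12, length.out = 50), rep(12, 50))
  ts <- mkTS(list(stationary, walk_in), list(stationary, stationary),
             ids = c("a", "b"))
  ps <- proximitySeries(ts, minBoutS = 2)
  ev <- detectEvents(ps, ts, windowS = 3)
  expect_equal(ev$kind, "approach")
  expect_equal(ev$mover, "b")
  # partner departs: avoidance attributed to the departing animal
  walk_out <- c(rep(12, 50), seq(12, 70, length.out = 50))
  ts2 <- mkTS(list(stationary, walk_out), list(stationary, stationary),
              ids = c("a", "b"))
  ps2 <- proximitySeries(ts2, minBoutS = 2)
  ev2 <- detectEvents(ps2, ts2, windowS = 3)
  expect_equal(ev2$kind, "avoidance")
  expect_equal(ev2$mover, "b")
  # mirror-image symmetric approach: ambiguous mover, event kept
  xa <- c(seq(10, 34.9, length.out = 50), rep(34.9, 50))
  xb <- c(seq(60, 35.1, length.out = 50), rep(35.1, 50))
  ts3 <- mkTS(list(xa, xb), list(stationary, stationary), ids = c("a", "b"))
  ps3 <- proximitySeries(ts3, minBoutS = 2)
  ev3 <- detectEvents(ps3, ts3, windowS = 3)
  expect_equal(ev3$kind, "approach")
  expect_true(is.na(ev3$mover))
})

test_that("isolation time equals the brute-force frame count", {
  # never in proximity: isolation is the whole session
  s_never <- matrix(FALSE, 100, 3)
  ps <- mkPS(s_never, dyadA = c("a", "a", "a"), dyadB = c("b", "c", "d"))
  expect_equal(isolationTime(ps, "a"), 20)  # 100 frames at 5 Hz
  # always with at least one partner: zero isolation
  s_always <- cbind(rep(TRUE, 100), rep(FALSE, 100), rep(FALSE, 100))
  ps2 <- mkPS(s_always, c("a", "a", "a"), c("b", "c", "d"))
  expect_equal(isolationTime(ps2, "a"), 0)
  # random series equal the all-false conjunction, frame-enumerated
  set.seed(8)
  s_rand <- matrix(runif(300) < 0.3, 100, 3)
  ps3 <- mkPS(s_rand, c("a", "a", "a"), c("b", "c", "d"))
  brute <- 0L
  for (f in 1:100) if (!any(s_rand[f, ])) brute <- brute + 1L
  expect_equal(isolationTime(ps3, "a"), brute * 0.2)
})

test_that("per-subject indices satisfy the counting identities", {
  cfg <- arenaConfig(sessionDuration = 300, nDays = 1, seed = 77)
  ts <- simulateGroup(pairTraits(w = 0.6), cfg, famMap())[[1]]
  ps <- proximitySeries(ts)
  ev <- detectEvents(ps, ts)
  si <- socialIndices(ts, ps, ev)
  expect_setequal(si$subject, c("a", "b", "c", "d"))
  # totals identity, exact
  expect_equal(si$approaches_total,
               si$approaches_familiar + 2 * si$approaches_unfamiliar)
  expect_equal(si$avoidances_total,
               si$avoidances_familiar + 2 * si$avoidances_unfamiliar)
  # conservation against an independent transition count per dyad
  for (k in seq_along(ps@dyadA)) {
    z <- ps@series[, k]
    z <- z[!is.na(z)]
    onsets <- sum(z[-1] & !z[-length(z)])
    offsets <- sum(!z[-1] & z[-length(z)])
    dev <- ev[ev$dyad_a == ps@dyadA[k] & ev$dyad_b == ps@dyadB[k], ]
    expect_equal(sum(dev$kind == "approach"), onsets)
    expect_equal(sum(dev$kind == "avoidance"), offsets)
    expect_lte(abs(onsets - offsets), 1L)
  }
  # isolation cannot exceed the session
  expect_true(all(si$isolation_s <= 300 + 1e-9))
})

test_that("term aggregation averages usable days and honours exclusions", {
  mk_day <- function(day, val) {
    df <- data.frame(subject = c("a", "b"), day = day)
    for (col in socialIndexNames()) df[[col]] <- val
    df
  }
  rows <- rbind(mk_day(1, 2), mk_day(2, 4))
  agg <- aggregateTerm(rows)
  expect_equal(agg$isolation_s, c(3, 3))
  expect_equal(agg$n_days, c(2L, 2L))
  # identical days: mean equals any single day
  same <- rbind(mk_day(1, 5), mk_day(2, 5), mk_day(3, 5))
  expect_equal(aggregateTerm(same)$prox_familiar_s, c(5, 5))
  # excluded days are dropped before averaging
  agg2 <- aggregateTerm(rows, excludeDays = 2)
  expect_equal(agg2$isolation_s, c(2, 2))
  expect_equal(agg2$n_days, c(1L, 1L))
  expect_error(aggregateTerm(rows, excludeDays = 1:2), "no usable days")
  # random values equal an independent re-mean
  set.seed(3)
  r1 <- mk_day(1, 0); r2 <- mk_day(2, 0)
  for (col in socialIndexNames()) {
    r1[[col]] <- rnorm(2); r2[[col]] <- rnorm(2)
  }
  agg3 <- aggregateTerm(rbind(r1, r2))
  expect_equal(agg3$avoidances_total[1],
               mean(c(r1$avoidances_total[1], r2$avoidances_total[1])))
})

test_that("group standardization makes every group-index mean exactly one", {
  tm <- data.frame(subject = c("a", "b", "c", "d", "e", "f"), n_days = 7L)
  set.seed(5)
  for (col in socialIndexNames()) tm[[col]] <- abs(rnorm(6)) + 0.5
  tm[["isolation_s"]][1:4] <- 2  # constant within group: all become 1
  groups <- setNames(c(rep("g1", 4), rep("g2", 2)), tm$subject)
  std <- standardizeByGroup(tm, groups)
  expect_equal(std$isolation_s[1:4], rep(1, 4))
  for (col in socialIndexNames()) {
    expect_equal(mean(std[[col]][std$group == "g1"]), 1)
    expect_equal(mean(std[[col]][std$group == "g2"]), 1)
  }
  # worked examples
  tm2 <- tm; tm2$prox_familiar_s <- c(1, 3, 1, 3, 1, 3)
  std2 <- standardizeByGroup(tm2, groups)
  expect_equal(std2$prox_familiar_s[1:2], c(0.5, 1.5))
  # zero group mean flagged
  tm3 <- tm; tm3$approaches_total <- 0
  expect_warning(expect_warning(std3 <- standardizeByGroup(tm3, groups),
                                "not standardizable"))
  expect_true(all(is.na(std3$approaches_total)))
})
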