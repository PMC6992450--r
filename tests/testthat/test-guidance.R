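# Hand-walked scripted traces through the illumination-guidance automaton.

step_trace <- function(t_s, changes, start = 100) {
  v <- rep(start, length(t_s))
  for (ch in changes) v[t_s >= ch[1]] <- ch[2]
  v
}

test_that("a trace that never occludes stays FULL and is unconfirmed", {
  t_s <- 0:300
  v <- rep(100, length(t_s))
  pt <- occlusionGuidance(v, v, t_s)
  ev <- protocolEvents(pt)
  expect_identical(ev$state, "FULL")
  expect_false(occlusionConfirmed(pt))
})

test_that("a sustained step occlusion walks FULL -> HALF -> OFF on schedule", {
  # step 100% -> 15% at t = 60 s, held; persistence 5 s, hold 120 s
  t_s <- 0:400
  v <- step_trace(t_s, list(c(60, 15)))
  r <- step_trace(t_s, list(c(60, 40)))
  pt <- occlusionGuidance(v, r, t_s)
  ev <- protocolEvents(pt)
  expect_identical(ev$state, c("FULL", "HALF", "OFF"))
  expect_equal(ev$t_s, c(0, 65, 185))
  expect_identical(ev$power_mw, c(0.6, 0.3, 0))
  expect_true(occlusionConfirmed(pt))
})

test_that("recanalization re-arms the laser and a re-occlusion re-walks the cycle", {
  # 15% from t=60, back to 90% at t=400, 15% again at t=500
  t_s <- 0:700
  v <- step_trace(t_s, list(c(60, 15), c(400, 90), c(500, 15)))
  pt <- occlusionGuidance(v, v, t_s)
  ev <- protocolEvents(pt)
  expect_identical(ev$state, c("FULL", "HALF", "OFF", "FULL", "HALF", "OFF"))
  # hand walk: HALF at 65, OFF at 185; drop < 50 sustained from 400 -> FULL
  # at 405; occluded again from 500 sustained -> HALF at 505, OFF at 625
  expect_equal(ev$t_s, c(0, 65, 185, 405, 505, 625))
})

test_that("region criterion is required for confirmation", {
  t_s <- 0:300
  v <- step_trace(t_s, list(c(60, 15)))
  r_weak <- step_trace(t_s, list(c(60, 60)))  # only a 40-point region drop
  pt <- occlusionGuidance(v, r_weak, t_s)
  expect_false(occlusionConfirmed(pt))
  expect_identical(protocolEvents(pt)$state, c("FULL", "HALF", "OFF"))
})

test_that("the automaton is deterministic and HALF lasts the full hold", {
  t_s <- seq(0, 500, by = 0.5)
  v <- step_trace(t_s, list(c(33, 10)))
  p1 <- occlusionGuidance(v, v, t_s)
  p2 <- occlusionGuidance(v, v, t_s)
  expect_identical(protocolEvents(p1), protocolEvents(p2))
  ev <- protocolEvents(p1)
  half_len <- ev$t_s[ev$state == "OFF"] - ev$t_s[ev$state == "HALF"]
  expect_true(all(half_len >= 120))
})

test_that("optimized FULL time never exceeds the fixed 15-min protocol when occlusion comes early", {
  for (t_occl in c(60, 300, 800)) {
    t_s <- 0:900
    v <- step_trace(t_s, list(c(t_occl, 10)))
    opt <- occlusionGuidance(v, v, t_s)
    expect_lte(fullPowerTime(opt), 900)
  }
})

test_that("mismatched clocks are rejected", {
  expect_error(occlusionGuidance(1:5, 1:4, 1:5), "clock")
  expect_error(occlusionGuidance(1:5, 1:5, c(1, 1, 2, 3, 4)), "increasing")
})

test_that("the nonoptimized protocol is a single fixed FULL interval", {
  pt <- nonoptimizedProtocol()
  ev <- protocolEvents(pt)
  expect_identical(ev$state, c("FULL", "OFF"))
  expect_identical(ev$t_s, c(0, 900))
  expect_identical(fullPowerTime(pt), 900)
  expect_identical(protocolEvents(nonoptimizedProtocol()), ev)
  expect_warning(z <- nonoptimizedProtocol(0), "empty")
  expect_identical(protocolEvents(z)$state, "OFF")
})
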