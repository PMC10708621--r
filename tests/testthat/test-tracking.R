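mk_est <- function(xy, time, nbs = 5, var = 25) {
  structure(list(location = c(xy, 0), covariance = diag(var, 2),
                 nbs = nbs, time = time, std = sqrt(var),
                 ambiguous = FALSE),
            class = "toa_estimate")
}

test_that("Kalman prediction grows uncertainty as specified", {
  st <- track_state(position = c(100, 200), time = 0, model = "cp",
                    cov = diag(4, 2))
  expect_identical(kf_predict(st, 0), st)
  st5 <- kf_predict(st, 5)  # q = min(10 * 5, 750) = 50 m
  expect_equal(diag(st5$P), c(4, 4) + 2500)
  expect_equal(st5$x, c(100, 200))
  # the evolution std is capped at 750 m
  stc <- kf_predict(st, 1e5)
  expect_equal(diag(stc$P), c(4, 4) + 750^2)
})

test_that("constant-velocity prediction follows a straight line", {
  st <- track_state(position = c(0, 0), time = 0, model = "cv",
                    cov = diag(1, 2))
  st$x <- c(0, 0, 3, -2)  # 3 m/s east, 2 m/s south
  st$evolution_const <- 0  # no process noise
  for (k in 1:5) st <- kf_predict(st, 2)
  expect_equal(st$x[1:2], c(30, -20), tolerance = 1e-9)
})

test_that("Kalman update halves equal prior/measurement variance", {
  st <- track_state(position = c(0, 0), time = 0, cov = diag(100, 2))
  st2 <- kf_update(st, mk_est(c(10, 0), 1, var = 100))
  expect_equal(diag(st2$P), c(50, 50), tolerance = 1e-9)
  expect_equal(st2$x, c(5, 0), tolerance = 1e-9)
  # repeated identical measurements: variance strictly decreases
  v <- diag(st2$P)[1]
  for (k in 1:5) {
    st2 <- kf_update(st2, mk_est(c(10, 0), 1 + k, var = 100))
    expect_lt(diag(st2$P)[1], v)
    v <- diag(st2$P)[1]
  }
})

test_that("non-SPD measurement covariance is regularized", {
  st <- track_state(position = c(0, 0), time = 0)
  bad <- mk_est(c(1, 1), 1)
  bad$covariance <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_message(st2 <- kf_update(st, bad), "regularizing")
  expect_true(all(is.finite(st2$P)))
})

test_that("a stationary tag's filtered state converges to the truth", {
  set.seed(71)
  truth <- c(500, -300)
  st <- track_state(position = c(0, 0), time = 0)
  for (k in 1:100) {
    z <- truth + rnorm(2, 0, 5)
    st <- kf_predict(st, 1)
    st <- kf_update(st, mk_est(z, k, var = 25))
  }
  expect_lt(sqrt(sum((st$x[1:2] - truth)^2)), 3 * 5)
})

test_that("the consistency gate applies the speed and NBS rules", {
  st <- track_state(position = c(0, 0), time = 0)
  # nbs 3, dt 5, 300 m: violates both 20*dt and the 250 m cap
  expect_false(gate_consistent(st, mk_est(c(300, 0), 5, nbs = 3), 5))
  # nbs 5, dt 60, 900 m <= 1200 m and no cap applies
  expect_true(gate_consistent(st, mk_est(c(900, 0), 60, nbs = 5), 60))
  # nbs 4, 1200 m: the 1 km cap rejects regardless of dt
  expect_false(gate_consistent(st, mk_est(c(1200, 0), 600, nbs = 4), 600))
  # nbs 3, small displacement: fine
  expect_true(gate_consistent(st, mk_est(c(40, 0), 5, nbs = 3), 5))
})

test_that("gating protects the filter from gross outlier fixes", {
  set.seed(72)
  wins <- 0
  for (rep in 1:20) {
    truth <- c(0, 0)
    gated <- ungated <- track_state(position = truth, time = 0)
    for (k in 1:60) {
      bad <- runif(1) < 0.05
      z <- if (bad) truth + c(5000, 5000) else truth + rnorm(2, 0, 5)
      e <- mk_est(z, k, nbs = 5, var = 25)
      gated <- track_step(gated, e)$state
      ungated <- kf_update(kf_predict(ungated, 1), e)
    }
    # the gated filter must never end materially worse; when an outlier
    # lands late the ungated one ends kilometers off
    if (sqrt(sum((gated$x[1:2] - truth)^2)) <=
        sqrt(sum((ungated$x[1:2] - truth)^2)) + 10) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("ambiguity flag transitions follow the NBS rules", {
  st <- track_state(position = c(0, 0), time = 0)
  expect_true(st$ambiguous)  # fresh tag
  # a single fix with nbs >= 6 clears the flag
  st$last_accept_time <- 100
  st2 <- update_ambiguity_flag(st, mk_est(c(0, 0), 100, nbs = 6),
                               now = 100)
  expect_false(st2$ambiguous)
  # staleness (> 20 min) reverts to ambiguous
  st3 <- update_ambiguity_flag(st2, NULL, now = 100 + 21 * 60)
  expect_true(st3$ambiguous)
  # five nbs >= 4 fixes clear it and reset to the median-anchored fix
  st4 <- track_state(position = c(0, 0), time = 0)
  pts <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(50, 50))
  for (i in seq_along(pts))
    st4 <- kf_update(st4, mk_est(pts[[i]], i, nbs = 4))
  st4 <- update_ambiguity_flag(st4, mk_est(c(50, 50), 5, nbs = 4), now = 5)
  expect_false(st4$ambiguous)
  expect_equal(st4$x[1:2], c(1, 1))  # closest to the per-axis medians
})

test_that("flag stays unambiguous while fresh high-NBS fixes arrive", {
  st <- track_state(position = c(0, 0), time = 0)
  for (k in 1:8) {
    e <- mk_est(c(0, 0), k * 60, nbs = 6)
    st <- track_step(st, e)$state
    if (k > 1) expect_false(st$ambiguous)
  }
})

test_that("the ambiguous queue enforces its cap", {
  q <- ambiguous_queue(cap = 5)
  emitted <- list()
  for (k in 1:6) {
    item <- list(time = k, candidates = matrix(c(k, 0), 1),
                 estimate = mk_est(c(k, 0), k, nbs = 3))
    p <- push_ambiguous(q, item)
    q <- p$queue
    if (!is.null(p$emitted)) emitted <- c(emitted, list(p$emitted))
  }
  expect_length(q$items, 5)
  expect_length(emitted, 1)
  expect_true(emitted[[1]]$ambiguous)
  expect_equal(emitted[[1]]$time, 1)
})

test_that("revisiting an empty queue is a no-op", {
  q <- ambiguous_queue()
  st <- track_state(position = c(0, 0), time = 10)
  out <- revisit_ambiguous(q, st)
  expect_length(out$estimates, 0)
})

test_that("backward propagation resolves mirror pairs to the true branch", {
  set.seed(73)
  ok <- 0; total <- 0
  for (rep in 1:30) {
    # straight track along +x; mirrors reflected across y = 1000
    speed <- 8
    q <- ambiguous_queue()
    truth <- function(t) c(200 + speed * t, 400)
    for (k in 1:10) {
      xy <- truth(k)
      mirror <- c(xy[1], 1600 - xy[2])
      q <- push_ambiguous(q, list(time = k,
                                  candidates = rbind(mirror, xy),
                                  estimate = mk_est(mirror, k, nbs = 3)))$queue
    }
    final <- mk_est(truth(11) + rnorm(2, 0, 3), 11, nbs = 5)
    st <- track_state(position = final$location[1:2], time = 11)
    st <- kf_update(st, final)
    st$ambiguous <- FALSE
    out <- revisit_ambiguous(q, st)
    expect_length(out$estimates, 10)
    for (e in out$estimates) {
      total <- total + 1
      if (sqrt(sum((e$location[1:2] - truth(e$time))^2)) < 100)
        ok <- ok + 1
    }
    # emitted in original time order
    expect_equal(vapply(out$estimates, `[[`, 0, "time"), as.numeric(1:10))
  }
  expect_gte(ok / total, 0.95)
})

test_that("hint initialization replays recent high-NBS fixes", {
  set.seed(74)
  # no qualifying estimate within 12 h
  old <- lapply(1:5, function(k) mk_est(c(k, k), k * 3600, nbs = 5))
  expect_null(init_from_hints(old, start_time = 20 * 3600))
  # 15 qualifying: only the newest 10 are used
  hist <- lapply(1:15, function(k) mk_est(c(10 * k, 0), 1000 + k * 10,
                                          nbs = 4))
  st <- init_from_hints(hist, start_time = 1200)
  expect_s3_class(st, "toa_track_state")
  expect_length(st$recent_fixes, 5)  # ring buffer keeps the last 5
  # prior lands within gate distance of the most recent position
  expect_lt(abs(st$x[1] - 150), 60)
  # low-NBS estimates never qualify
  low <- lapply(1:5, function(k) mk_est(c(k, k), 1000 + k, nbs = 3))
  expect_null(init_from_hints(low, start_time = 1010))
})

test_that("track state serializes through JSON losslessly enough to resume", {
  set.seed(75)
  st <- track_state(position = c(12.5, -7.25), time = 99, model = "cv")
  st <- kf_update(st, mk_est(c(13, -7), 100, nbs = 5))
  j <- track_state_to_json(st)
  st2 <- track_state_from_json(j)
  expect_equal(st2$x, st$x)
  expect_equal(st2$P, st$P)
  expect_equal(st2$ambiguous, st$ambiguous)
  expect_equal(length(st2$recent_fixes), length(st$recent_fixes))
})
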