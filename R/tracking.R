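# Per-tag state-space prior: Kalman filter (constant-position or
# constant-velocity evolution), consistency gating, ambiguity flag
# transitions, backward resolution of queued ambiguous problems, and
# prior initialization from recent history ("hints").

#' Create a fresh track state
#'
#' The state starts ambiguous with a diffuse covariance.
#'
#' @param position length-2 initial position (x, y), meters.
#' @param time state epoch, seconds.
#' @param model `"cp"` (constant position) or `"cv"` (constant velocity).
#' @param cov initial position covariance (2x2), meters^2.
#' @param evolution_const,evolution_cap evolution noise
#'   `q(dt) = min(evolution_const * dt, evolution_cap)` meters.
#' @return an object of class `toa_track_state`.
#' @export
track_state <- function(position = c(0, 0), time = 0,
                        model = c("cp", "cv"), cov = diag(1e6, 2),
                        evolution_const = 10, evolution_cap = 750) {
  model <- match.arg(model)
  x <- if (model == "cv") c(position, 0, 0) else position
  P <- if (model == "cv") {
    P <- diag(c(0, 0, 100, 100)); P[1:2, 1:2] <- cov; P
  } else cov
  structure(list(model = model, x = x, P = P, last_time = time,
                 last_accept_time = -Inf, ambiguous = TRUE,
                 recent_fixes = list(),
                 evolution_const = evolution_const,
                 evolution_cap = evolution_cap),
            class = "toa_track_state")
}

#' @export
print.toa_track_state <- function(x, ...) {
  cat(sprintf("<toa_track_state> (%s) at (%.1f, %.1f) m, t = %.1f s%s\n",
              x$model, x$x[1], x$x[2], x$last_time,
              if (x$ambiguous) " [ambiguous]" else ""))
  invisible(x)
}

#' Position of a track state
#' @param state a `toa_track_state`.
#' @return length-2 numeric (x, y).
#' @export
track_position <- function(state) state$x[1:2]

# evolution noise std for a time gap
evolution_std <- function(state, dt) {
  min(state$evolution_const * dt, state$evolution_cap)
}

#' Kalman prediction step
#'
#' Constant-position model: position unchanged, each axis's variance grows
#' by `q(dt)^2` with `q(dt) = min(const * dt, cap)`. Constant-velocity
#' model: position advances by `v * dt` under the standard
#' white-acceleration process noise with acceleration standard deviation
#' `const` (the position noise is capped at `cap` as in the CP model).
#'
#' @param state a `toa_track_state`.
#' @param dt time step, seconds (>= 0).
#' @return the advanced state.
#' @export
kf_predict <- function(state, dt) {
  stopifnot(dt >= 0)
  if (dt == 0) return(state)
  if (state$model == "cp") {
    q <- evolution_std(state, dt)
    state$P <- state$P + diag(q^2, 2)
  } else {
    FF <- diag(4); FF[1, 3] <- dt; FF[2, 4] <- dt
    # standard white-acceleration process noise; the evolution constant
    # plays the role of the acceleration standard deviation here
    a <- state$evolution_const
    Q1 <- a^2 * matrix(c(dt^4 / 4, dt^3 / 2, dt^3 / 2, dt^2), 2)
    Q <- matrix(0, 4, 4)
    Q[c(1, 3), c(1, 3)] <- Q1
    Q[c(2, 4), c(2, 4)] <- Q1
    state$x <- drop(FF %*% state$x)
    state$P <- FF %*% state$P %*% t(FF) + Q
  }
  state$last_time <- state$last_time + dt
  state
}

#' Kalman measurement update with a location estimate
#'
#' Standard update using the estimate's 2D covariance as measurement
#' noise. A non-positive-definite measurement covariance is regularized by
#' adding `1e-6` to the diagonal (with a message). Gating is the caller's
#' responsibility (see [gate_consistent()], [track_step()]).
#'
#' @param state a `toa_track_state`.
#' @param estimate a `toa_estimate` (or a list with `location`,
#'   `covariance`, `nbs`, `time`).
#' @return the updated state (the fix is appended to `recent_fixes`).
#' @export
kf_update <- function(state, estimate) {
  R <- estimate$covariance[1:2, 1:2]
  if (inherits(try(chol(R), silent = TRUE), "try-error")) {
    message("regularizing non-SPD measurement covariance")
    R <- R + diag(1e-6, 2)
  }
  n <- length(state$x)
  H <- matrix(0, 2, n); H[1, 1] <- 1; H[2, 2] <- 1
  S <- H %*% state$P %*% t(H) + R
  K <- state$P %*% t(H) %*% solve(S)
  z <- estimate$location[1:2]
  state$x <- drop(state$x + K %*% (z - drop(H %*% state$x)))
  state$P <- (diag(n) - K %*% H) %*% state$P
  state$P <- (state$P + t(state$P)) / 2
  state$last_accept_time <- estimate$time
  state$recent_fixes <- c(state$recent_fixes,
                          list(list(location = estimate$location,
                                    nbs = estimate$nbs,
                                    time = estimate$time)))
  nkeep <- 5L
  if (length(state$recent_fixes) > nkeep)
    state$recent_fixes <-
      state$recent_fixes[seq.int(length(state$recent_fixes) - nkeep + 1L,
                                 length(state$recent_fixes))]
  state
}

#' Consistency gate for new localizations
#'
#' A localization is inconsistent (rejected) iff its distance from the
#' state position exceeds `20 * dt` meters, OR exceeds 250 m when it used
#' only three base stations, OR exceeds 1000 m when it used four.
#'
#' @param state a `toa_track_state` (already predicted to the estimate's
#'   time).
#' @param estimate a `toa_estimate`.
#' @param dt seconds since the last accepted localization.
#' @return `TRUE` if the estimate passes the gate.
#' @export
gate_consistent <- function(state, estimate, dt) {
  d <- sqrt(sum((track_position(state) - estimate$location[1:2])^2))
  !(d > 20 * dt ||
      (estimate$nbs == 3 && d > 250) ||
      (estimate$nbs == 4 && d > 1000))
}

#' Update the ambiguity flag of a track state
#'
#' The flag reverts to ambiguous when the last accepted localization is
#' older than 20 minutes. It becomes unambiguous when the new estimate
#' used six or more receivers, or when the last five accepted fixes all
#' used four or more -- in which case the state position is reset to the
#' fix (among those five) closest to their per-axis medians, for
#' robustness.
#'
#' @param state a `toa_track_state`.
#' @param estimate the latest accepted `toa_estimate` (or `NULL`).
#' @param now current time, seconds.
#' @return the state with the flag (and possibly position) updated.
#' @export
update_ambiguity_flag <- function(state, estimate = NULL, now) {
  if (now - state$last_accept_time > 20 * 60) state$ambiguous <- TRUE
  if (!is.null(estimate) && estimate$nbs >= 6) {
    state$ambiguous <- FALSE
    return(state)
  }
  rf <- state$recent_fixes
  if (length(rf) >= 5) {
    last5 <- rf[seq.int(length(rf) - 4L, length(rf))]
    if (all(vapply(last5, `[[`, 0, "nbs") >= 4)) {
      state$ambiguous <- FALSE
      xy <- t(vapply(last5, function(f) f$location[1:2], numeric(2)))
      med <- c(stats::median(xy[, 1]), stats::median(xy[, 2]))
      anchor <- which.min((xy[, 1] - med[1])^2 + (xy[, 2] - med[2])^2)
      state$x[1:2] <- xy[anchor, ]
    }
  }
  state
}

#' Advance a track state with one localization
#'
#' Convenience orchestration: predict to the estimate's time, gate,
#' update if consistent, and maintain the ambiguity flag.
#'
#' @param state a `toa_track_state`.
#' @param estimate a `toa_estimate`.
#' @return list with the new `state` and logical `accepted`.
#' @export
track_step <- function(state, estimate) {
  dt <- max(estimate$time - state$last_time, 0)
  state <- kf_predict(state, dt)
  state$last_time <- estimate$time
  accepted <- gate_consistent(state, estimate,
                              max(estimate$time - state$last_accept_time, 0))
  if (is.infinite(state$last_accept_time)) accepted <- TRUE  # first fix
  if (accepted) state <- kf_update(state, estimate)
  state <- update_ambiguity_flag(state, if (accepted) estimate else NULL,
                                 now = estimate$time)
  list(state = state, accepted = accepted)
}

#' Create an ambiguous-problem queue
#'
#' Per-tag FIFO of unresolved (mirror-ambiguous) localization problems.
#'
#' @param cap maximum number of stored problems.
#' @return an object of class `ambiguous_queue`.
#' @export
ambiguous_queue <- function(cap = 1000) {
  structure(list(items = list(), cap = cap), class = "ambiguous_queue")
}

#' Queue an ambiguous problem
#'
#' When the cap is reached the oldest problem is evicted and emitted
#' immediately, flagged ambiguous.
#'
#' @param queue an `ambiguous_queue`.
#' @param item a list with at least `time`, `candidates` (2 x 2 matrix of
#'   candidate x, y rows), and `estimate` (the provisional
#'   `toa_estimate`).
#' @return list with the new `queue` and `emitted` (the evicted estimate
#'   or `NULL`).
#' @export
push_ambiguous <- function(queue, item) {
  emitted <- NULL
  if (length(queue$items) >= queue$cap) {
    oldest <- queue$items[[1]]
    queue$items <- queue$items[-1]
    emitted <- oldest$estimate
    emitted$ambiguous <- TRUE
  }
  queue$items <- c(queue$items, list(item))
  list(queue = queue, emitted = emitted)
}

#' Resolve queued ambiguous problems backward in time
#'
#' Given a newly unambiguous state (newer than every queued problem), walk
#' the queue newest to oldest, predicting the state backward across each
#' time gap, selecting for each problem the candidate solution closest to
#' the propagated position, and updating the state with it. Resolved
#' estimates are returned in original time order and the queue is cleared.
#'
#' @param queue an `ambiguous_queue`.
#' @param state an unambiguous `toa_track_state`.
#' @return list with `estimates` (resolved, time-ordered), the emptied
#'   `queue`, and the final backward-propagated `state`.
#' @export
revisit_ambiguous <- function(queue, state) {
  if (!length(queue$items))
    return(list(estimates = list(), queue = queue, state = state))
  if (state$model == "cv") state$x[3:4] <- -state$x[3:4]  # run time backward
  items <- rev(queue$items)
  out <- vector("list", length(items))
  tprev <- state$last_time
  for (k in seq_along(items)) {
    it <- items[[k]]
    dt <- max(tprev - it$time, 0)
    state <- kf_predict(state, dt)  # covariance inflation over the gap
    state$last_time <- it$time
    tprev <- it$time
    xy <- track_position(state)
    d2 <- (it$candidates[, 1] - xy[1])^2 + (it$candidates[, 2] - xy[2])^2
    pick <- which.min(d2)
    est <- it$estimate
    est$location[1:2] <- it$candidates[pick, ]
    est$ambiguous <- FALSE
    est$resolved_backward <- TRUE
    state <- kf_update(state, est)
    out[[k]] <- est
  }
  queue$items <- list()
  list(estimates = rev(out), queue = queue, state = state)
}

#' Initialize a track prior from recent history
#'
#' Uses up to the ten most recent localizations with four or more base
#' stations from the 12 hours before `start_time`, replayed in time order
#' through the Kalman filter. Returns `NULL` when no localization
#' qualifies.
#'
#' @param history time-sorted list of `toa_estimate`s.
#' @param start_time batch start epoch, seconds.
#' @param model,evolution_const,evolution_cap see [track_state()].
#' @return a `toa_track_state` or `NULL`.
#' @export
init_from_hints <- function(history, start_time, model = "cp",
                            evolution_const = 10, evolution_cap = 750) {
  ok <- vapply(history, function(e)
    e$nbs >= 4 && e$time <= start_time && e$time > start_time - 12 * 3600,
    logical(1))
  h <- history[ok]
  if (!length(h)) return(NULL)
  if (length(h) > 10) h <- h[seq.int(length(h) - 9L, length(h))]
  st <- track_state(position = h[[1]]$location[1:2], time = h[[1]]$time,
                    model = model, cov = h[[1]]$covariance[1:2, 1:2],
                    evolution_const = evolution_const,
                    evolution_cap = evolution_cap)
  st <- kf_update(st, h[[1]])
  st <- update_ambiguity_flag(st, h[[1]], now = h[[1]]$time)
  for (e in h[-1]) {
    st <- kf_predict(st, max(e$time - st$last_time, 0))
    st$last_time <- e$time
    st <- kf_update(st, e)
    st <- update_ambiguity_flag(st, e, now = e$time)
  }
  # advance to the batch start so the prior reflects the elapsed gap
  st <- kf_predict(st, max(start_time - st$last_time, 0))
  st$last_time <- start_time
  st
}

#' Serialize a track state to JSON
#' @param state a `toa_track_state`.
#' @return a JSON string.
#' @export
track_state_to_json <- function(state) {
  jsonlite::toJSON(unclass(state), auto_unbox = TRUE, digits = NA,
                   force = TRUE)
}

#' Restore a track state from JSON
#' @param json a string produced by [track_state_to_json()].
#' @return a `toa_track_state`.
#' @export
track_state_from_json <- function(json) {
  o <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  st <- track_state(model = o$model)
  st$x <- as.numeric(unlist(o$x))
  st$P <- matrix(as.numeric(unlist(o$P)), nrow = length(st$x))
  st$last_time <- as.numeric(o$last_time)
  st$last_accept_time <- if (is.null(o$last_accept_time)) -Inf else
    as.numeric(o$last_accept_time)
  st$ambiguous <- isTRUE(o$ambiguous)
  st$evolution_const <- as.numeric(o$evolution_const)
  st$evolution_cap <- as.numeric(o$evolution_cap)
  st$recent_fixes <- lapply(o$recent_fixes, function(f)
    list(location = as.numeric(unlist(f$location)),
         nbs = as.numeric(f$nbs), time = as.numeric(f$time)))
  st
}
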