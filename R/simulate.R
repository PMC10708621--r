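# Synthetic-scenario generator emulating an ATLAS-like deployment:
# receiver networks with per-receiver clock offsets, beacons, tag
# trajectories, SNR-dependent ToA noise, NLOS delay outliers and
# distance-dependent dropout. Every draw flows from one root seed, so
# identical seeds give identical detection streams.

# run code under a local RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Scenario configuration for the simulator
#'
#' Defaults emulate a mid-sized terrestrial ToA deployment: a jittered
#' 3 x 3 receiver grid over 10 x 10 km, three beacons, nanosecond-scale
#' ToA noise derived from a log-distance SNR model, per-receiver clock
#' offsets uniform on +/-1 ms, and optional NLOS delay outliers that are
#' log-uniform on 1--10 microseconds and (deliberately) reported with an
#' unchanged sigma -- the overestimated-SNR failure mode the robust
#' pipeline must detect.
#'
#' @param n_receivers number of receivers (>= 3).
#' @param extent side of the square deployment area, meters.
#' @param elev_range receiver elevation range (uniform), meters.
#' @param n_beacons number of beacons.
#' @param trajectory `"stationary"`, `"cv"` (constant velocity) or
#'   `"waypoint"`.
#' @param speed speed of the moving tag, m/s (capped by `speed_cap`).
#' @param speed_cap maximum speed, m/s.
#' @param n_packets number of tag transmissions.
#' @param packet_interval transmission period, seconds.
#' @param tag_altitude true tag altitude, meters.
#' @param snr0 SNR at 1 m, dB; `snr_slope` dB lost per decade of
#'   distance; `snr_sd` SNR scatter, dB.
#' @param sigma0 ToA standard deviation at `snr_ref` dB, seconds.
#' @param snr_ref reference SNR of `sigma0`, dB.
#' @param offset_range receiver clock offset range (uniform), seconds.
#' @param nlos_prob probability a tag detection is NLOS-delayed.
#' @param nlos_range NLOS delay range (log-uniform), seconds.
#' @param detect_range50 distance of 50% detection probability, meters.
#' @param detect_scale logistic scale of the dropout curve, meters.
#' @param timestamp_jitter coarse-timestamp jitter half-width, seconds.
#' @param seed root RNG seed.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n_receivers = 9, extent = 10000,
                            elev_range = c(0, 30), n_beacons = 3,
                            trajectory = c("stationary", "cv", "waypoint"),
                            speed = 10, speed_cap = 20, n_packets = 50,
                            packet_interval = 1, tag_altitude = 0,
                            snr0 = 60, snr_slope = 10, snr_sd = 3,
                            sigma0 = 1e-8, snr_ref = 20,
                            offset_range = c(-1e-3, 1e-3),
                            nlos_prob = 0, nlos_range = c(1e-6, 1e-5),
                            detect_range50 = 15000, detect_scale = 2000,
                            timestamp_jitter = 5e-4, seed = 1) {
  stopifnot(n_receivers >= 3, nlos_prob >= 0, nlos_prob <= 1,
            all(c(sigma0, extent, packet_interval) > 0))
  structure(list(n_receivers = n_receivers, extent = extent,
                 elev_range = elev_range, n_beacons = n_beacons,
                 trajectory = match.arg(trajectory), speed = speed,
                 speed_cap = speed_cap, n_packets = n_packets,
                 packet_interval = packet_interval,
                 tag_altitude = tag_altitude,
                 snr0 = snr0, snr_slope = snr_slope, snr_sd = snr_sd,
                 sigma0 = sigma0, snr_ref = snr_ref,
                 offset_range = offset_range, nlos_prob = nlos_prob,
                 nlos_range = nlos_range,
                 detect_range50 = detect_range50,
                 detect_scale = detect_scale,
                 timestamp_jitter = timestamp_jitter, seed = seed),
            class = "scenario_config")
}

#' Generate a receiver network and beacons
#'
#' Receivers are placed on a seeded jittered grid over the extent (cell
#' centers plus uniform jitter of 20% of the cell), beacons at a subset of
#' receiver sites (2 m above the antenna) plus interior points.
#' Deterministic per seed.
#'
#' @param config a `scenario_config`.
#' @return list with `receivers` (receiver table) and `beacons`
#'   (data.frame id, x, y, z).
#' @export
make_network <- function(config) {
  n <- config$n_receivers
  side <- ceiling(sqrt(n))
  cell <- config$extent / side
  if (cell < 10) stop("extent too small for the receiver count")
  with_seed(config$seed, {
    centers <- expand.grid(i = seq_len(side), j = seq_len(side))
    centers <- centers[seq_len(n), ]
    x <- (centers$i - 0.5) * cell + stats::runif(n, -0.2, 0.2) * cell
    y <- (centers$j - 0.5) * cell + stats::runif(n, -0.2, 0.2) * cell
    z <- stats::runif(n, config$elev_range[1], config$elev_range[2])
    receivers <- receiver_table(sprintf("R%02d", seq_len(n)), x, y, z)
    nb <- config$n_beacons
    at_site <- seq_len(min(ceiling(nb / 2), n))
    bx <- receivers$x[at_site]; by <- receivers$y[at_site]
    bz <- receivers$z[at_site] + 2
    n_int <- nb - length(at_site)
    if (n_int > 0) {
      bx <- c(bx, stats::runif(n_int, 0.25, 0.75) * config$extent)
      by <- c(by, stats::runif(n_int, 0.25, 0.75) * config$extent)
      bz <- c(bz, stats::runif(n_int, 1, 5))
    }
    beacons <- data.frame(id = sprintf("B%02d", seq_len(nb)),
                          x = bx, y = by, z = bz,
                          stringsAsFactors = FALSE)
    list(receivers = receivers, beacons = beacons)
  })
}

#' Generate a tag trajectory
#'
#' @param config a `scenario_config`.
#' @return data.frame `time`, `x`, `y`, `z` -- the true tag position at
#'   each transmission.
#' @export
simulate_track <- function(config) {
  times <- (seq_len(config$n_packets) - 1) * config$packet_interval
  e <- config$extent
  with_seed(config$seed + 1, {
    sp <- min(config$speed, config$speed_cap)
    if (config$trajectory == "stationary") {
      p0 <- stats::runif(2, 0.25, 0.75) * e
      x <- rep(p0[1], length(times)); y <- rep(p0[2], length(times))
    } else if (config$trajectory == "cv") {
      p0 <- stats::runif(2, 0.3, 0.7) * e
      th <- stats::runif(1, 0, 2 * pi)
      x <- p0[1] + sp * cos(th) * times
      y <- p0[2] + sp * sin(th) * times
    } else {
      nw <- 4
      wp <- cbind(stats::runif(nw, 0.2, 0.8) * e,
                  stats::runif(nw, 0.2, 0.8) * e)
      seg <- sqrt(rowSums(diff(wp)^2))
      cum <- c(0, cumsum(seg))
      s <- pmin(sp * times, max(cum))
      k <- findInterval(s, cum, rightmost.closed = TRUE)
      f <- (s - cum[k]) / pmax(seg[k], 1e-9)
      x <- wp[k, 1] + f * (wp[k + 1, 1] - wp[k, 1])
      y <- wp[k, 2] + f * (wp[k + 1, 2] - wp[k, 2])
    }
    data.frame(time = times, x = x, y = y, z = config$tag_altitude)
  })
}

# SNR -> ToA sigma map: sigma = sigma0 * 10^(-(snr - snr_ref)/20)
snr_to_sigma <- function(snr, config) {
  config$sigma0 * 10^(-(snr - config$snr_ref) / 20)
}

#' Forward-simulate detection reports
#'
#' For each packet and receiver: arrival time
#' `t = tau + |rho_r - l|/c + o_r + eps`, `eps ~ N(0, sigma^2)` with sigma
#' from the SNR model; the detection is kept with a logistic
#' probability-of-detection in distance; NLOS events (tag detections only)
#' add a positive log-uniform delay while reporting an unchanged sigma.
#' Beacons transmit once per packet interval, staggered after the tag.
#'
#' @param track data.frame from [simulate_track()].
#' @param network list from [make_network()].
#' @param config a `scenario_config`.
#' @param noise_free if `TRUE`, zero ToA noise, full detection, no NLOS
#'   (clock offsets and timestamp jitter remain).
#' @return list with `detections` (detection table), `truth` (list with
#'   `packets`, per-detection `labels` including NLOS flags, and
#'   `offsets`), and the `network`.
#' @export
simulate_detections <- function(track, network, config,
                                noise_free = FALSE) {
  rec <- network$receivers
  bea <- network$beacons
  nr <- nrow(rec); nb <- nrow(bea); np <- nrow(track)
  with_seed(config$seed + 2, {
    offsets <- stats::runif(nr, config$offset_range[1],
                            config$offset_range[2])
    names(offsets) <- rec$id
    stagger <- config$packet_interval * seq_len(nb) / (nb + 2)
    rows <- vector("list", np * (nb + 1))
    labs <- vector("list", np * (nb + 1))
    k <- 0L
    for (p in seq_len(np)) {
      pk <- sprintf("P%05d", p)
      emitters <- data.frame(
        id = c("TAG", bea$id),
        packet = c(pk, paste0(pk, "-", bea$id)),
        tau = c(track$time[p], track$time[p] + stagger),
        x = c(track$x[p], bea$x), y = c(track$y[p], bea$y),
        z = c(track$z[p], bea$z), is_tag = c(TRUE, rep(FALSE, nb)),
        stringsAsFactors = FALSE)
      for (e in seq_len(nb + 1)) {
        dist <- sqrt((rec$x - emitters$x[e])^2 + (rec$y - emitters$y[e])^2 +
                       (rec$z - emitters$z[e])^2)
        pdet <- stats::plogis(-(dist - config$detect_range50) /
                                config$detect_scale)
        keep <- if (noise_free) rep(TRUE, nr) else
          stats::runif(nr) < pdet
        if (!any(keep)) next
        snr <- config$snr0 - config$snr_slope * log10(pmax(dist, 1)) +
          stats::rnorm(nr, 0, config$snr_sd)
        sigma <- snr_to_sigma(snr, config)
        eps <- if (noise_free) 0 else stats::rnorm(nr, 0, sigma)
        nlos <- !noise_free & emitters$is_tag[e] &
          stats::runif(nr) < config$nlos_prob
        delay <- ifelse(nlos,
                        exp(stats::runif(nr, log(config$nlos_range[1]),
                                         log(config$nlos_range[2]))), 0)
        true_arrival <- emitters$tau[e] + dist / SPEED_OF_LIGHT
        toa <- true_arrival + offsets + eps + delay
        ts <- true_arrival + stats::runif(nr, -config$timestamp_jitter,
                                          config$timestamp_jitter)
        k <- k + 1L
        rows[[k]] <- data.frame(
          packet_id = emitters$packet[e], emitter_id = emitters$id[e],
          receiver_id = rec$id, toa_s = toa, sigma_s = sigma,
          snr_db = snr, timestamp_s = ts,
          stringsAsFactors = FALSE)[keep, ]
        labs[[k]] <- data.frame(
          packet_id = emitters$packet[e], emitter_id = emitters$id[e],
          receiver_id = rec$id, outlier = nlos, true_toa = true_arrival +
            offsets, stringsAsFactors = FALSE)[keep, ]
      }
    }
    detections <- do.call(rbind, rows[seq_len(k)])
    rownames(detections) <- NULL
    labels <- do.call(rbind, labs[seq_len(k)])
    rownames(labels) <- NULL
    packets <- data.frame(packet_id = sprintf("P%05d", seq_len(np)),
                          tau = track$time, x = track$x, y = track$y,
                          z = track$z, stringsAsFactors = FALSE)
    list(detections = detections,
         truth = list(packets = packets, labels = labels,
                      offsets = offsets),
         network = network)
  })
}

#' Simulate a complete scenario
#'
#' Convenience wrapper: network + trajectory + detections.
#'
#' @inheritParams simulate_detections
#' @param config a `scenario_config`.
#' @return list of class `toa_scenario` with `config`, `network`,
#'   `track`, `detections`, `truth`.
#' @export
simulate_scenario <- function(config, noise_free = FALSE) {
  network <- make_network(config)
  track <- simulate_track(config)
  sim <- simulate_detections(track, network, config,
                             noise_free = noise_free)
  structure(list(config = config, network = network, track = track,
                 detections = sim$detections, truth = sim$truth),
            class = "toa_scenario")
}

#' Build localization problems from a scenario
#'
#' Groups the detection stream into detsets and pairs each tag detset with
#' the beacon detsets inside the admission window.
#'
#' @param scenario a `toa_scenario` (or list with `detections`,
#'   `network`).
#' @param config a `toa_config` (grouping tolerance, time window).
#' @return list of `toa_problem`s, time-ordered.
#' @export
scenario_problems <- function(scenario, config = toa_config()) {
  bea <- scenario$network$beacons
  kp <- stats::setNames(lapply(seq_len(nrow(bea)), function(i)
    c(bea$x[i], bea$y[i], bea$z[i])), bea$id)
  detsets <- group_detections(scenario$detections,
                              tolerance = config$grouping_tolerance,
                              known_positions = kp)
  is_beacon <- vapply(detsets, function(d) !is.null(d$known_position),
                      logical(1))
  tags <- detsets[!is_beacon]
  beacons <- detsets[is_beacon]
  btimes <- vapply(beacons, function(b)
    stats::median(b$detections$timestamp_s), 0)
  probs <- lapply(tags, function(tg) {
    t0 <- stats::median(tg$detections$timestamp_s)
    near <- beacons[abs(btimes - t0) <= config$time_window]
    toa_problem(tg, near, scenario$network$receivers,
                time_window = config$time_window)
  })
  probs[order(vapply(probs, `[[`, 0, "time"))]
}
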