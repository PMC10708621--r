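# Shared fixture builders: small forward-simulated localization problems
# with full ground truth, built in code (no stored data).

C_LIGHT <- toatrack::SPEED_OF_LIGHT

d3 <- function(p, q) sqrt(sum((p - q)^2))

# Forward-simulate one single/multi-beacon localization problem.
# All randomness comes from the caller's RNG state (call set.seed first).
# outliers: receiver ids whose TAG detection gets +outlier_delay seconds.
toy_problem <- function(n_receivers = 6, n_beacons = 1, sigma = 5e-9,
                        noise = TRUE, extent = 5000, tag = NULL,
                        rec_z = c(0, 30), outliers = character(),
                        outlier_delay = 5e-6, tag_z = 0) {
  rec <- toatrack::receiver_table(
    sprintf("R%02d", seq_len(n_receivers)),
    x = runif(n_receivers, 0, extent), y = runif(n_receivers, 0, extent),
    z = runif(n_receivers, rec_z[1], rec_z[2]))
  if (is.null(tag)) tag <- c(runif(2, 0.2, 0.8) * extent, tag_z)
  offs <- runif(n_receivers, -1e-3, 1e-3)
  sig <- function() if (noise) runif(n_receivers, 0.5, 2) * sigma else
    rep(sigma, n_receivers)
  mk <- function(emitter, packet, pos, tau, delays = 0) {
    s <- sig()
    dist <- sqrt((rec$x - pos[1])^2 + (rec$y - pos[2])^2 +
                   (rec$z - pos[3])^2)
    eps <- if (noise) rnorm(n_receivers, 0, s) else 0
    toatrack::detection_table(
      packet_id = packet, emitter_id = emitter, receiver_id = rec$id,
      toa_s = tau + dist / C_LIGHT + offs + eps + delays,
      sigma_s = s, snr_db = 40 - 10 * log10(pmax(dist, 1)),
      timestamp_s = tau + dist / C_LIGHT)
  }
  delays <- ifelse(rec$id %in% outliers, outlier_delay, 0)
  tag_det <- toatrack::detset(mk("TAG", "P1", tag, 0, delays))
  taub <- runif(n_beacons, -0.5, 0.5)
  beacons <- lapply(seq_len(n_beacons), function(b) {
    bpos <- c(runif(2, 0.2, 0.8) * extent, runif(1, 1, 5))
    toatrack::detset(mk(sprintf("B%02d", b), sprintf("P1-B%02d", b),
                        bpos, taub[b]),
                     known_position = bpos)
  })
  list(problem = toatrack::toa_problem(tag_det, beacons, rec),
       tag = tag, d_true = -taub, offsets = offs, receivers = rec,
       tag_detset = tag_det, beacon_detsets = beacons)
}

# independent dense-algebra oracle for the nuisance-eliminated objective:
# assemble the raw weighted system explicitly and minimize over the
# nuisance parameters with a QR solve
brute_force_f <- function(problem, selection, location, fixed_altitude = 0) {
  tg <- problem$tag_detset$detections
  rec <- problem$receivers
  l3 <- c(location[1], location[2], fixed_altitude)
  rows <- list()
  for (r in selection$tag_receivers) {
    i <- match(r, tg$receiver_id)
    k <- match(r, rec$id)
    pred <- d3(c(rec$x[k], rec$y[k], rec$z[k]), l3) / C_LIGHT
    rows[[length(rows) + 1]] <- list(y = tg$toa_s[i] - pred,
                                     sigma = tg$sigma_s[i],
                                     tau = "tag", rec = r)
  }
  bmap <- list()
  for (b in problem$beacon_detsets)
    bmap[[paste0(b$emitter_id, "@", b$packet_id)]] <- b
  bp <- selection$beacon_pairs
  for (k in seq_len(nrow(bp))) {
    b <- bmap[[bp$beacon_id[k]]]
    i <- match(bp$receiver_id[k], b$detections$receiver_id)
    j <- match(bp$receiver_id[k], rec$id)
    pred <- d3(c(rec$x[j], rec$y[j], rec$z[j]), b$known_position) / C_LIGHT
    rows[[length(rows) + 1]] <- list(y = b$detections$toa_s[i] - pred,
                                     sigma = b$detections$sigma_s[i],
                                     tau = bp$beacon_id[k],
                                     rec = bp$receiver_id[k])
  }
  taus <- unique(vapply(rows, `[[`, "", "tau"))
  recs <- sort(unique(vapply(rows, `[[`, "", "rec")))
  pars <- c(paste0("tau:", taus), paste0("off:", recs[-1]))
  n <- length(rows)
  N <- matrix(0, n, length(pars), dimnames = list(NULL, pars))
  y <- numeric(n); w <- numeric(n)
  for (i in seq_len(n)) {
    N[i, paste0("tau:", rows[[i]]$tau)] <- 1
    oc <- paste0("off:", rows[[i]]$rec)
    if (oc %in% pars) N[i, oc] <- 1
    y[i] <- rows[[i]]$y; w[i] <- 1 / rows[[i]]$sigma
  }
  A <- w * N
  theta <- qr.coef(qr(A), w * y)
  theta[is.na(theta)] <- 0
  sum((w * y - A %*% theta)^2)
}

# 2D localization error of an estimate against a true position
err2d <- function(est, truth) {
  sqrt((est$location[1] - truth[1])^2 + (est$location[2] - truth[2])^2)
}
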