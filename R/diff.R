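# Differenced tag-beacon constraints.
#
# Subtracting a beacon detection from a tag detection at the same receiver
# cancels the receiver's clock offset:
#   t_ir - t_br + |rho_r - l_b|/c = (tau_i - tau_b) + |rho_r - l_i|/c + noise
# leaving the tag position l_i and the transmission-time difference
# d = tau_i - tau_b as the only unknowns. Variances add under differencing.

#' Form difference constraints between a tag and a beacon detset
#'
#' One constraint per receiver that detected both packets. The differenced
#' time is `t_diff = t_ir - t_br` and its standard deviation is
#' `sqrt(sigma_ir^2 + sigma_br^2)`.
#'
#' @param tag_detset,beacon_detset `detset`s; the beacon one must carry
#'   `known_position`.
#' @param receivers receiver table.
#' @return a `data.frame` of class `diff_constraints` with one row per
#'   shared receiver (possibly zero rows): columns `receiver_id`, `t_diff`,
#'   `sigma`, receiver position `rx/ry/rz`, beacon position `bx/by/bz`,
#'   `beacon_id`, and the beacon detection SNR `beacon_snr`.
#' @export
make_diff_constraints <- function(tag_detset, beacon_detset, receivers) {
  if (is.null(beacon_detset$known_position))
    stop("beacon detset lacks known_position")
  tg <- tag_detset$detections
  bc <- beacon_detset$detections
  if (any(tg$sigma_s <= 0) || any(bc$sigma_s <= 0))
    stop("nonpositive sigma in detections")
  shared <- intersect(tg$receiver_id, bc$receiver_id)
  it <- match(shared, tg$receiver_id)
  ib <- match(shared, bc$receiver_id)
  rp <- if (length(shared)) receiver_positions(receivers, shared) else
    matrix(numeric(0), 0, 3)
  lb <- beacon_detset$known_position
  out <- data.frame(
    receiver_id = shared,
    t_diff = tg$toa_s[it] - bc$toa_s[ib],
    sigma = sqrt(tg$sigma_s[it]^2 + bc$sigma_s[ib]^2),
    rx = rp[, 1], ry = rp[, 2], rz = rp[, 3],
    bx = lb[1], by = lb[2], bz = lb[3],
    beacon_id = beacon_detset$emitter_id,
    beacon_snr = bc$snr_db[ib],
    stringsAsFactors = FALSE)
  class(out) <- c("diff_constraints", "data.frame")
  out
}

#' Weighted residuals of difference constraints at a hypothesis
#'
#' Residual per constraint:
#' `(t_diff + |rho_r - l_b|/c - d - |rho_r - l|/c) / sigma`
#' (dimensionless). Distances are always evaluated in 3D.
#'
#' @param constraints `diff_constraints` rows.
#' @param location numeric length-3 hypothesis position, meters.
#' @param d transmission-time-difference hypothesis, seconds.
#' @return numeric vector of weighted residuals.
#' @export
diff_residuals <- function(constraints, location, d) {
  if (!nrow(constraints)) stop("no constraints")
  unweighted_diff_residuals(constraints, location, d) / constraints$sigma
}

# residuals in seconds (unweighted)
unweighted_diff_residuals <- function(constraints, location, d) {
  rp <- cbind(constraints$rx, constraints$ry, constraints$rz)
  bp <- cbind(constraints$bx, constraints$by, constraints$bz)
  db <- sqrt(rowSums((rp - bp)^2))
  dl <- sqrt((rp[, 1] - location[1])^2 + (rp[, 2] - location[2])^2 +
               (rp[, 3] - location[3])^2)
  constraints$t_diff + db / SPEED_OF_LIGHT - d - dl / SPEED_OF_LIGHT
}

#' Robust transmission-time-difference estimate at a location hypothesis
#'
#' Median over receivers of `t_diff + |rho_r - l_b|/c - |rho_r - l|/c`;
#' for an even count the mean of the two middle values.
#'
#' @inheritParams diff_residuals
#' @return scalar `d` estimate, seconds.
#' @export
median_time_diff <- function(constraints, location) {
  if (!nrow(constraints)) stop("no constraints")
  stats::median(unweighted_diff_residuals(constraints, location, 0))
}
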