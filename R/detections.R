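# Domain containers: receiver tables, detections, detsets, grouping.

#' Build a validated receiver table
#'
#' Receivers live in a local planar metric frame (ENU: x east, y north,
#' z up, meters). Ids must be unique and coordinates finite.
#'
#' @param id character vector of receiver ids.
#' @param x,y,z numeric coordinates in meters.
#' @return a `data.frame` with columns `id`, `x`, `y`, `z`.
#' @export
receiver_table <- function(id, x, y, z = 0) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("receiver ids must be unique")
  x <- as.numeric(x); y <- as.numeric(y)
  z <- rep_len(as.numeric(z), length(id))
  if (!all(is.finite(c(x, y, z)))) stop("receiver coordinates must be finite")
  data.frame(id = id, x = x, y = y, z = z, stringsAsFactors = FALSE)
}

#' Build a detection table
#'
#' One row per detection report: one receiver's arrival-time measurement of
#' one packet. `toa_s` is the estimated arrival time at the digital part of
#' the receiver (includes the receiver's unknown clock offset); `sigma_s` is
#' the receiver's estimate of the ToA error standard deviation, derived from
#' the SNR. `timestamp_s` is a coarse absolute timestamp (about 1 ms
#' accuracy) used only for grouping detections into detsets.
#'
#' @param packet_id,emitter_id,receiver_id character identifiers.
#' @param toa_s arrival time, seconds.
#' @param sigma_s ToA standard deviation, seconds (> 0).
#' @param snr_db signal-to-noise ratio, dB (optional, `NA` allowed).
#' @param timestamp_s coarse timestamp for grouping, seconds.
#' @return a `data.frame` with the canonical detection columns.
#' @export
detection_table <- function(packet_id, emitter_id, receiver_id, toa_s,
                            sigma_s, snr_db = NA_real_,
                            timestamp_s = toa_s) {
  n <- length(as.character(packet_id))
  d <- data.frame(packet_id = as.character(packet_id),
                  emitter_id = rep_len(as.character(emitter_id), n),
                  receiver_id = as.character(receiver_id),
                  toa_s = as.numeric(toa_s),
                  sigma_s = rep_len(as.numeric(sigma_s), n),
                  snr_db = rep_len(as.numeric(snr_db), n),
                  timestamp_s = rep_len(as.numeric(timestamp_s), n),
                  stringsAsFactors = FALSE)
  validate_detections(d)
  d
}

validate_detections <- function(d) {
  need <- c("packet_id", "emitter_id", "receiver_id", "toa_s", "sigma_s")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("detection table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(d$toa_s))) stop("non-finite toa_s in detections")
  if (!all(is.finite(d$sigma_s)) || any(d$sigma_s <= 0))
    stop("sigma_s must be finite and > 0")
  invisible(d)
}

#' Construct a detset
#'
#' A detset is the set of detections of one transmitted packet, keyed by
#' receiver (at most one detection per receiver). Beacon detsets carry the
#' transmitter's known position.
#'
#' @param detections a detection data.frame, all rows sharing
#'   `emitter_id` (and nominally `packet_id`).
#' @param known_position optional numeric length-3 position (set for
#'   beacons).
#' @return an object of class `detset`.
#' @export
detset <- function(detections, known_position = NULL) {
  validate_detections(detections)
  if (length(unique(detections$emitter_id)) != 1)
    stop("a detset holds detections of a single emitter")
  if (anyDuplicated(detections$receiver_id))
    stop("at most one detection per receiver in a detset")
  if (!is.null(known_position)) {
    known_position <- as.numeric(known_position)
    stopifnot(length(known_position) == 3, all(is.finite(known_position)))
  }
  structure(list(emitter_id = detections$emitter_id[[1]],
                 packet_id = detections$packet_id[[1]],
                 detections = detections,
                 known_position = known_position),
            class = "detset")
}

#' @export
print.detset <- function(x, ...) {
  cat(sprintf("<detset> emitter %s packet %s: %d detections%s\n",
              x$emitter_id, x$packet_id, nrow(x$detections),
              if (is.null(x$known_position)) "" else " (beacon)"))
  invisible(x)
}

#' Group a detection stream into detsets
#'
#' Detections of the same emitter whose coarse timestamps fall within
#' `tolerance` of the first detection of the group form one detset (sort by
#' timestamp, greedy window). Duplicate (emitter, receiver) pairs inside a
#' window keep the higher-SNR detection with a warning.
#'
#' @param stream detection data.frame with a `timestamp_s` column.
#' @param tolerance grouping window, seconds (default 1 ms).
#' @param known_positions optional named list mapping beacon emitter ids to
#'   length-3 positions; matching detsets get `known_position` set.
#' @return list of `detset` objects, ordered by emitter then time.
#' @export
group_detections <- function(stream, tolerance = 1e-3,
                             known_positions = NULL) {
  validate_detections(stream)
  if (is.null(stream$timestamp_s)) stop("grouping requires timestamp_s")
  out <- list()
  for (em in sort(unique(stream$emitter_id))) {
    d <- stream[stream$emitter_id == em, , drop = FALSE]
    d <- d[order(d$timestamp_s), , drop = FALSE]
    start <- 1
    n <- nrow(d)
    bounds <- list()
    for (i in seq_len(n)) {
      if (d$timestamp_s[i] - d$timestamp_s[start] > tolerance) {
        bounds[[length(bounds) + 1L]] <- start:(i - 1L)
        start <- i
      }
    }
    bounds[[length(bounds) + 1L]] <- start:n
    kp <- if (!is.null(known_positions)) known_positions[[em]] else NULL
    for (idx in bounds) {
      g <- d[idx, , drop = FALSE]
      if (anyDuplicated(g$receiver_id)) {
        warning(sprintf("duplicate receiver in detset of %s; keeping higher SNR",
                        em))
        snr <- ifelse(is.na(g$snr_db), -Inf, g$snr_db)
        keep <- unlist(lapply(split(seq_len(nrow(g)), g$receiver_id),
                              function(ii) ii[which.max(snr[ii])]))
        g <- g[sort(keep), , drop = FALSE]
      }
      out[[length(out) + 1L]] <- detset(g, known_position = kp)
    }
  }
  out
}

#' Bundle a localization problem
#'
#' @param tag_detset `detset` of the mobile tag.
#' @param beacon_detsets list of `detset`s with known positions, from
#'   within `time_window` seconds of the tag detset.
#' @param receivers receiver table (see [receiver_table()]).
#' @param prior optional `toa_track_state` prior.
#' @param time_window admission window for beacon detsets, seconds.
#' @return an object of class `toa_problem`.
#' @export
toa_problem <- function(tag_detset, beacon_detsets, receivers,
                        prior = NULL, time_window = 2) {
  stopifnot(inherits(tag_detset, "detset"))
  t0 <- stats::median(tag_detset$detections$timestamp_s)
  keep <- vapply(beacon_detsets, function(b) {
    if (is.null(b$known_position))
      stop("every beacon detset must carry known_position")
    abs(stats::median(b$detections$timestamp_s) - t0) <= time_window
  }, logical(1))
  structure(list(tag_detset = tag_detset,
                 beacon_detsets = beacon_detsets[keep],
                 receivers = receivers,
                 prior = prior,
                 time = t0),
            class = "toa_problem")
}

#' @export
print.toa_problem <- function(x, ...) {
  cat(sprintf("<toa_problem> tag %s: %d receivers, %d beacon detsets\n",
              x$tag_detset$emitter_id, nrow(x$tag_detset$detections),
              length(x$beacon_detsets)))
  invisible(x)
}

# identity of one beacon transmission (a beacon can have several detsets
# inside a problem's admission window; each carries its own tau_b)
beacon_key <- function(b) paste0(b$emitter_id, "@", b$packet_id)

# receiver position lookup, rows aligned to ids
receiver_positions <- function(receivers, ids) {
  m <- match(ids, receivers$id)
  if (anyNA(m)) stop("unknown receiver id(s): ",
                     paste(ids[is.na(m)], collapse = ", "))
  cbind(x = receivers$x[m], y = receivers$y[m], z = receivers$z[m])
}

dist3 <- function(p, q) {
  # p: n x 3 matrix or length-3; q: length-3
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  sqrt((p[, 1] - q[1])^2 + (p[, 2] - q[2])^2 + (p[, 3] - q[3])^2)
}
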