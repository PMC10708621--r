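# RANSAC-style robust stages: outlier classification against a hypothesis,
# hypothesis generation from beacon triplets via the closed-form solver,
# selection by consensus or by density clustering, single-beacon
# refinement, and assembly of the ultimate constraint set.

#' Classify difference constraints as inliers or outliers
#'
#' A constraint is an outlier iff its weighted residual exceeds `delta`
#' standard deviations AND its unweighted residual exceeds
#' `meters_threshold` meters (both strict; `rule = "weighted"` uses the
#' delta test alone). If `d` is missing it is first estimated robustly via
#' [median_time_diff()].
#'
#' @param constraints `diff_constraints` rows (a single beacon's).
#' @param location length-3 hypothesis position, meters.
#' @param d transmission-time-difference hypothesis, seconds, or `NULL`.
#' @param delta weighted-residual threshold, standard deviations.
#' @param meters_threshold unweighted-residual threshold, meters.
#' @param rule `"both"` (AND of the two tests) or `"weighted"`.
#' @return list with logical `inlier`, the weighted residuals `wres`, the
#'   `d` used, and the inlier/outlier row subsets.
#' @export
classify_outliers <- function(constraints, location, d = NULL, delta = 3,
                              meters_threshold = 100, rule = c("both",
                                                               "weighted")) {
  rule <- match.arg(rule)
  if (is.null(d)) d <- median_time_diff(constraints, location)
  ures <- unweighted_diff_residuals(constraints, location, d)
  wres <- ures / constraints$sigma
  out <- abs(wres) > delta
  if (rule == "both")
    out <- out & (abs(ures) * SPEED_OF_LIGHT > meters_threshold)
  list(inlier = !out, wres = wres, d = d,
       inliers = constraints[!out, , drop = FALSE],
       outliers = constraints[out, , drop = FALSE])
}

#' Rank beacon detsets for hypothesis generation
#'
#' Lexicographic order: (1) size of the receiver intersection with the tag
#' detset, descending; (2) whether the approximate transmission-time
#' difference (tag toa minus beacon toa at a shared receiver) is below 2 s
#' in magnitude, true first; (3) mean SNR of the beacon detections in the
#' intersection, descending. Remaining ties break by beacon id (stable).
#'
#' @param tag_detset the tag `detset`.
#' @param beacon_detsets list of beacon `detset`s.
#' @param max_tau_diff threshold on the approximate |tau_i - tau_b|, s.
#' @return the beacon detsets, reordered.
#' @export
rank_beacon_detsets <- function(tag_detset, beacon_detsets,
                                max_tau_diff = 2) {
  if (!length(beacon_detsets)) return(beacon_detsets)
  tg <- tag_detset$detections
  keys <- lapply(beacon_detsets, function(b) {
    shared <- intersect(tg$receiver_id, b$detections$receiver_id)
    if (length(shared)) {
      r <- shared[1]
      tdiff <- tg$toa_s[match(r, tg$receiver_id)] -
        b$detections$toa_s[match(r, b$detections$receiver_id)]
      snr <- mean(b$detections$snr_db[match(shared,
                                            b$detections$receiver_id)],
                  na.rm = TRUE)
      if (is.nan(snr)) snr <- -Inf
    } else {
      tdiff <- Inf; snr <- -Inf
    }
    list(n = length(shared), near = abs(tdiff) < max_tau_diff, snr = snr,
         id = b$emitter_id)
  })
  ord <- order(-vapply(keys, `[[`, 0, "n"),
               !vapply(keys, `[[`, TRUE, "near"),
               -vapply(keys, `[[`, 0, "snr"),
               vapply(keys, `[[`, "", "id"))
  beacon_detsets[ord]
}

# triplet enumeration ordered by descending-sorted sigma vectors
# (ascending lexicographically), i.e. best (smallest worst-sigma) first
order_triplets <- function(sigma, max_constraints = 12) {
  n <- length(sigma)
  idx <- order(sigma)[seq_len(min(n, max_constraints))]
  tri <- utils::combn(idx, 3, simplify = FALSE)
  key <- t(vapply(tri, function(t) sort(sigma[t], decreasing = TRUE),
                  numeric(3)))
  tri[order(key[, 1], key[, 2], key[, 3])]
}

#' Generate closed-form location hypotheses
#'
#' For each of the `max_beacons` best-ranked beacons that share at least 3
#' receivers with the tag detset, enumerate receiver triplets (preferring
#' triplets with small constraint standard deviations), solve each with the
#' 2D closed-form solver at the assumed altitude, and emit 0--2 hypotheses
#' per triplet. Degenerate (e.g. collinear) triplets are skipped.
#'
#' @param tag_detset tag `detset`.
#' @param beacon_detsets beacon detsets, already ranked
#'   (see [rank_beacon_detsets()]).
#' @param receivers receiver table.
#' @param fixed_altitude assumed altitude for the 2D solve, meters.
#' @param max_beacons number of top-ranked beacons admitted.
#' @param max_triplets_per_beacon triplets solved per beacon.
#' @param max_constraints cap on constraints entering triplet enumeration
#'   (the smallest-sigma ones are kept).
#' @return list of hypotheses, each a list `location` (length-3), `d`
#'   (seconds), `beacon_id`, `triplet` (receiver ids), `kind =
#'   "closed_form"`; the list carries the per-beacon constraints in
#'   attribute `constraints_by_beacon`.
#' @export
generate_hypotheses <- function(tag_detset, beacon_detsets, receivers,
                                fixed_altitude = 0, max_beacons = 5,
                                max_triplets_per_beacon = 20,
                                max_constraints = 12) {
  hyps <- list()
  cons <- list()
  admitted <- 0L
  for (b in beacon_detsets) {
    if (admitted >= max_beacons) break
    dc <- make_diff_constraints(tag_detset, b, receivers)
    if (nrow(dc) < 3) {
      message("skipping beacon ", b$emitter_id, ": fewer than 3 shared receivers")
      next
    }
    admitted <- admitted + 1L
    key <- beacon_key(b)
    cons[[key]] <- dc
    tri <- order_triplets(dc$sigma, max_constraints)
    tri <- tri[seq_len(min(length(tri), max_triplets_per_beacon))]
    for (t3 in tri) {
      sub <- dc[t3, , drop = FALSE]
      pos <- cbind(sub$rx, sub$ry, sub$rz)
      bpos <- c(sub$bx[1], sub$by[1], sub$bz[1])
      ti <- SPEED_OF_LIGHT * sub$t_diff + dist3(pos, bpos)
      sols <- try(solve_exact(pos, ti, known_z = fixed_altitude),
                  silent = TRUE)
      if (inherits(sols, "try-error")) next  # degenerate triplet
      for (s in sols) {
        hyps[[length(hyps) + 1L]] <- list(
          location = s$location, d = s$t / SPEED_OF_LIGHT,
          beacon_id = key, triplet = sub$receiver_id,
          kind = "closed_form")
      }
    }
  }
  attr(hyps, "constraints_by_beacon") <- cons
  hyps
}

# minimal DBSCAN on an n x 2 coordinate matrix (no suitable implementation
# ships with the pre-installed stack). Returns integer labels, 0 = noise.
dbscan_xy <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  labels <- integer(n)  # 0 = unassigned/noise
  visited <- logical(n)
  cl <- 0L
  neighbors <- function(i) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    which(d2 <= eps^2)
  }
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbors(i)
    if (length(nb) < min_pts) next  # noise (may become border later)
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- setdiff(nb, i)
    while (length(seeds)) {
      j <- seeds[1]; seeds <- seeds[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nb2 <- neighbors(j)
        if (length(nb2) >= min_pts) seeds <- union(seeds, nb2)
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

#' Select a hypothesis by density clustering
#'
#' Runs DBSCAN on the (x, y) hypothesis locations only, takes the largest
#' cluster (ties: smaller summed distance to its own center), computes the
#' center as the per-axis medians, and returns the member hypothesis
#' closest to the center -- an actual solution, so its `d` is retained.
#'
#' @param hypotheses list from [generate_hypotheses()].
#' @param eps DBSCAN radius, meters.
#' @param min_pts DBSCAN density threshold.
#' @param constraints_by_beacon optional named list of `diff_constraints`
#'   used for the all-noise fallback (best consensus score).
#' @param delta,meters_threshold outlier thresholds for the fallback.
#' @return the selected hypothesis.
#' @export
select_clustering <- function(hypotheses, eps = 50, min_pts = 3,
                              constraints_by_beacon = NULL, delta = 3,
                              meters_threshold = 100) {
  if (!length(hypotheses)) stop("no hypotheses")
  xy <- t(vapply(hypotheses, function(h) h$location[1:2], numeric(2)))
  labels <- dbscan_xy(xy, eps, min_pts)
  if (all(labels == 0L)) {
    warning("all hypotheses classified as noise; falling back to consensus score")
    if (!is.null(constraints_by_beacon)) {
      res <- select_consensus(hypotheses, constraints_by_beacon,
                              delta = delta,
                              meters_threshold = meters_threshold)
      return(res$hypothesis)
    }
    return(hypotheses[[1]])
  }
  sizes <- tabulate(labels)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {  # tie: smaller summed distance to own center
    spread <- vapply(best, function(cl) {
      m <- xy[labels == cl, , drop = FALSE]
      ctr <- c(stats::median(m[, 1]), stats::median(m[, 2]))
      sum(sqrt((m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2))
    }, 0)
    best <- best[which.min(spread)]
  }
  mem <- which(labels == best[1])
  ctr <- c(stats::median(xy[mem, 1]), stats::median(xy[mem, 2]))
  d2 <- (xy[mem, 1] - ctr[1])^2 + (xy[mem, 2] - ctr[2])^2
  hypotheses[[mem[which.min(d2)]]]
}

#' Select a hypothesis by consensus
#'
#' Each hypothesis is scored against its own beacon's difference
#' constraints via [classify_outliers()]. Ranking is lexicographic:
#' (1) consensus-set size, descending; (2) if a `prior` is given, among
#' candidates whose maximum weighted residuals differ by at most 1, the
#' smaller distance to the prior location; (3) the smaller maximum weighted
#' residual. Remaining ties break by enumeration order.
#'
#' @inheritParams select_clustering
#' @param constraints_by_beacon named list of `diff_constraints` per
#'   beacon id.
#' @param prior optional `toa_track_state` (its position is used).
#' @return a consensus result: list with `hypothesis`, `inliers`,
#'   `max_weighted_residual`, `prior_distance`, `consensus_size`.
#' @export
select_consensus <- function(hypotheses, constraints_by_beacon,
                             prior = NULL, delta = 3,
                             meters_threshold = 100) {
  if (!length(hypotheses)) stop("no hypotheses")
  scored <- lapply(hypotheses, function(h) {
    dc <- constraints_by_beacon[[h$beacon_id]]
    cl <- classify_outliers(dc, h$location, h$d, delta, meters_threshold)
    mwr <- if (any(cl$inlier)) max(abs(cl$wres[cl$inlier])) else Inf
    pd <- if (!is.null(prior))
      sqrt(sum((track_position(prior) - h$location[1:2])^2)) else NA_real_
    list(hypothesis = h, inliers = cl$inliers, consensus_size = sum(cl$inlier),
         max_weighted_residual = mwr, prior_distance = pd)
  })
  sizes <- vapply(scored, `[[`, 0, "consensus_size")
  if (max(sizes) == 0) stop("no consistent hypothesis")
  top <- which(sizes == max(sizes))
  mwr <- vapply(scored[top], `[[`, 0, "max_weighted_residual")
  if (!is.null(prior)) {
    near <- top[mwr <= min(mwr) + 1]
    pd <- vapply(scored[near], `[[`, 0, "prior_distance")
    pick <- near[which.min(pd)]
  } else {
    pick <- top[which.min(mwr)]
  }
  structure(scored[[pick]], class = "consensus_result")
}

#' Refine a hypothesis over its whole consensus set
#'
#' If the consensus set holds more than three constraints, solve them in
#' the weighted least-squares sense over (x, y, d) by Levenberg--Marquardt
#' started at the hypothesis; otherwise return the hypothesis unchanged.
#'
#' @param result a `consensus_result` from [select_consensus()] (or built
#'   equivalently for the clustering variant).
#' @param fixed_altitude altitude of the 2D solve, meters.
#' @param step_tol Levenberg-Marquardt stopping step, meters.
#' @return a hypothesis; `kind = "refined"` when refinement ran, carrying
#'   the consensus set in `$consensus`.
#' @export
refine_single_beacon <- function(result, fixed_altitude = 0,
                                 step_tol = 1e-4) {
  h <- result$hypothesis
  dc <- result$inliers
  if (nrow(dc) <= 3) return(h)
  fa <- fixed_altitude
  # parameterize the time difference in meters (c * d) so the three
  # unknowns share a scale and the damped normal equations stay
  # well-conditioned
  resid <- function(p) diff_residuals(dc, c(p[1], p[2], fa),
                                      p[3] / SPEED_OF_LIGHT)
  jac <- function(p) {
    rp <- cbind(dc$rx, dc$ry, dc$rz)
    l3 <- c(p[1], p[2], fa)
    dl <- dist3(rp, l3); dl[dl == 0] <- .Machine$double.eps
    cbind(-(l3[1] - rp[, 1]) / (SPEED_OF_LIGHT * dl * dc$sigma),
          -(l3[2] - rp[, 2]) / (SPEED_OF_LIGHT * dl * dc$sigma),
          -1 / (SPEED_OF_LIGHT * dc$sigma))
  }
  fit <- lm_core(resid, jac, c(h$location[1:2], h$d * SPEED_OF_LIGHT),
                 step_tol = step_tol)
  if (fit$status != "converged") {
    warning("single-beacon refinement did not converge; keeping hypothesis")
    h$refine_failed <- TRUE
    return(h)
  }
  list(location = c(fit$par[1], fit$par[2], fa),
       d = fit$par[3] / SPEED_OF_LIGHT,
       beacon_id = h$beacon_id, triplet = h$triplet, kind = "refined",
       consensus = dc)
}

#' Assemble the ultimate constraint selection
#'
#' Classifies difference constraints against the refined hypothesis and
#' returns the union of the raw (tag, receiver) and (beacon, receiver)
#' constraints constituting the inliers: the best hypothesis's beacon only
#' (`mode = "single"`) or every admitted beacon with a per-beacon median
#' `d` (`mode = "multi"`). Each raw constraint enters at most once.
#'
#' @param problem a `toa_problem`.
#' @param best the selected (refined) hypothesis.
#' @param constraints_by_beacon named list of per-beacon
#'   `diff_constraints`.
#' @param mode `"single"` or `"multi"`.
#' @param delta,meters_threshold outlier thresholds.
#' @return a `toa_selection`; attribute `n_outliers` counts discarded
#'   difference constraints.
#' @export
assemble_ultimate <- function(problem, best, constraints_by_beacon,
                              mode = c("single", "multi"), delta = 3,
                              meters_threshold = 100) {
  mode <- match.arg(mode)
  ids <- if (mode == "single") best$beacon_id else
    names(constraints_by_beacon)
  tag_receivers <- character()
  pairs <- list()
  n_out <- 0L
  for (bid in ids) {
    dc <- constraints_by_beacon[[bid]]
    d <- if (bid == best$beacon_id && !is.null(best$d) && mode == "single")
      best$d else median_time_diff(dc, best$location)
    cl <- classify_outliers(dc, best$location, d, delta, meters_threshold)
    n_out <- n_out + sum(!cl$inlier)
    if (!any(cl$inlier)) next
    r <- dc$receiver_id[cl$inlier]
    tag_receivers <- union(tag_receivers, r)
    pairs[[length(pairs) + 1L]] <- data.frame(beacon_id = bid,
                                              receiver_id = r,
                                              stringsAsFactors = FALSE)
  }
  if (length(unique(tag_receivers)) < 3)
    stop("underdetermined: fewer than 3 distinct receivers among inliers")
  sel <- toa_selection(tag_receivers, do.call(rbind, pairs))
  attr(sel, "n_outliers") <- n_out
  sel
}
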