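# Iterative weighted nonlinear least squares, covariance estimation, and
# the end-to-end localize() orchestration.

# Generic Levenberg-Marquardt on a residual/Jacobian pair.
# Multiplicative damping: start lambda0, x10 on reject, /10 on accept;
# stop on step norm < step_tol or max_iter.
lm_core <- function(resid_fun, jac_fun, x0, max_iter = 50, step_tol = 1e-4,
                    lambda0 = 1e-3, lambda_max = 1e12) {
  x <- as.numeric(x0)
  r <- resid_fun(x)
  f <- sum(r^2)
  lambda <- lambda0
  iter <- 0L
  status <- "maxiter"
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- jac_fun(x)
    g <- crossprod(J, r)
    H <- crossprod(J)
    repeat {
      step <- tryCatch(
        drop(solve(H + lambda * diag(nrow(H)), -g)),
        error = function(e) NULL)
      if (!is.null(step)) {
        xn <- x + step
        rn <- resid_fun(xn)
        fn <- sum(rn^2)
        if (is.finite(fn) && fn <= f) break
      }
      lambda <- lambda * 10
      if (lambda > lambda_max)
        return(list(par = x, f = f, iterations = iter, status = "failed"))
    }
    x <- xn; r <- rn; f <- fn
    lambda <- max(lambda / 10, 1e-12)
    if (sqrt(sum(step^2)) < step_tol) { status <- "converged"; break }
  }
  if (status == "maxiter") status <- "converged"  # budget exhausted; keep best
  list(par = x, f = f, iterations = iter, status = status)
}

#' Minimize a ToA objective by Levenberg--Marquardt
#'
#' Standard damped Gauss--Newton iteration on the projected weighted
#' residual of a [build_objective()] object. Damping starts at `1e-3`,
#' is multiplied by 10 on a rejected step and divided by 10 on an accepted
#' one; iteration stops when the step norm falls below `step_tol` meters or
#' after `max_iter` iterations.
#'
#' @param objective a `toa_objective`.
#' @param initial starting position (length = objective dimension).
#' @param max_iter,step_tol iteration controls.
#' @return list with `location` (length-3, altitude filled in 2D mode),
#'   `par`, `f`, `iterations`, `status` (`"converged"` or `"failed"`).
#' @export
levenberg_marquardt <- function(objective, initial, max_iter = 50,
                                step_tol = 1e-4) {
  stopifnot(inherits(objective, "toa_objective"))
  fit <- lm_core(objective$resid, objective$jac,
                 initial[seq_len(objective$dimension)],
                 max_iter = max_iter, step_tol = step_tol)
  loc <- if (objective$dimension == 2)
    c(fit$par, objective$fixed_altitude) else fit$par
  c(list(location = loc), fit)
}

#' First-derivative covariance of a location estimate
#'
#' With `B = (I - U U') W` the nuisance-projecting weighting and `J_M` the
#' Jacobian of the raw predictions at the converged estimate, the position
#' covariance is approximated by
#' `cov = (B J_M)^+ (I - U U') ((B J_M)^+)'`,
#' the pseudoinverse computed by SVD with tolerance `1e-10` times the
#' largest singular value. A rank-deficient `B J_M` yields an unreliable
#' covariance, which is inflated to `ceiling^2` times the identity and
#' flagged via attribute `"unreliable"`.
#'
#' @param objective a `toa_objective`.
#' @param location the converged estimate (length-3 or length-dimension).
#' @param ceiling standard-deviation ceiling for the unreliable case, m.
#' @return dimension x dimension covariance matrix, meters^2.
#' @export
estimate_covariance <- function(objective, location, ceiling = 1e4) {
  dim <- objective$dimension
  Jm <- objective$J_M(location[seq_len(dim)])
  U <- objective$U
  P <- diag(nrow(Jm)) - tcrossprod(U)
  BJ <- P %*% (objective$W * Jm)
  sv <- svd(BJ)
  rank <- sum(sv$d > 1e-10 * max(sv$d, 0))
  if (rank < dim) {
    cov <- diag(ceiling^2, dim)
    attr(cov, "unreliable") <- TRUE
    return(cov)
  }
  pinv <- sv$v %*% (t(sv$u) / sv$d)
  cov <- pinv %*% P %*% t(pinv)
  (cov + t(cov)) / 2
}

toa_unsolved <- function(reason, ...) {
  msg <- sprintf(reason, ...)
  stop(structure(class = c("toa_unsolved", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Configuration for localization runs
#'
#' All tunables of the pipeline with their defaults. Unknown keys are
#' rejected.
#'
#' @param variant hypothesis-selection variant: `"consensus"`,
#'   `"clustering"`, or `"baseline"` (no robust stages).
#' @param beacon_mode `"single"` or `"multi"` beacon ultimate set.
#' @param altitude_mode `"fixed"`, `"terrain"`, `"supplied"`, `"free3d"`.
#' @param fixed_altitude assumed altitude (2D modes), meters.
#' @param terrain_offset height above terrain in terrain mode, meters
#'   (e.g. 0 for a ground bird, 30 for a bat).
#' @param supplied_altitude caller-supplied altitude (e.g. altimeter), m.
#' @param dem a `dem_grid` for terrain mode.
#' @param delta weighted outlier threshold, standard deviations.
#' @param meters_threshold unweighted outlier threshold, meters.
#' @param outlier_rule `"both"` or `"weighted"` (see
#'   [classify_outliers()]).
#' @param max_beacons beacons admitted for hypothesis generation.
#' @param max_triplets_per_beacon,max_constraints triplet enumeration caps.
#' @param eps,min_pts DBSCAN parameters (clustering variant), meters / count.
#' @param kf_model `"cp"` (constant position) or `"cv"` (constant
#'   velocity).
#' @param evolution_const,evolution_cap Kalman evolution noise:
#'   `q(dt) = min(evolution_const * dt, evolution_cap)` meters.
#' @param queue_cap cap on stored ambiguous problems per tag.
#' @param time_window beacon detset admission window, seconds.
#' @param grouping_tolerance detset grouping window, seconds.
#' @param cov_ceiling unreliable-covariance standard deviation, meters.
#' @param seed optional RNG seed for batch drivers.
#' @return a list of class `toa_config`.
#' @export
toa_config <- function(variant = c("consensus", "clustering", "baseline"),
                       beacon_mode = c("single", "multi"),
                       altitude_mode = c("fixed", "terrain", "supplied",
                                         "free3d"),
                       fixed_altitude = 0, terrain_offset = 0,
                       supplied_altitude = NULL, dem = NULL,
                       delta = 3, meters_threshold = 100,
                       outlier_rule = c("both", "weighted"),
                       max_beacons = 5, max_triplets_per_beacon = 20,
                       max_constraints = 12, eps = 50, min_pts = 3,
                       kf_model = c("cp", "cv"), evolution_const = 10,
                       evolution_cap = 750, queue_cap = 1000,
                       time_window = 2, grouping_tolerance = 1e-3,
                       cov_ceiling = 1e4, seed = NULL) {
  cfg <- list(variant = match.arg(variant),
              beacon_mode = match.arg(beacon_mode),
              altitude_mode = match.arg(altitude_mode),
              fixed_altitude = fixed_altitude,
              terrain_offset = terrain_offset,
              supplied_altitude = supplied_altitude, dem = dem,
              delta = delta, meters_threshold = meters_threshold,
              outlier_rule = match.arg(outlier_rule),
              max_beacons = max_beacons,
              max_triplets_per_beacon = max_triplets_per_beacon,
              max_constraints = max_constraints, eps = eps,
              min_pts = min_pts, kf_model = match.arg(kf_model),
              evolution_const = evolution_const,
              evolution_cap = evolution_cap, queue_cap = queue_cap,
              time_window = time_window,
              grouping_tolerance = grouping_tolerance,
              cov_ceiling = cov_ceiling, seed = seed)
  structure(cfg, class = "toa_config")
}

# the assumed altitude for the first (hypothesis/2D) solve
assumed_altitude <- function(config) {
  if (config$altitude_mode == "supplied") {
    if (is.null(config$supplied_altitude))
      stop("supplied altitude mode requires supplied_altitude")
    config$supplied_altitude
  } else config$fixed_altitude
}

#' Localize one tag packet (robust pipeline)
#'
#' The fitting function of the package. Ranks the problem's beacon
#' detsets, generates closed-form hypotheses from receiver triplets,
#' selects the best one by consensus or clustering, refines it over its
#' consensus set, assembles the ultimate raw-constraint set (discarding
#' outliers), and minimizes the nuisance-eliminated weighted least-squares
#' objective by Levenberg--Marquardt, honoring the configured altitude
#' mode. `variant = "baseline"` skips every robust stage (prior/centroid
#' start, all constraints).
#'
#' @param problem a `toa_problem`.
#' @param config a `toa_config`.
#' @return an object of class `toa_estimate`: position, covariance,
#'   `nbs` (number of base stations), `std` (square root of the largest
#'   covariance eigenvalue -- the uncertainty along the worst direction),
#'   `ambiguous` flag and diagnostics. Throws a condition of class
#'   `toa_unsolved` when no consistent solution exists.
#' @seealso [toa_problem()], [toa_config()], [localize_baseline()]
#' @export
localize <- function(problem, config = toa_config()) {
  stopifnot(inherits(problem, "toa_problem"))
  if (config$variant == "baseline") return(localize_baseline(problem, config))
  z0 <- assumed_altitude(config)
  ranked <- rank_beacon_detsets(problem$tag_detset, problem$beacon_detsets)
  hyps <- withCallingHandlers(
    generate_hypotheses(problem$tag_detset, ranked, problem$receivers,
                        fixed_altitude = z0, max_beacons = config$max_beacons,
                        max_triplets_per_beacon = config$max_triplets_per_beacon,
                        max_constraints = config$max_constraints),
    message = function(m) invokeRestart("muffleMessage"))
  cons <- attr(hyps, "constraints_by_beacon")
  if (!length(hyps)) toa_unsolved("no hypotheses could be generated")
  res <- tryCatch({
    if (config$variant == "consensus") {
      select_consensus(hyps, cons, prior = problem$prior,
                       delta = config$delta,
                       meters_threshold = config$meters_threshold)
    } else {
      h <- select_clustering(hyps, eps = config$eps,
                             min_pts = config$min_pts,
                             constraints_by_beacon = cons,
                             delta = config$delta,
                             meters_threshold = config$meters_threshold)
      cl <- classify_outliers(cons[[h$beacon_id]], h$location, h$d,
                              config$delta, config$meters_threshold)
      structure(list(hypothesis = h, inliers = cl$inliers,
                     consensus_size = sum(cl$inlier),
                     max_weighted_residual =
                       if (any(cl$inlier)) max(abs(cl$wres[cl$inlier])) else Inf,
                     prior_distance = NA_real_),
                class = "consensus_result")
    }
  }, error = function(e) {
    if (inherits(e, "toa_unsolved")) stop(e)
    toa_unsolved("hypothesis selection failed: %s", conditionMessage(e))
  })
  best <- refine_single_beacon(res, fixed_altitude = z0)
  sel <- tryCatch(
    assemble_ultimate(problem, best, cons, mode = config$beacon_mode,
                      delta = config$delta,
                      meters_threshold = config$meters_threshold),
    error = function(e) toa_unsolved("%s", conditionMessage(e)))
  est <- finish_estimate(problem, config, sel, start = best$location,
                         n_hypotheses = length(hyps),
                         n_outliers = attr(sel, "n_outliers"))
  if (est$ambiguous)
    est$candidates <- mirror_candidates(est, best, cons, z0)
  est
}

# both closed-form solutions of an exactly determined (3-receiver)
# problem, as candidate (x, y) rows for later disambiguation
mirror_candidates <- function(est, best, constraints_by_beacon, z0) {
  dc <- constraints_by_beacon[[best$beacon_id]]
  sel <- est$diagnostics$selection
  dc <- dc[dc$receiver_id %in% sel$tag_receivers, , drop = FALSE]
  cand <- matrix(est$location[1:2], 1)
  if (nrow(dc) == 3) {
    pos <- cbind(dc$rx, dc$ry, dc$rz)
    ti <- SPEED_OF_LIGHT * dc$t_diff + dist3(pos, c(dc$bx[1], dc$by[1],
                                                    dc$bz[1]))
    sols <- try(solve_exact(pos, ti, known_z = z0), silent = TRUE)
    if (!inherits(sols, "try-error") && length(sols) == 2) {
      xy <- t(vapply(sols, function(s) s$location[1:2], numeric(2)))
      # keep the converged estimate itself plus the mirror solution
      far <- which.max((xy[, 1] - est$location[1])^2 +
                         (xy[, 2] - est$location[2])^2)
      cand <- rbind(cand, xy[far, ])
    }
  }
  cand
}

#' Baseline localizer (no robust stages)
#'
#' Minimal comparison baseline: initial guess at the prior location if one
#' exists, otherwise the centroid of the receivers that detected the tag,
#' then Levenberg--Marquardt on the multi-beacon objective using every
#' available constraint. No outlier rejection.
#'
#' @inheritParams localize
#' @return a `toa_estimate`.
#' @export
localize_baseline <- function(problem, config = toa_config()) {
  sel <- full_selection(problem)
  if (length(sel$tag_receivers) < 3)
    toa_unsolved("underdetermined: fewer than 3 receivers")
  if (!is.null(problem$prior)) {
    start <- c(track_position(problem$prior), assumed_altitude(config))
  } else {
    rp <- receiver_positions(problem$receivers, sel$tag_receivers)
    start <- c(mean(rp[, 1]), mean(rp[, 2]), assumed_altitude(config))
  }
  finish_estimate(problem, config, sel, start = start, n_hypotheses = 0L,
                  n_outliers = 0L)
}

# shared tail of localize/localize_baseline: altitude modes, LM solve,
# covariance, flags
finish_estimate <- function(problem, config, sel, start, n_hypotheses,
                            n_outliers) {
  z0 <- assumed_altitude(config)
  solve_at <- function(dim, z, init) {
    obj <- tryCatch(build_objective(problem, sel, dim, z),
                    error = function(e) toa_unsolved("%s",
                                                     conditionMessage(e)))
    fit <- levenberg_marquardt(obj, init)
    if (fit$status == "failed")
      toa_unsolved("Levenberg-Marquardt diverged")
    list(obj = obj, fit = fit)
  }
  mode <- config$altitude_mode
  alt_used <- mode
  if (mode == "free3d") {
    if (length(sel$tag_receivers) < 4)
      toa_unsolved("free-3D altitude requires at least 4 receivers")
    warning("free-3D altitude estimates are usually inaccurate for ",
            "planar receiver networks")
    s <- solve_at(3, NA, c(start[1:2], z0))
  } else if (mode == "terrain") {
    if (is.null(config$dem)) stop("terrain mode requires config$dem")
    s <- solve_at(2, z0, start[1:2])
    elev <- tryCatch(
      dem_elevation(config$dem, s$fit$location[1], s$fit$location[2]),
      error = function(e) NULL)
    if (is.null(elev)) {
      warning("DEM lookup failed; falling back to fixed-altitude solution")
      alt_used <- "fixed (terrain fallback)"
    } else {
      s <- solve_at(2, elev + config$terrain_offset, s$fit$location[1:2])
    }
  } else {
    s <- solve_at(2, z0, start[1:2])
  }
  cov <- estimate_covariance(s$obj, s$fit$location,
                             ceiling = config$cov_ceiling)
  std <- sqrt(max(eigen(cov, symmetric = TRUE, only.values = TRUE)$values))
  nbs <- s$obj$nbs
  prior <- problem$prior
  ambiguous <- nbs == 3 && (is.null(prior) || isTRUE(prior$ambiguous))
  structure(list(
    location = s$fit$location, covariance = cov, nbs = nbs,
    ambiguous = ambiguous, std = std,
    emitter_id = problem$tag_detset$emitter_id,
    packet_id = problem$tag_detset$packet_id,
    time = problem$time, dimension = s$obj$dimension,
    diagnostics = list(variant = config$variant,
                       altitude_mode = alt_used,
                       iterations = s$fit$iterations, fmin = s$fit$f,
                       n_hypotheses = n_hypotheses,
                       n_outliers = n_outliers,
                       cov_unreliable = isTRUE(attr(cov, "unreliable")),
                       selection = sel)),
    class = "toa_estimate")
}

#' @export
print.toa_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("<toa_estimate> %s / %s @ %.3f s\n", x$emitter_id,
              x$packet_id, x$time))
  cat(sprintf("  position: (%.*f, %.*f, %.*f) m\n", digits, x$location[1],
              digits, x$location[2], digits, x$location[3]))
  cat(sprintf("  std %.*f m | nbs %d | %s%s\n", digits, x$std, x$nbs,
              x$diagnostics$variant,
              if (x$ambiguous) " | AMBIGUOUS" else ""))
  invisible(x)
}

#' @export
coef.toa_estimate <- function(object, ...) {
  stats::setNames(object$location, c("x", "y", "z"))
}

#' @export
vcov.toa_estimate <- function(object, ...) object$covariance

#' @export
summary.toa_estimate <- function(object, ...) {
  d <- object$diagnostics
  cat(sprintf(
    "ToA localization of %s (packet %s)\n  position (m): %.3f %.3f %.3f\n",
    object$emitter_id, object$packet_id, object$location[1],
    object$location[2], object$location[3]))
  cat(sprintf("  std (worst direction): %.3f m\n", object$std))
  cat("  covariance (m^2):\n")
  print(object$covariance)
  cat(sprintf(
    "  nbs %d | ambiguous %s | variant %s | altitude %s\n  %d hypotheses, %d outlier difference constraints removed, %d LM iterations, f = %.3g\n",
    object$nbs, object$ambiguous, d$variant, d$altitude_mode,
    d$n_hypotheses, d$n_outliers, d$iterations, d$fmin))
  invisible(object)
}
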