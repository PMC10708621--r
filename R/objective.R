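# The nuisance-eliminated weighted least-squares objective.
#
# Raw constraints (tag and beacon arrival times) depend linearly on the
# nuisance parameters: the tag transmission time tau_i, one tau_b per
# beacon, and one clock offset o_r per receiver (one offset pinned to zero
# to fix the gauge). Writing the weighted prediction as
# W (m(l) + N theta), the minimum over theta of the weighted squared error
# is || (I - U U') W (y - m(l)) ||^2, where U is an orthonormal basis of
# range(W N). This is the objective f(l) used by every iterative solve.

#' Selection of raw constraints entering an objective
#'
#' @param tag_receivers character receiver ids contributing tag constraints.
#' @param beacon_pairs data.frame with columns `beacon_id`, `receiver_id`
#'   of contributing beacon constraints.
#' @return a list of class `toa_selection`.
#' @export
toa_selection <- function(tag_receivers, beacon_pairs) {
  stopifnot(is.data.frame(beacon_pairs),
            all(c("beacon_id", "receiver_id") %in% names(beacon_pairs)))
  structure(list(tag_receivers = unique(as.character(tag_receivers)),
                 beacon_pairs = unique(beacon_pairs[c("beacon_id",
                                                      "receiver_id")])),
            class = "toa_selection")
}

#' Selection using every available constraint of a problem
#'
#' Tag constraints for all detected receivers known to the receiver table;
#' beacon constraints restricted to receivers that also detected the tag
#' (beacon detections at other receivers carry no position information).
#'
#' @param problem a `toa_problem`.
#' @return a `toa_selection`.
#' @export
full_selection <- function(problem) {
  tagr <- intersect(problem$tag_detset$detections$receiver_id,
                    problem$receivers$id)
  bp <- do.call(rbind, lapply(problem$beacon_detsets, function(b) {
    r <- intersect(b$detections$receiver_id, tagr)
    if (!length(r)) return(NULL)
    data.frame(beacon_id = beacon_key(b), receiver_id = r,
               stringsAsFactors = FALSE)
  }))
  if (is.null(bp)) bp <- data.frame(beacon_id = character(),
                                    receiver_id = character())
  toa_selection(tagr, bp)
}

#' Build the projected weighted least-squares objective
#'
#' Assembles the raw tag and beacon arrival-time constraints named by
#' `selection`, eliminates the linear nuisance parameters (transmission
#' times and receiver clock offsets, with the offset of the
#' lexicographically smallest participating receiver pinned to zero as the
#' gauge), and returns an objective object whose value
#' `f(l) = min_theta sum of weighted squared residuals`.
#'
#' The nuisance basis is computed rank-aware (singular values below
#' `1e-10 * max` are treated as zero), so any residual gauge redundancy is
#' absorbed automatically and `f` is invariant to the pinning choice.
#'
#' @param problem a `toa_problem`.
#' @param selection a `toa_selection` (see [toa_selection()],
#'   [full_selection()]).
#' @param dimension 2 or 3 free position coordinates (distances are always
#'   3D; in 2D the altitude is fixed at `fixed_altitude`).
#' @param fixed_altitude altitude used in 2D mode, meters.
#' @return an object of class `toa_objective` with elements `f(l)`,
#'   `resid(l)`, `jac(l)` (Jacobian of the projected residual), `J_M(l)`
#'   (Jacobian of the raw predictions), `W`, `U`, `nbs`, `n_constraints`.
#' @export
build_objective <- function(problem, selection, dimension = 2,
                            fixed_altitude = 0) {
  stopifnot(inherits(problem, "toa_problem"),
            inherits(selection, "toa_selection"),
            dimension %in% c(2, 3))
  tg <- problem$tag_detset$detections
  it <- match(selection$tag_receivers, tg$receiver_id)
  if (anyNA(it)) stop("selected tag receiver not in tag detset")
  rows <- data.frame(y = tg$toa_s[it], sigma = tg$sigma_s[it],
                     receiver_id = tg$receiver_id[it],
                     tau = "tau:<tag>", type = "tag",
                     stringsAsFactors = FALSE)
  bmap <- list()
  for (b in problem$beacon_detsets) bmap[[beacon_key(b)]] <- b
  bp <- selection$beacon_pairs
  if (nrow(bp)) {
    brows <- lapply(seq_len(nrow(bp)), function(k) {
      b <- bmap[[bp$beacon_id[k]]]
      if (is.null(b)) stop("unknown beacon in selection: ", bp$beacon_id[k])
      i <- match(bp$receiver_id[k], b$detections$receiver_id)
      if (is.na(i)) stop("selected beacon receiver not detected")
      data.frame(y = b$detections$toa_s[i], sigma = b$detections$sigma_s[i],
                 receiver_id = bp$receiver_id[k],
                 tau = paste0("tau:", bp$beacon_id[k]), type = "beacon",
                 stringsAsFactors = FALSE)
    })
    rows <- rbind(rows, do.call(rbind, brows))
  }
  n <- nrow(rows)
  rp <- receiver_positions(problem$receivers, rows$receiver_id)
  # constant geometric part of beacon predictions
  const <- numeric(n)
  for (k in which(rows$type == "beacon")) {
    b <- bmap[[sub("^tau:", "", rows$tau[k])]]
    const[k] <- dist3(rp[k, ], b$known_position) / SPEED_OF_LIGHT
  }
  # nuisance incidence: tag/beacon transmission times + receiver offsets
  recs <- sort(unique(rows$receiver_id))
  pinned <- recs[1]  # gauge: lexicographically smallest receiver
  cols <- c(unique(rows$tau), paste0("off:", setdiff(recs, pinned)))
  N <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  N[cbind(seq_len(n), match(rows$tau, cols))] <- 1
  off <- match(paste0("off:", rows$receiver_id), cols)
  ok <- !is.na(off)
  N[cbind(which(ok), off[ok])] <- 1
  W <- 1 / rows$sigma
  A <- W * N
  sv <- svd(A)
  rank <- sum(sv$d > 1e-10 * max(sv$d, 0))
  if (n - rank < dimension)
    stop("underdetermined: ", n, " constraints, nuisance rank ", rank,
         ", ", dimension, " position unknowns")
  U <- sv$u[, seq_len(rank), drop = FALSE]
  tagrow <- rows$type == "tag"
  yvec <- rows$y
  loc3 <- function(l) {
    if (dimension == 2) c(l[1], l[2], fixed_altitude) else l[1:3]
  }
  m_fun <- function(l) {
    l3 <- loc3(l)
    g <- const
    g[tagrow] <- dist3(rp[tagrow, , drop = FALSE], l3) / SPEED_OF_LIGHT
    g
  }
  J_M <- function(l) {
    l3 <- loc3(l)
    J <- matrix(0, n, dimension)
    d <- dist3(rp[tagrow, , drop = FALSE], l3)
    d[d == 0] <- .Machine$double.eps  # receiver-coincident location is legal
    for (j in seq_len(dimension))
      J[tagrow, j] <- (l3[j] - rp[tagrow, j]) / (SPEED_OF_LIGHT * d)
    J
  }
  # remove a rough nuisance solve from y up front: N theta0 lies in the
  # projected-away subspace, so f is unchanged, but the projection then
  # acts on residual-scale numbers instead of second-scale transmission
  # times (an 8-order-of-magnitude conditioning gain under the 1/sigma
  # weights)
  rp_all <- receiver_positions(problem$receivers,
                               sort(unique(rows$receiver_id)))
  lc <- c(mean(rp_all[, 1]), mean(rp_all[, 2]))
  theta0 <- qr.coef(qr(A), W * (yvec - m_fun(lc)))
  theta0[is.na(theta0)] <- 0
  yvec <- yvec - drop(N %*% theta0)
  project <- function(v) v - U %*% crossprod(U, v)
  resid <- function(l) drop(project(W * (yvec - m_fun(l))))
  obj <- list(
    f = function(l) sum(resid(l)^2),
    resid = resid,
    jac = function(l) -apply(W * J_M(l), 2, function(col) drop(project(col))),
    m_fun = m_fun, J_M = J_M,
    W = W, U = U, y = rows$y,
    dimension = dimension, fixed_altitude = fixed_altitude,
    nbs = length(unique(rows$receiver_id[tagrow])),
    n_constraints = n, pinned = pinned, rows = rows)
  class(obj) <- "toa_objective"
  obj
}

#' @export
print.toa_objective <- function(x, ...) {
  cat(sprintf(
    "<toa_objective> %d constraints (%d tag receivers), %dD, nuisance rank %d\n",
    x$n_constraints, x$nbs, x$dimension, ncol(x$U)))
  invisible(x)
}
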