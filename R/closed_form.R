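# Algebraic closed-form solver for exactly determined (differenced) ToA
# problems. Working units are meters: each constraint reads
#   t_i - t = |p_i - l|        (Eq. "range" form)
# with p_i the receiver position, t_i the measured pseudorange
# (c * (t_diff + |rho_r - l_b|/c)) and t = c * (tau_i - tau_b) the unknown
# pseudorange offset. Squaring and differencing adjacent equations cancels
# the quadratic terms, leaving a linear system A u = b with a
# one-dimensional null space; substituting u = w + alpha * v into one
# squared equation yields a quadratic in alpha, hence 0, 1 or 2 solutions.

#' Build the squared-and-differenced linear system
#'
#' Rows difference adjacent equations (a spanning path):
#' `A[i,] = [2(x_i-x_j), 2(y_i-y_j), 2(z_i-z_j), -2(t_i-t_j)]` with
#' `j = i+1`, and
#' `b[i] = -(t_i^2-t_j^2) + (x_i^2-x_j^2) + (y_i^2-y_j^2) + (z_i^2-z_j^2)`.
#' Columns of known unknowns (`z` and/or `t`) are folded into `b` and
#' dropped.
#'
#' @param positions m x 3 matrix of receiver positions, meters.
#' @param ti length-m measured pseudoranges, meters.
#' @param known_z,known_t fixed values (meters) or `NULL` if unknown.
#' @return list with `A`, `b`, `unknowns` (column names among x,y,z,t),
#'   `degenerate_rows` (indices of all-zero rows).
#' @export
build_squared_system <- function(positions, ti, known_z = NULL,
                                 known_t = NULL) {
  positions <- as.matrix(positions)
  m <- nrow(positions)
  stopifnot(length(ti) == m, m >= 2)
  i <- seq_len(m - 1); j <- i + 1
  Afull <- cbind(2 * (positions[i, 1] - positions[j, 1]),
                 2 * (positions[i, 2] - positions[j, 2]),
                 2 * (positions[i, 3] - positions[j, 3]),
                 -2 * (ti[i] - ti[j]))
  Afull <- matrix(Afull, nrow = m - 1)
  b <- -(ti[i]^2 - ti[j]^2) + rowSums(positions[i, , drop = FALSE]^2) -
    rowSums(positions[j, , drop = FALSE]^2)
  keep <- c(TRUE, TRUE, is.null(known_z), is.null(known_t))
  if (!is.null(known_z)) b <- b - Afull[, 3] * known_z
  if (!is.null(known_t)) b <- b - Afull[, 4] * known_t
  A <- Afull[, keep, drop = FALSE]
  scale <- max(abs(A), 1)
  deg <- which(apply(abs(A), 1, max) <= 1e-12 * scale)
  list(A = A, b = b, unknowns = c("x", "y", "z", "t")[keep],
       known_z = known_z, known_t = known_t, positions = positions,
       ti = ti, degenerate_rows = deg)
}

#' Quadratic coefficients of the null-space substitution
#'
#' Substituting `u = w + alpha v` (full 4-vectors over x, y, z, t; known
#' components carry `v = 0`) into one squared equation
#' `(x_i-x)^2 + (y_i-y)^2 + (z_i-z)^2 - (t_i-t)^2 = 0` gives
#' `a2 alpha^2 + a1 alpha + a0 = 0` with, per component `k` and sign
#' `s = (+1,+1,+1,-1)`:
#' `a2 += s v_k^2`, `a1 += -2 s (p_k - w_k) v_k`, `a0 += s (p_k - w_k)^2`.
#'
#' @param w,v numeric length-4 vectors (x, y, z, t components).
#' @param p numeric length-4: `(x_i, y_i, z_i, t_i)` of the equation used.
#' @return named numeric `c(a2, a1, a0)`.
#' @export
quadratic_coefficients <- function(w, v, p) {
  s <- c(1, 1, 1, -1)
  r <- p - w
  c(a2 = sum(s * v^2), a1 = sum(-2 * s * r * v), a0 = sum(s * r^2))
}

# a couple of Newton steps on the original (unsquared) range equations
# g_i = |p_i - l| - (t_i - t) = 0, to polish away the cancellation the
# squaring step incurs when the t_i carry a large common magnitude.
# slots: indices among (x, y, z, t) that are free unknowns.
newton_polish <- function(positions, ti, loc, tt, slots, iters = 2) {
  m <- nrow(positions)
  for (it in seq_len(iters)) {
    dl <- sweep(-positions, 2, loc, `+`)  # l - p_i rows
    dist <- sqrt(rowSums(dl^2))
    if (any(dist == 0)) break
    g <- dist - (ti - tt)
    J4 <- cbind(dl / dist, 1)
    J <- J4[, slots, drop = FALSE]
    step <- tryCatch(qr.solve(J, -g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    u <- c(loc, tt)
    u[slots] <- u[slots] + step
    loc <- u[1:3]; tt <- u[4]
  }
  list(loc = loc, t = tt)
}

# numerically stable real quadratic roots; near-double roots collapse to one
quad_roots <- function(a2, a1, a0) {
  scale <- max(abs(c(a1^2, 4 * a2 * a0, 1)))
  if (abs(a2) <= 1e-14 * max(abs(a1), abs(a0), 1)) {
    if (abs(a1) <= 1e-14 * max(abs(a0), 1)) return(numeric(0))
    return(-a0 / a1)
  }
  disc <- a1^2 - 4 * a2 * a0
  if (disc < -1e-12 * scale) return(numeric(0))
  if (abs(disc) <= 1e-12 * scale) return(-a1 / (2 * a2))
  q <- -(a1 + sign(a1 + (a1 == 0)) * sqrt(disc)) / 2
  if (q == 0) return(0)
  c(q / a2, a0 / q)
}

#' Solve an exactly determined ToA problem in closed form
#'
#' Modes are implied by which values are known: 2D multilateration
#' (`known_z` given, `t` unknown, m = 3), 3D multilateration (nothing
#' known, m = 4), 2D trilateration (`known_z` and `known_t`, m = 2), 3D
#' trilateration (`known_t` only, m = 3).
#'
#' Solutions of the squared system whose range differences `t_i - t` are
#' all nonnegative satisfy the original (unsquared) equations. If all `t_i`
#' are identical and the differences are negative, `t` is repaired to
#' `2 t_i - t`; mixed-sign solutions are inconsistent with the unsquared
#' equations and dropped (with a message when `verbose`).
#'
#' @inheritParams build_squared_system
#' @param verbose emit a message when an inconsistent solution is dropped.
#' @return list (possibly empty, at most 2) of solutions, each a list with
#'   `location` (length-3, meters), `t` (pseudorange offset, meters),
#'   `alpha`, `valid_sign` (TRUE), and `residual` (max abs squared-equation
#'   residual, m^2).
#' @export
solve_exact <- function(positions, ti, known_z = NULL, known_t = NULL,
                        verbose = FALSE) {
  positions <- as.matrix(positions)
  m <- nrow(positions)
  expected <- 2L + is.null(known_z) + is.null(known_t)
  if (m != expected)
    stop(sprintf("mode expects m = %d equations, got %d", expected, m))
  # the equations are invariant under a common shift of (ti, t); remove
  # any large common offset before squaring to avoid cancellation
  t_shift <- if (is.null(known_t)) ti[1] else known_t
  ti <- ti - t_shift
  if (!is.null(known_t)) known_t <- 0
  sys <- build_squared_system(positions, ti, known_z, known_t)
  A <- sys$A
  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  if (nrow(A) == 0 || sv$d[nrow(A)] <= 1e-8 * sv$d[1])
    stop("degenerate geometry: difference system is rank deficient")
  # min-norm particular solution and the null direction
  w <- sv$v[, seq_len(nrow(A)), drop = FALSE] %*%
    (crossprod(sv$u[, seq_len(nrow(A)), drop = FALSE], sys$b) /
       sv$d[seq_len(nrow(A))])
  v <- sv$v[, ncol(A)]
  full <- function(u, known, slots) {
    out <- numeric(4)
    out[slots] <- u
    if (!is.null(known$z)) out[3] <- known$z
    if (!is.null(known$t)) out[4] <- known$t
    out
  }
  slots <- which(c(TRUE, TRUE, is.null(known_z), is.null(known_t)))
  known <- list(z = known_z, t = known_t)
  w4 <- full(drop(w), known, slots)
  v4 <- full(v, list(z = NULL, t = NULL), slots)  # known comps: v = 0
  p1 <- c(positions[1, ], ti[1])
  co <- quadratic_coefficients(w4, v4, p1)
  roots <- quad_roots(co[["a2"]], co[["a1"]], co[["a0"]])
  t_unknown <- is.null(known_t)
  tol_sign <- 1e-6
  out <- list()
  for (alpha in roots) {
    u <- w4 + alpha * v4
    loc <- u[1:3]; tt <- u[4]
    if (t_unknown) {
      d <- ti - tt
      if (all(d >= -tol_sign)) {
        # ok
      } else if (all(d <= tol_sign)) {
        if (max(ti) - min(ti) <= tol_sign) {
          tt <- 2 * ti[1] - tt  # negate the differences
        } else {
          if (verbose) message("dropping inconsistent closed-form solution ",
                               "(all range differences negative)")
          next
        }
      } else {
        if (verbose) message("dropping inconsistent closed-form solution ",
                             "(mixed-sign range differences)")
        next
      }
    }
    pol <- newton_polish(positions, ti, loc, tt, slots)
    loc <- pol$loc; tt <- pol$t
    res <- max(abs((positions[, 1] - loc[1])^2 + (positions[, 2] - loc[2])^2 +
                     (positions[, 3] - loc[3])^2 - (ti - tt)^2))
    out[[length(out) + 1L]] <- list(location = loc, t = tt + t_shift,
                                    alpha = alpha, valid_sign = TRUE,
                                    residual = res)
  }
  # sign repair can map both roots onto one point: deduplicate
  if (length(out) == 2 &&
      max(abs(c(out[[1]]$location - out[[2]]$location,
                out[[1]]$t - out[[2]]$t))) < 1e-6)
    out <- out[1]
  out
}
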