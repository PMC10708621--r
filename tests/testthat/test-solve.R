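test_that("Levenberg-Marquardt converges from near and far starts", {
  set.seed(51)
  tp <- toy_problem(n_receivers = 7, noise = FALSE)
  obj <- build_objective(tp$problem, full_selection(tp$problem), 2,
                         fixed_altitude = tp$tag[3])
  # start at the truth: immediate fixed point
  fit0 <- levenberg_marquardt(obj, tp$tag[1:2])
  expect_lte(fit0$iterations, 2)
  expect_lt(fit0$f, 1e-12)
  # start 1 km away: full recovery
  fit1 <- levenberg_marquardt(obj, tp$tag[1:2] + c(800, -600))
  expect_equal(fit1$status, "converged")
  expect_lt(d3(fit1$location[1:2], tp$tag[1:2]), 1e-4)
})

test_that("LM solves a linear least-squares problem exactly", {
  # on a synthetic affine residual the minimizer must match the normal
  # equations in one step
  set.seed(52)
  A <- matrix(rnorm(12), 6, 2)
  b <- rnorm(6)
  resid <- function(x) drop(A %*% x - b)
  jac <- function(x) A
  fit <- toatrack:::lm_core(resid, jac, c(5, -3), step_tol = 1e-10)
  expect_equal(fit$par, drop(solve(crossprod(A), crossprod(A, b))),
               tolerance = 1e-8)
})

test_that("covariance matches the textbook linear-model formula", {
  set.seed(53)
  tp <- toy_problem(n_receivers = 8, n_beacons = 2, sigma = 5e-9)
  sel <- full_selection(tp$problem)
  obj <- build_objective(tp$problem, sel, 2, fixed_altitude = tp$tag[3])
  fit <- levenberg_marquardt(obj, tp$tag[1:2], step_tol = 1e-8)
  cov <- estimate_covariance(obj, fit$location)
  # independent route: (J' P' W' W P J)^-1 on the projected design
  J <- obj$W * obj$J_M(fit$location[1:2])
  P <- diag(nrow(J)) - tcrossprod(obj$U)
  PJ <- P %*% J
  cov_ref <- solve(crossprod(PJ))
  expect_equal(cov, cov_ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("covariance is homogeneous of degree 2 in sigma", {
  set.seed(54)
  tp <- toy_problem(n_receivers = 6, noise = FALSE, sigma = 5e-9)
  scale_sig <- function(p, s) {
    p$tag_detset$detections$sigma_s <- p$tag_detset$detections$sigma_s * s
    p$beacon_detsets <- lapply(p$beacon_detsets, function(b) {
      b$detections$sigma_s <- b$detections$sigma_s * s
      b
    })
    p
  }
  sel <- full_selection(tp$problem)
  o1 <- build_objective(tp$problem, sel, 2, 0)
  p2 <- scale_sig(tp$problem, 2)
  o2 <- build_objective(p2, full_selection(p2), 2, 0)
  c1 <- estimate_covariance(o1, tp$tag)
  c2 <- estimate_covariance(o2, tp$tag)
  expect_equal(c2, 4 * c1, tolerance = 1e-10)
})

test_that("Monte Carlo covariance of the estimator matches the formula", {
  # fixed 8-receiver geometry, sigma = 5 ns, repeated noisy solves
  set.seed(55)
  rec <- receiver_table(sprintf("R%d", 1:8),
                        x = c(600, 4200, 7600, 1800, 6400, 800, 5200, 8600),
                        y = c(700, 300, 1400, 4600, 5000, 8200, 7400, 8800),
                        z = c(12, 25, 8, 30, 5, 18, 22, 15))
  truth <- c(3600, 3900, 0)
  bpos <- c(5000, 2500, 3)
  sigma <- 5e-9
  offs <- runif(8, -1e-3, 1e-3)
  nrep <- 400
  ests <- matrix(0, nrep, 2)
  cov_f <- NULL
  for (r in seq_len(nrep)) {
    mk <- function(em, pk, pos, tau) {
      dist <- sqrt((rec$x - pos[1])^2 + (rec$y - pos[2])^2 +
                     (rec$z - pos[3])^2)
      detection_table(pk, em, rec$id,
                      tau + dist / C_LIGHT + offs + rnorm(8, 0, sigma),
                      sigma, timestamp_s = tau)
    }
    pr <- toa_problem(detset(mk("TAG", "P1", truth, 0)),
                      list(detset(mk("B1", "P1-B1", bpos, 0.3),
                                  known_position = bpos)), rec)
    obj <- build_objective(pr, full_selection(pr), 2, fixed_altitude = 0)
    fit <- levenberg_marquardt(obj, truth[1:2], step_tol = 1e-7)
    ests[r, ] <- fit$location[1:2]
    if (r == 1) cov_f <- estimate_covariance(obj, fit$location)
  }
  cov_emp <- stats::cov(ests)
  expect_equal(cov_emp[1, 1], cov_f[1, 1], tolerance = 0.25)
  expect_equal(cov_emp[2, 2], cov_f[2, 2], tolerance = 0.25)
  # reported std is the worst-direction standard deviation
  expect_equal(sqrt(max(eigen(cov_f)$values)),
               sqrt(max(eigen(cov_f, only.values = TRUE)$values)))
})

test_that("bilinear DEM lookup is exact for constant and ramp rasters", {
  flat <- make_dem(c(3000, 3000), "flat", value = 30)
  expect_equal(dem_elevation(flat, 1234.5, 2000.1), 30)
  expect_equal(dem_elevation(flat, 15, 15), 30)  # cell center
  ramp <- make_dem(c(3000, 3000), "ramp", value = 0, slope = 0.01)
  for (x in c(200.5, 1500, 2755)) {
    expect_equal(dem_elevation(ramp, x, 1100), 0.01 * x,
                 tolerance = 1e-9)
  }
  expect_error(dem_elevation(flat, -5, 100), "outside")
  hills1 <- make_dem(c(2000, 2000), "hills", seed = 5)
  hills2 <- make_dem(c(2000, 2000), "hills", seed = 5)
  expect_identical(hills1$z, hills2$z)
})

test_that("localize solves a noise-free problem to sub-millimeter", {
  set.seed(56)
  tp <- toy_problem(n_receivers = 6, noise = FALSE)
  est <- localize(tp$problem, toa_config(fixed_altitude = tp$tag[3]))
  expect_lt(err2d(est, tp$tag), 1e-4)
  expect_s3_class(est, "toa_estimate")
  expect_equal(est$nbs, 6)
  expect_false(est$ambiguous)
  expect_equal(est$std, sqrt(max(eigen(est$covariance)$values)))
  expect_equal(unname(coef(est)[1:2]), est$location[1:2])
  expect_equal(vcov(est), est$covariance)
})

test_that("free-3D mode needs four receivers and warns", {
  set.seed(57)
  tp <- toy_problem(n_receivers = 6, noise = FALSE, tag_z = 15)
  cfg <- toa_config(altitude_mode = "free3d")
  expect_warning(est <- localize(tp$problem, cfg), "free-3D")
  expect_equal(dim(est$covariance), c(3L, 3L))
})

test_that("terrain mode on a constant DEM equals fixed mode at that value", {
  set.seed(58)
  tp <- toy_problem(n_receivers = 6, noise = FALSE, extent = 2900,
                    tag_z = 30)
  dem <- make_dem(c(3000, 3000), "flat", value = 30)
  e_fix <- localize(tp$problem, toa_config(fixed_altitude = 30))
  e_ter <- localize(tp$problem,
                    toa_config(altitude_mode = "terrain", dem = dem,
                               fixed_altitude = 30))
  # the snapped altitude equals the fixed one bit-for-bit; the planar
  # solutions agree to solver precision (different LM starting points)
  expect_identical(e_ter$location[3], e_fix$location[3])
  expect_equal(e_ter$location, e_fix$location, tolerance = 1e-9)
  expect_equal(e_ter$covariance, e_fix$covariance, tolerance = 1e-9)
})

test_that("terrain snapping beats a wrong fixed altitude near a receiver", {
  # tag on a terrain ramp close to an elevated receiver: the assumed
  # altitude is badly wrong there, terrain mode corrects it
  set.seed(59)
  dem <- make_dem(c(6000, 6000), "ramp", value = 0, slope = 0.03)
  err_fix <- err_ter <- c()
  rec <- receiver_table(sprintf("R%d", 1:6),
                        x = c(5000, 200, 2500, 4800, 300, 2600),
                        y = c(2500, 300, 150, 4900, 4700, 5200),
                        z = 0.03 * c(5000, 200, 2500, 4800, 300, 2600) + 15)
  bpos <- c(2500, 2600, 0.03 * 2500 + 2)
  for (k in 1:25) {
    tagp <- c(5000 + runif(1, -150, -50), 2500 + runif(1, -50, 50), 0)
    tagp[3] <- 0.03 * tagp[1]  # on the terrain
    offs <- runif(6, -1e-3, 1e-3)
    mk <- function(em, pk, pos, tau) {
      dist <- sqrt((rec$x - pos[1])^2 + (rec$y - pos[2])^2 +
                     (rec$z - pos[3])^2)
      detection_table(pk, em, rec$id,
                      tau + dist / C_LIGHT + offs + rnorm(6, 0, 3e-9),
                      3e-9, timestamp_s = tau)
    }
    pr <- toa_problem(detset(mk("TAG", "P1", tagp, 0)),
                      list(detset(mk("B1", "P1-B1", bpos, 0.2),
                                  known_position = bpos)), rec)
    cfg_f <- toa_config(fixed_altitude = 90, outlier_rule = "weighted",
                        delta = 1e6)  # keep all constraints: isolate altitude
    cfg_t <- toa_config(altitude_mode = "terrain", dem = dem,
                        fixed_altitude = 90, outlier_rule = "weighted",
                        delta = 1e6)
    e_f <- localize(pr, cfg_f)
    e_t <- localize(pr, cfg_t)
    err_fix <- c(err_fix, err2d(e_f, tagp))
    err_ter <- c(err_ter, err2d(e_t, tagp))
  }
  expect_lt(median(err_ter), median(err_fix))
})

test_that("baseline localizer matches the robust one on clean data", {
  set.seed(60)
  tp <- toy_problem(n_receivers = 7, n_beacons = 2, noise = FALSE)
  cfg <- toa_config(fixed_altitude = tp$tag[3])
  e_r <- localize(tp$problem, cfg)
  e_b <- localize_baseline(tp$problem, cfg)
  expect_lt(d3(e_r$location[1:2], e_b$location[1:2]), 1)
  expect_lt(err2d(e_b, tp$tag), 1e-3)  # centroid start, interior tag
  # variant dispatch through localize()
  e_b2 <- localize(tp$problem, toa_config(variant = "baseline",
                                          fixed_altitude = tp$tag[3]))
  expect_equal(e_b2$location, e_b$location)
})

test_that("error/std calibration is near one on clean simulations", {
  set.seed(61)
  ratios <- c()
  for (k in 1:40) {
    tp <- toy_problem(n_receivers = 7, sigma = 5e-9)
    est <- localize(tp$problem, toa_config(fixed_altitude = tp$tag[3]))
    ratios <- c(ratios, err2d(est, tp$tag) / est$std)
  }
  expect_gt(median(ratios), 0.3)
  expect_lt(median(ratios), 3)
})
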