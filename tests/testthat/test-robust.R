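test_that("outlier classification applies strict thresholds", {
  set.seed(41)
  tp <- toy_problem(n_receivers = 6, noise = FALSE, sigma = 1e-9)
  dc <- make_diff_constraints(tp$tag_detset, tp$beacon_detsets[[1]],
                              tp$receivers)
  # all-zero residuals: no outliers
  cl <- classify_outliers(dc, tp$tag, tp$d_true[1])
  expect_true(all(cl$inlier))
  # boundary case in exact arithmetic: hypothesis at the beacon makes
  # the geometric terms cancel bit-for-bit, so a residual of exactly
  # delta sigma stays an inlier (strict >)
  bpos <- tp$beacon_detsets[[1]]$known_position
  dcb <- dc
  rp <- cbind(dcb$rx, dcb$ry, dcb$rz)
  dcb$sigma <- rep(1e-9, nrow(dcb))
  dcb$t_diff <- 0
  dcb$t_diff[2] <- 3 * dcb$sigma[2]
  cl2 <- classify_outliers(dcb, bpos, 0, delta = 3, rule = "weighted")
  expect_true(cl2$inlier[2])
  dcb$t_diff[2] <- 3.5 * dcb$sigma[2]
  cl3 <- classify_outliers(dcb, bpos, 0, delta = 3, rule = "weighted")
  expect_false(cl3$inlier[2])
  # under the combined rule a large weighted residual is kept while it
  # stays under the meters threshold
  cl4 <- classify_outliers(dcb, bpos, 0, delta = 3,
                           meters_threshold = 100, rule = "both")
  expect_true(cl4$inlier[2])  # 3.5 ns ~ 1 m << 100 m
})

test_that("an injected gross delay is flagged, and only it", {
  set.seed(42)
  for (k in 1:10) {
    tp <- toy_problem(n_receivers = 6, noise = FALSE, sigma = 3e-9,
                      outliers = "R04", outlier_delay = 1e-5)
    dc <- make_diff_constraints(tp$tag_detset, tp$beacon_detsets[[1]],
                                tp$receivers)
    cl <- classify_outliers(dc, tp$tag, NULL)
    expect_equal(cl$outliers$receiver_id, "R04")
  }
})

test_that("beacon ranking is lexicographic on intersection, time, SNR", {
  mkdet <- function(emitter, receivers, toas, snr = 20, packet = "p") {
    detection_table(packet, emitter, receivers, toas, 1e-9, snr_db = snr,
                    timestamp_s = toas)
  }
  tag <- detset(mkdet("TAG", c("r1", "r2", "r3", "r4", "r5"), rep(0, 5)))
  # A: intersection 5; B: intersection 4 -> A first regardless of SNR
  A <- detset(mkdet("A", c("r1", "r2", "r3", "r4", "r5"), rep(0.1, 5),
                    snr = 1), known_position = c(0, 0, 0))
  B <- detset(mkdet("B", c("r1", "r2", "r3", "r4"), rep(0.1, 4),
                    snr = 50), known_position = c(0, 0, 0))
  expect_equal(vapply(rank_beacon_detsets(tag, list(B, A)), `[[`, "",
                      "emitter_id"), c("A", "B"))
  # equal intersections: 0.5 s offset beats 3 s offset
  C <- detset(mkdet("C", c("r1", "r2", "r3", "r4"), rep(0.5, 4)),
              known_position = c(0, 0, 0))
  D <- detset(mkdet("D", c("r1", "r2", "r3", "r4"), rep(3, 4)),
              known_position = c(0, 0, 0))
  expect_equal(vapply(rank_beacon_detsets(tag, list(D, C)), `[[`, "",
                      "emitter_id"), c("C", "D"))
  # equal on both: higher SNR first
  E <- detset(mkdet("E", c("r1", "r2", "r3", "r4"), rep(0.1, 4),
                    snr = 20), known_position = c(0, 0, 0))
  F2 <- detset(mkdet("F", c("r1", "r2", "r3", "r4"), rep(0.1, 4),
                     snr = 10), known_position = c(0, 0, 0))
  expect_equal(vapply(rank_beacon_detsets(tag, list(F2, E)), `[[`, "",
                      "emitter_id"), c("E", "F"))
})

test_that("triplets are ordered by their worst sigma", {
  tri <- toatrack:::order_triplets(c(1, 2, 3, 9) * 1e-9)
  expect_equal(tri[[1]], c(1, 2, 3))
  # next-best triplet is sigmas {1, 2, 9} (ties on the worst sigma break
  # by the second-worst)
  expect_equal(tri[[2]], c(1, 2, 4))
})

test_that("noise-free hypothesis generation reaches the truth", {
  set.seed(43)
  for (k in 1:5) {
    tp <- toy_problem(n_receivers = 6, noise = FALSE)
    ranked <- rank_beacon_detsets(tp$tag_detset, tp$beacon_detsets)
    hyps <- generate_hypotheses(tp$tag_detset, ranked, tp$receivers,
                                fixed_altitude = tp$tag[3])
    errs <- vapply(hyps, function(h) d3(h$location[1:2], tp$tag[1:2]), 0)
    expect_lt(min(errs), 1e-6)
  }
})

test_that("degenerate collinear triplets never crash hypothesis generation", {
  rec <- receiver_table(c("r1", "r2", "r3"), c(0, 1000, 2000), 0, 0)
  bpos <- c(500, 800, 0)
  tagp <- c(900, 1200, 0)
  mk <- function(em, pk, pos, tau) {
    dist <- sqrt((rec$x - pos[1])^2 + (rec$y - pos[2])^2 + rec$z^2)
    detection_table(pk, em, rec$id, tau + dist / C_LIGHT, 1e-9,
                    timestamp_s = tau)
  }
  tag <- detset(mk("TAG", "p", tagp, 0))
  bcn <- detset(mk("B", "pb", bpos, 0.1), known_position = bpos)
  hyps <- generate_hypotheses(tag, list(bcn), rec, fixed_altitude = 0)
  # collinear receivers: mirror-pair hypotheses or clean skip
  expect_lte(length(hyps), 2)
  if (length(hyps) == 2) {
    errs <- vapply(hyps, function(h) d3(h$location[1:2], tagp[1:2]), 0)
    expect_lt(min(errs), 1e-6)
  }
})

test_that("clustering selection returns a member of the majority cluster", {
  near_p <- lapply(1:10, function(i)
    list(location = c(1000 + i, 2000 - i, 0), d = 0, beacon_id = "b",
         triplet = NULL, kind = "closed_form"))
  near_q <- lapply(1:3, function(i)
    list(location = c(9000 + i, 8000, 0), d = 0, beacon_id = "b",
         triplet = NULL, kind = "closed_form"))
  scatter <- lapply(1:4, function(i)
    list(location = c(i * 1.7e4, -i * 2.3e4, 0), d = 0, beacon_id = "b",
         triplet = NULL, kind = "closed_form"))
  sel <- select_clustering(c(near_p, near_q, scatter), eps = 50,
                           min_pts = 3)
  expect_lt(d3(sel$location[1:2], c(1005, 1995)), 20)
  # all identical hypotheses: that hypothesis is returned
  same <- lapply(1:5, function(i)
    list(location = c(42, 43, 0), d = 1e-6, beacon_id = "b",
         triplet = NULL, kind = "closed_form"))
  expect_equal(select_clustering(same, 50, 3)$location, c(42, 43, 0))
})

test_that("consensus selection ranks by size, then prior, then residual", {
  set.seed(44)
  tp <- toy_problem(n_receivers = 6, noise = FALSE, sigma = 1e-9)
  dc <- make_diff_constraints(tp$tag_detset, tp$beacon_detsets[[1]],
                              tp$receivers)
  key <- paste0(tp$beacon_detsets[[1]]$emitter_id, "@",
                tp$beacon_detsets[[1]]$packet_id)
  cons <- list(dc); names(cons) <- key
  # hypothesis A at the truth (6 inliers) vs B far away (fewer inliers)
  hA <- list(location = tp$tag, d = tp$d_true[1], beacon_id = key)
  hB <- list(location = tp$tag + c(5000, 5000, 0), d = tp$d_true[1],
             beacon_id = key)
  res <- select_consensus(list(hB, hA), cons)
  expect_equal(res$hypothesis$location, tp$tag)
  expect_equal(res$consensus_size, 6L)

  # equal sizes and near-equal max residuals: the prior decides
  prior <- track_state(position = tp$tag[1:2] + c(2000, 0), time = 0)
  hC <- list(location = tp$tag + c(2000, 0, 0), d = tp$d_true[1],
             beacon_id = key)
  hD <- list(location = tp$tag + c(-2000, 0, 0), d = tp$d_true[1],
             beacon_id = key)
  # both hypotheses far from truth: equally sized consensus sets via the
  # permissive meters threshold
  resP <- select_consensus(list(hD, hC), cons, prior = prior,
                           delta = 1e9, meters_threshold = 1e9)
  expect_equal(resP$hypothesis$location, hC$location)
})

test_that("selection is invariant to hypothesis enumeration order", {
  set.seed(45)
  tp <- toy_problem(n_receivers = 7, sigma = 5e-9)
  ranked <- rank_beacon_detsets(tp$tag_detset, tp$beacon_detsets)
  hyps <- generate_hypotheses(tp$tag_detset, ranked, tp$receivers, 0)
  cons <- attr(hyps, "constraints_by_beacon")
  r1 <- select_consensus(hyps, cons)
  r2 <- select_consensus(rev(hyps), cons)
  expect_equal(r1$hypothesis$location, r2$hypothesis$location)
  s1 <- select_clustering(hyps, 50, 3)
  s2 <- select_clustering(rev(hyps), 50, 3)
  expect_equal(s1$location, s2$location)
})

test_that("refinement leaves 3-constraint consensus sets unchanged and
           improves larger noisy ones", {
  set.seed(46)
  tp <- toy_problem(n_receivers = 3, noise = FALSE)
  dc <- make_diff_constraints(tp$tag_detset, tp$beacon_detsets[[1]],
                              tp$receivers)
  h <- list(location = tp$tag, d = tp$d_true[1], beacon_id = "b",
            triplet = dc$receiver_id, kind = "closed_form")
  out <- refine_single_beacon(list(hypothesis = h, inliers = dc))
  expect_identical(out, h)

  # noise-free 6-constraint set: refinement reproduces the truth
  tp6 <- toy_problem(n_receivers = 6, noise = FALSE)
  dc6 <- make_diff_constraints(tp6$tag_detset, tp6$beacon_detsets[[1]],
                               tp6$receivers)
  h6 <- list(location = tp6$tag + c(200, -100, 0),
             d = tp6$d_true[1] + 1e-7, beacon_id = "b",
             triplet = NULL, kind = "closed_form")
  ref <- refine_single_beacon(list(hypothesis = h6, inliers = dc6),
                              fixed_altitude = tp6$tag[3])
  expect_equal(ref$kind, "refined")
  expect_lt(d3(ref$location[1:2], tp6$tag[1:2]), 1e-6)

})

test_that("refinement lowers the RMSE over many noisy problems", {
  set.seed(146)
  err_h <- err_r <- numeric(300)
  for (k in 1:300) {
    tpn <- toy_problem(n_receivers = 6, sigma = 1e-8, noise = TRUE)
    dcn <- make_diff_constraints(tpn$tag_detset, tpn$beacon_detsets[[1]],
                                 tpn$receivers)
    ranked <- rank_beacon_detsets(tpn$tag_detset, tpn$beacon_detsets)
    hyps <- generate_hypotheses(tpn$tag_detset, ranked, tpn$receivers,
                                fixed_altitude = tpn$tag[3])
    cons <- attr(hyps, "constraints_by_beacon")
    res <- select_consensus(hyps, cons)
    ref <- refine_single_beacon(res, fixed_altitude = tpn$tag[3])
    err_h[k] <- d3(res$hypothesis$location[1:2], tpn$tag[1:2])
    err_r[k] <- d3(ref$location[1:2], tpn$tag[1:2])
  }
  expect_lte(sqrt(mean(err_r^2)), sqrt(mean(err_h^2)))
})

test_that("the ultimate set unions raw constraints without duplicates", {
  set.seed(47)
  tp <- toy_problem(n_receivers = 6, n_beacons = 2, noise = FALSE)
  ranked <- rank_beacon_detsets(tp$tag_detset, tp$beacon_detsets)
  hyps <- generate_hypotheses(tp$tag_detset, ranked, tp$receivers,
                              fixed_altitude = tp$tag[3])
  cons <- attr(hyps, "constraints_by_beacon")
  res <- select_consensus(hyps, cons)
  best <- refine_single_beacon(res, fixed_altitude = tp$tag[3])
  sel_m <- assemble_ultimate(tp$problem, best, cons, mode = "multi")
  # the same receiver under two beacons contributes the tag constraint once
  expect_false(anyDuplicated(sel_m$tag_receivers) > 0)
  expect_false(anyDuplicated(paste(sel_m$beacon_pairs$beacon_id,
                                   sel_m$beacon_pairs$receiver_id)) > 0)
  expect_setequal(sel_m$tag_receivers, tp$receivers$id)
  expect_equal(nrow(sel_m$beacon_pairs), 12)  # 6 receivers x 2 beacons
  sel_s <- assemble_ultimate(tp$problem, best, cons, mode = "single")
  expect_equal(length(unique(sel_s$beacon_pairs$beacon_id)), 1L)
})

test_that("the ultimate set excludes exactly the corrupted receivers", {
  set.seed(48)
  hit <- 0
  for (k in 1:15) {
    tp <- toy_problem(n_receivers = 6, n_beacons = 2, sigma = 3e-9,
                      outliers = c("R02", "R05"), outlier_delay = 6e-6)
    ranked <- rank_beacon_detsets(tp$tag_detset, tp$beacon_detsets)
    hyps <- generate_hypotheses(tp$tag_detset, ranked, tp$receivers, 0)
    cons <- attr(hyps, "constraints_by_beacon")
    res <- select_consensus(hyps, cons)
    best <- refine_single_beacon(res, fixed_altitude = 0)
    sel <- try(assemble_ultimate(tp$problem, best, cons, mode = "multi"),
               silent = TRUE)
    if (inherits(sel, "try-error")) next
    if (setequal(setdiff(tp$receivers$id, sel$tag_receivers),
                 c("R02", "R05"))) hit <- hit + 1
  }
  expect_gte(hit, 12)
})
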