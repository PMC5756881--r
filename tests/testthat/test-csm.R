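test_that("pairing enumeration has the documented combinatorics", {
  # L = 4, at-point-0 pairing: {(0,0), (1,3), (2,2)}
  prs <- enumerate_pairings(4)
  expect_length(prs, 4)
  at0 <- prs[[3]]   # first at-point pairing
  expect_identical(attr(at0, "start"), "at point 0")
  key <- function(p) paste(sort(paste(pmin(p[, 1], p[, 2]),
                                      pmax(p[, 1], p[, 2]))), collapse = ";")
  expect_identical(key(at0), key(rbind(c(0, 0), c(1, 3), c(2, 2))))

  # every pairing for L = 6 is a partition of the indices
  for (p in enumerate_pairings(6)) {
    expect_setequal(unique(c(p[, 1], p[, 2])), 0:5)
    counts <- table(c(p[p[, 1] != p[, 2], ], p[p[, 1] == p[, 2], 1]))
    expect_true(all(counts == 1))
  }

  # L = 200: 200 distinct pairings, 100 of size 100 and 100 of size 101
  prs200 <- enumerate_pairings(200)
  expect_length(prs200, 200)
  sizes <- vapply(prs200, nrow, integer(1))
  expect_equal(sum(sizes == 100), 100)
  expect_equal(sum(sizes == 101), 100)
  keys <- vapply(prs200, key, character(1))
  expect_false(any(duplicated(keys)))

  expect_error(enumerate_pairings(5), "even")
})

test_that("pairing enumeration matches the literal walk-and-pair oracle", {
  for (L in c(4, 6, 8, 12)) {
    key <- function(p) paste(sort(paste(pmin(p[, 1], p[, 2]),
                                        pmax(p[, 1], p[, 2]))), collapse = ";")
    got <- sort(vapply(enumerate_pairings(L), key, character(1)))
    want <- sort(vapply(oracle_pairings(L), key, character(1)))
    expect_identical(got, want, info = paste("L =", L))
  }
})

test_that("the analytic optimal axis attains the dense-grid minimum", {
  for (seed in 1:25) {
    poly <- random_polygon(8, seed = seed)
    norm <- normalize_outline(poly)
    for (p in enumerate_pairings(8)[c(1, 3, 5, 8)]) {
      ax <- optimal_axis(norm, p)
      P <- cbind(norm$x, norm$y)
      th <- seq(0, pi, length.out = 3601)[-3601]
      grid_min <- min(oracle_msd(P, p, th))
      expect_lte(ax$objective, grid_min + 1e-8)
      # and the reported objective equals the explicit fold-average cost
      expect_equal(ax$objective, oracle_msd(P, p, ax$angle), tolerance = 1e-10)
    }
  }
})

test_that("optimal axis recovers the true mirror axis of a symmetric polygon", {
  # symmetric hexagon about the x-axis; at-point-0 pairing matches the symmetry
  hexa <- tibble::tibble(
    x = c(1.3, 0.5, -0.6, -1.0, -0.6, 0.5),
    y = c(0, 0.8, 0.7, 0, -0.7, -0.8))
  norm <- normalize_outline(hexa)
  p <- enumerate_pairings(6)[[4]]   # at point 0
  ax <- optimal_axis(norm, p)
  expect_equal(ax$objective, 0, tolerance = 1e-12)
  expect_true(min(ax$angle, pi - ax$angle) < 1e-8)

  # rotating the polygon rotates the optimal axis, objective unchanged
  rot <- rotate_outline(norm, 0.7)
  ax2 <- optimal_axis(normalize_outline(rot), p)
  expect_equal(ax2$objective, ax$objective, tolerance = 1e-12)
  expect_equal((ax2$angle - ax$angle) %% pi, 0.7, tolerance = 1e-9)
})

test_that("the symmetry transform folds pairs as specified", {
  # worked pair: p_i = (1, 1), p_j = (0.6, -1), axis = x-axis
  pts <- tibble::tibble(x = c(1, 0.6), y = c(1, -1))
  pairing <- cbind(i = 0L, j = 1L)
  tr <- symmetry_transform(pts, pairing, list(angle = 0))
  expect_equal(tr$x, c(0.8, 0.8), tolerance = 1e-12)
  expect_equal(tr$y, c(1, -1), tolerance = 1e-12)
  expect_equal(msd_between(pts, tr), 0.04, tolerance = 1e-12)

  # already-symmetric pair is a fixed point
  pts2 <- tibble::tibble(x = c(1, 1), y = c(1, -1))
  tr2 <- symmetry_transform(pts2, pairing, list(angle = 0))
  expect_equal(tr2$x, pts2$x, tolerance = 1e-12)
  expect_equal(tr2$y, pts2$y, tolerance = 1e-12)
})

test_that("the symmetry transform is mirror-symmetric and reflection-order-free", {
  for (seed in 1:10) {
    poly <- random_polygon(8, seed = 100 + seed)
    norm <- normalize_outline(poly)
    for (p in enumerate_pairings(8)[c(2, 7)]) {
      ax <- optimal_axis(norm, p)
      tr <- symmetry_transform(norm, p, ax)
      # reflecting the transform across its axis permutes the point set
      P <- cbind(tr$x, tr$y)
      R <- frondsym:::reflect_points(P, ax$angle)
      key <- function(m) sort(paste(round(m[, 1], 9), round(m[, 2], 9)))
      expect_identical(key(R), key(P))
      # swapping which pair member is "reflected first" changes nothing
      p_sw <- p[, c(2, 1)]
      colnames(p_sw) <- c("i", "j")
      tr_sw <- symmetry_transform(norm, p_sw, ax)
      expect_equal(tr$x, tr_sw$x, tolerance = 1e-12)
      expect_equal(tr$y, tr_sw$y, tolerance = 1e-12)
    }
  }
})

test_that("CSM is zero for exactly mirror-symmetric outlines", {
  # ellipse built from a mirrored half: symmetric to the bit
  m <- 100
  t_up <- seq(0, pi, length.out = m + 1)
  x_up <- 2 * cos(t_up); y_up <- sin(t_up)
  ell <- tibble::tibble(x = c(x_up, x_up[m:2]), y = c(y_up, -y_up[m:2]))
  expect_equal(nrow(ell), 200)
  expect_lt(csm(ell)$csm, 1e-10)
  expect_lt(csm_forced(ell)$csm, 1e-10)
})

test_that("CSM equals the exhaustive brute-force oracle", {
  # displaced-corner square, L = 8 (corners + edge midpoints)
  sq <- tibble::tibble(
    x = c(1, 0, -1, -1, -1, 0, 1, 1) + c(0.1, 0, 0, 0, 0, 0, 0, 0),
    y = c(1, 1, 1, 0, -1, -1, -1, 0) + c(0.1, 0, 0, 0, 0, 0, 0, 0))
  got <- csm(sq)$csm
  expect_gt(got, 0)
  expect_equal(got, oracle_csm(sq), tolerance = 1e-7)

  # a handful of random polygons across sizes (the full sweep runs in the
  # acceptance suite)
  for (L in c(4, 6, 12)) {
    for (seed in 1:3) {
      poly <- random_polygon(L, seed = 1000 * L + seed)
      expect_equal(csm(poly)$csm, oracle_csm(poly), tolerance = 1e-7,
                   info = paste("L", L, "seed", seed))
    }
  }
})

test_that("CSM is invariant to rotation and translation", {
  poly <- random_polygon(12, seed = 42)
  base <- csm(poly)$csm
  for (phi in c(0.3, 1.1, 2.9)) {
    rot <- rotate_outline(poly, phi)
    shifted <- tibble::tibble(x = rot$x + 3.7, y = rot$y - 1.2)
    expect_equal(csm(shifted)$csm, base, tolerance = 1e-9)
  }
})

test_that("CSM_forced dominates CSM and matches its restricted oracle", {
  # forced >= free on random polygons; both nonnegative
  for (seed in 1:30) {
    poly <- random_polygon(8, seed = 2000 + seed)
    v <- csm(poly)$csm
    vf <- csm_forced(poly)$csm
    expect_gte(v, 0)
    expect_gte(vf, v - 1e-12)
  }

  # symmetric egg: tip on the axis is the farthest point, forced == free == 0
  egg <- make_outline(asymmetry = 0, n_points = 60)
  expect_lt(csm(egg)$csm, 1e-10)
  expect_lt(csm_forced(egg)$csm, 1e-10)

  # bent outline whose best axis misses the farthest point: forced > free,
  # both matching the brute-force oracle
  bent <- make_outline(asymmetry = 0.18, n_points = 12)
  v <- csm(bent)$csm
  vf <- csm_forced(bent)$csm
  expect_equal(v, oracle_csm(bent), tolerance = 1e-7)
  expect_equal(vf, oracle_csm_forced(bent), tolerance = 1e-7)
  expect_gte(vf, v)
})

test_that("csm_result exposes tidy() and autoplot()", {
  res <- csm(make_outline(asymmetry = 0.1, n_points = 20))
  td <- tidy(res)
  expect_named(td, c("measure", "value", "axis_angle", "n_points"))
  expect_equal(td$value, res$csm)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
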