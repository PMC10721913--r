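test_that("tfce handles degenerate maps and closed forms", {
  expect_equal(tfce(rep(0, 10)), rep(0, 10))
  # isolated point of height v: sum_h 1^E h^H dh ~ v^(H+1)/(H+1) as dh -> 0
  v <- 0.8
  x <- c(rep(0, 5), v, rep(0, 5))
  got <- tfce(x, e_power = 0.5, h_power = 2, dh = v / 100)[6]
  expect_lt(abs(got - v^3 / 3) / (v^3 / 3), 0.02)
  # constant map of height c over n points: every point gets the same
  # value, equal to the explicit sum over the matching height grid
  cc <- 0.4; n <- 7
  dh <- cc / 100
  expected <- sum(n^0.5 * ((1:100) * dh)^2 * dh)
  out <- tfce(rep(cc, n), dh = dh)
  expect_equal(out, rep(expected, n), tolerance = 1e-12)
  # signed maps: negative part mirrors the positive part
  xs <- c(0.5, 0, -0.5)
  ts <- tfce(xs, dh = 0.005)
  expect_equal(ts[1], -ts[3])
  expect_error(tfce(c(1, NA)), "non-finite")
})

test_that("tfce matches the brute-force oracle on random maps", {
  for (seed in 1:12) {
    set.seed(seed)
    x <- rnorm(30) * 0.1
    dh <- max(abs(x)) / 100
    expect_equal(tfce(x, dh = dh), tfce_oracle(x, dh = dh), tolerance = 1e-9)
  }
  # 2-D grids with 4-neighbour connectivity
  for (seed in 1:5) {
    set.seed(100 + seed)
    x <- matrix(rnorm(56) * 0.1, 8, 7)
    dh <- max(abs(x)) / 50
    expect_equal(tfce(x, dh = dh), tfce_oracle(x, dh = dh), tolerance = 1e-9)
  }
})

test_that("tfce is pointwise monotone in input height on fixed support", {
  set.seed(5)
  x <- abs(rnorm(25)) * 0.1
  dh <- max(x) / 100
  t1 <- tfce(x, dh = dh)
  t2 <- tfce(x * 1.5, dh = dh)
  expect_true(all(t2 - t1 >= -1e-12))
})

test_that("rank-based z maps reproduce the permutation ceiling", {
  set.seed(3)
  null_max <- abs(rnorm(100))
  null_min <- -abs(rnorm(100))
  # observed above every null max -> z = 2.33 at 2 decimals (qnorm(100/101))
  z_top <- z_from_null(max(null_max) + 1, null_max, null_min)
  expect_equal(round(z_top, 2), 2.33)
  expect_equal(z_top, qnorm(100 / 101))
  # observed inside both nulls -> no evidence in either tail
  mid <- z_from_null(0, null_max, null_min)
  expect_lte(mid, 0)
  expect_equal(mid, 0)
  # extreme negative -> -2.33
  expect_equal(round(z_from_null(min(null_min) - 1, null_max, null_min), 2),
               -2.33)
  # monotone: larger observed TFCE never yields smaller z
  obs <- sort(rnorm(50, sd = 2))
  zz <- z_from_null(obs, null_max, null_min)
  expect_true(all(diff(zz) >= 0))
})

test_that("max-statistic masks control false positives on null maps", {
  set.seed(11)
  hits <- vapply(1:200, function(i) {
    null_maps <- matrix(rnorm(50 * 20, sd = 0.02), 50, 20)
    obs <- rnorm(20, sd = 0.02)
    nm <- apply(null_maps, 1, function(v) max(tfce(v, dh = 0.001)))
    nn <- apply(null_maps, 1, function(v) min(tfce(v, dh = 0.001)))
    z <- z_from_null(tfce(obs, dh = 0.001), nm, nn)
    any(abs(z) > 1.96)
  }, logical(1))
  expect_lt(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("clusters are maximal contiguous runs split by sign", {
  z <- c(0, 2.3, 2.3, 0, 2.3)
  cl <- extract_clusters(z, z_crit = 1.96)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$onset, c(2, 5))
  expect_equal(cl$offset, c(3, 5))
  expect_equal(cl$n_points, c(2L, 1L))
  expect_equal(nrow(extract_clusters(rep(0, 5))), 0)
  # sign split: adjacent positive and negative excursions are two clusters
  z2 <- c(2.5, 2.5, -2.5, -2.5)
  cl2 <- extract_clusters(z2)
  expect_equal(nrow(cl2), 2)
  expect_equal(cl2$sign, c(1, -1))
  # 2-D: 4-connected components, diagonal adjacency excluded
  zm <- matrix(0, 4, 4)
  zm[1, 1] <- 3; zm[2, 2] <- 3 # diagonal neighbours -> separate clusters
  zm[4, 3] <- 3; zm[4, 4] <- 3 # edge neighbours -> one cluster
  clm <- extract_clusters(zm, times = (1:4) * 10)
  expect_equal(nrow(clm), 3)
  # peak reporting carries the underlying accuracy
  acc <- c(0.5, 0.62, 0.55, 0.5, 0.5)
  zp <- c(0, 2.33, 2.0, 0, 0)
  clp <- extract_clusters(zp, times = c(100, 148, 152, 200, 204),
                          accuracy = acc)
  expect_equal(clp$peak_time, 148)
  expect_equal(clp$peak_z, 2.33)
  expect_equal(clp$peak_accuracy, 0.62)
})

test_that("averaging z-maps recomputes the mask on the mean", {
  z1 <- c(0, 2.5, 0)
  z2 <- c(0, 2.5, 2.5)
  avg <- average_zmaps(list(z1, z2), times = 1:3)
  expect_equal(avg$z, c(0, 2.5, 1.25))
  expect_equal(avg$mask, c(FALSE, TRUE, FALSE))
  one <- average_zmaps(list(z1), times = 1:3)
  expect_equal(one$z, z1)
  same <- average_zmaps(list(z2, z2, z2), times = 1:3)
  expect_equal(same$z, z2)
})

test_that("permutation_null records extrema of TFCE-transformed maps", {
  maps <- list(c(0, 0.3, 0), c(0, 0, -0.4), c(0.1, 0, 0))
  null <- permutation_null(function(i) maps[[i]], n_perm = 3, dh = 0.01)
  expect_length(null$max, 3)
  for (i in 1:3) {
    tf <- tfce(maps[[i]], dh = 0.01)
    expect_equal(null$max[i], max(tf))
    expect_equal(null$min[i], min(tf))
  }
})

test_that("the paired test is antisymmetric under swapping with shared seeds", {
  set.seed(21)
  times <- (0:19) * 4
  mk <- function(shift) {
    sa <- array(0.5 + rnorm(6 * 20 * 2, sd = 0.03), c(6, 20, 2))
    sa[, 8:12, ] <- sa[, 8:12, ] + shift
    list(subject_acc = sa, times = times)
  }
  a <- mk(0.15); b <- mk(0)
  ab <- paired_accuracy_test(a, b, n_perm = 40, seed = 9)
  ba <- paired_accuracy_test(b, a, n_perm = 40, seed = 9)
  expect_equal(ab$z, -ba$z)
  # the injected difference is detected with positive sign
  expect_true(any(ab$mask[8:12] & ab$z[8:12] > 0))
  expect_false(any(ab$mask & ab$z < 0))
})

test_that("the paired test stays null for exchangeable inputs", {
  set.seed(31)
  times <- (0:14) * 4
  hits <- vapply(1:30, function(i) {
    mk <- function() list(
      subject_acc = array(0.5 + rnorm(6 * 15, sd = 0.05), c(6, 15, 1)),
      times = times)
    res <- paired_accuracy_test(mk(), mk(), n_perm = 50, seed = i)
    any(res$mask)
  }, logical(1))
  expect_lt(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 30) + 0.05)
})
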