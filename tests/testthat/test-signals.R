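# Parcel extraction, cleaning, and connectome generation.

test_that("label extraction averages voxels and matches a voxel-loop oracle", {
  atlas <- tiny_atlas(c(6, 6, 6), 3)
  set.seed(8)
  img <- array(rnorm(6 * 6 * 6 * 10), dim = c(6, 6, 6, 10))

  # constant image -> constant series
  const <- array(5.0, dim = c(6, 6, 6, 4))
  ts_const <- extract_labels(const, atlas)
  expect_true(all(ts_const$series == 5.0))

  ts <- extract_labels(img, atlas)
  # independent per-voxel loop
  for (k in 1:3) {
    vox <- which(atlas$data == k)
    for (t in c(1, 5, 10)) {
      vol <- img[, , , t]
      expect_equal(unname(ts$series[t, k]), mean(vol[vox]),
                   tolerance = 1e-12)
    }
  }
})

test_that("label extraction is linear and flags grid mismatches", {
  lab <- array(0L, dim = c(4, 4, 4))
  lab[1:2, , ] <- 1L
  lab[3:4, , ] <- 2L
  atlas <- fc_atlas(lab, diag(4), data.frame(index = 1:2,
                                             name = c("a", "b")))
  base <- sin(seq_len(8))
  img <- array(0, dim = c(4, 4, 4, 8))
  for (t in 1:8) {
    img[1:2, , , t] <- base[t]
    img[3:4, , , t] <- 2 * base[t]
  }
  ts <- extract_labels(img, atlas)
  expect_equal(ts$series[, 2], 2 * ts$series[, 1], tolerance = 1e-12)

  expect_error(extract_labels(array(0, c(5, 4, 4, 3)), atlas),
               "does not match atlas grid")
})

test_that("empty parcels yield zero series with a warning, ids retained", {
  lab <- array(1L, dim = c(3, 3, 3))
  atlas <- fc_atlas(lab, diag(4),
                    data.frame(index = 1:2, name = c("a", "missing")))
  img <- array(rnorm(27 * 5), dim = c(3, 3, 3, 5))
  expect_warning(ts <- extract_labels(img, atlas), "empty parcels")
  expect_equal(ncol(ts$series), 2)
  expect_true(all(ts$series[, 2] == 0))
})

test_that("maps extraction solves least squares, matching the oracle", {
  dims <- c(5, 5, 5)
  set.seed(11)
  p <- 4
  maps <- array(abs(rnorm(prod(dims) * p)), dim = c(dims, p))
  atlas <- fc_atlas(maps, diag(4),
                    data.frame(index = 1:p, name = paste0("m", 1:p)),
                    kind = "maps")
  n_t <- 7
  img <- array(rnorm(prod(dims) * n_t), dim = c(dims, n_t))
  ts <- extract_maps(img, atlas)
  # normal-equations oracle
  M <- matrix(as.vector(maps), prod(dims), p)
  V <- matrix(as.vector(img), prod(dims), n_t)
  oracle <- t(solve(t(M) %*% M, t(M) %*% V))
  expect_equal(unname(ts$series), unname(oracle), tolerance = 1e-10)

  # exact generative model: image = 3.0 x map_2 time course
  tc <- cos(seq_len(n_t))
  img2 <- array(0, dim = c(dims, n_t))
  for (t in seq_len(n_t)) img2[, , , t] <- 3.0 * tc[t] * maps[, , , 2]
  ts2 <- extract_maps(img2, atlas)
  expect_equal(ts2$series[, 2], 3.0 * tc, tolerance = 1e-10)
  expect_lt(max(abs(ts2$series[, -2])), 1e-10)
})

test_that("indicator maps reproduce label-mean extraction", {
  atlas_l <- tiny_atlas(c(4, 4, 4), 2, seed = 3)
  p <- 2
  maps <- array(0, dim = c(4, 4, 4, p))
  for (k in 1:p) maps[, , , k][atlas_l$data == k] <- 1
  atlas_m <- fc_atlas(maps, diag(4),
                      data.frame(index = 1:p, name = c("a", "b")),
                      kind = "maps")
  img <- array(rnorm(64 * 6), dim = c(4, 4, 4, 6))
  expect_equal(unname(extract_maps(img, atlas_m)$series),
               unname(extract_labels(img, atlas_l)$series),
               tolerance = 1e-10)
})

test_that("rank-deficient maps raise an error naming collinear maps", {
  maps <- array(0, dim = c(3, 3, 3, 2))
  maps[, , , 1] <- 1
  maps[, , , 2] <- 2  # collinear with map 1
  atlas <- fc_atlas(maps, diag(4), data.frame(index = 1:2,
                                              name = c("a", "b")),
                    kind = "maps")
  img <- array(rnorm(27 * 4), dim = c(3, 3, 3, 4))
  expect_error(extract_maps(img, atlas), "rank-deficient")
})

test_that("cleaning equals the explicit projection-matrix oracle", {
  set.seed(21)
  n <- 40; p <- 6; q <- 5
  ts <- rand_ts(n, p, seed = 21)
  X <- matrix(rnorm(n * q), n, q)
  sel <- fcbench:::new_selection(
    matrix(X, n, q, dimnames = list(NULL, paste0("c", 1:q))),
    stats::setNames(q, "motion"))
  kept <- sort(sample(n, 32))
  mask <- sample_mask(kept, n)
  out <- clean_timeseries(ts, sel, mask)
  # hat-matrix oracle on the censored rows
  Xk <- cbind(1, X[kept, ])
  H <- Xk %*% solve(t(Xk) %*% Xk) %*% t(Xk)
  oracle <- (diag(length(kept)) - H) %*% ts$series[kept, ]
  expect_lt(max(abs(out$series - oracle)), 1e-10)
})

test_that("cleaning is idempotent and kills a perfectly-known confound", {
  ts <- rand_ts(30, 4, seed = 2)
  X <- matrix(ts$series[, 2], 30, 1, dimnames = list(NULL, "copy"))
  sel <- fcbench:::new_selection(X, stats::setNames(1L, "tissue"))
  out <- clean_timeseries(ts, sel, NULL)
  expect_lt(max(abs(out$series[, 2])), 1e-10)
  again <- clean_timeseries(out, sel, NULL)
  expect_lt(max(abs(again$series - out$series)), 1e-8)
})

test_that("empty selection with demeaning returns the demeaned input", {
  ts <- rand_ts(25, 3, seed = 4)
  out <- clean_timeseries(ts, NULL, NULL)
  centred <- sweep(ts$series, 2, colMeans(ts$series))
  expect_equal(unname(out$series), unname(centred), tolerance = 1e-12)
})

test_that("volumes are censored before regression", {
  # a huge spike confined to censored volumes must leave the retained
  # cleaned series identical to the spike-free run
  n <- 30
  ts0 <- rand_ts(n, 4, seed = 6)
  spiked <- ts0
  spiked$series[10, ] <- spiked$series[10, ] + 1e6
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  sel <- fcbench:::new_selection(X, stats::setNames(2L, "motion"))
  mask <- sample_mask(setdiff(1:n, 10), n)
  c0 <- clean_timeseries(ts0, sel, mask)
  c1 <- clean_timeseries(spiked, sel, mask)
  expect_lt(max(abs(c0$series - c1$series)), 1e-10)
})

test_that("degrees-of-freedom exhaustion raises an error", {
  ts <- rand_ts(10, 3, seed = 9)
  X <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(NULL, paste0("x", 1:12)))
  sel <- fcbench:::new_selection(X, stats::setNames(12L, "motion"))
  expect_error(clean_timeseries(ts, sel, NULL), "degrees of freedom")
})

test_that("connectome invariants hold on random fixtures", {
  for (seed in 1:5) {
    ts <- rand_ts(25, 6, seed = seed)
    conn <- pearson_connectome(ts)
    m <- conn$matrix
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_equal(unname(diag(m)), rep(1, 6))
    expect_true(all(abs(m) <= 1 + 1e-12))
  }
})

test_that("perfectly (anti)correlated parcels give unit edges", {
  base <- sin(seq_len(20))
  ts <- parcel_timeseries(cbind(base, base, -base), 1:3)
  m <- pearson_connectome(ts)$matrix
  expect_equal(m[2, 1], 1, tolerance = 1e-12)
  expect_equal(m[3, 1], -1, tolerance = 1e-12)
})

test_that("zero-variance parcels produce NA edges with a warning", {
  ts <- parcel_timeseries(cbind(rnorm(10), rep(2, 10)), 1:2)
  expect_warning(conn <- pearson_connectome(ts), "zero-variance")
  expect_true(is.na(conn$matrix[2, 1]))
  expect_equal(diag(conn$matrix), c(`1` = 1, `2` = 1), ignore_attr = TRUE)
})

test_that("edge vectorization follows row-major lower-triangle order", {
  p <- 5
  m <- matrix(0, p, p)
  # index-pair enumeration oracle
  expected <- c()
  val <- function(i, j) i * 10 + j
  for (i in 2:p) for (j in 1:(i - 1)) {
    m[i, j] <- m[j, i] <- val(i, j)
    expected <- c(expected, val(i, j))
  }
  expect_equal(vectorize_connectome(m), expected)
  expect_length(vectorize_connectome(m), p * (p - 1) / 2)
})

test_that("centers of mass push voxels through the affine", {
  lab <- array(0L, dim = c(5, 5, 5))
  lab[3, 4, 5] <- 1L   # 0-based voxel (2, 3, 4)
  lab[1, 1, 1] <- 2L
  lab[3, 1, 1] <- 2L   # parcel 2: voxels (0,0,0) and (2,0,0)
  atlas <- fc_atlas(lab, diag(4), data.frame(index = 1:2,
                                             name = c("a", "b")))
  geom <- centers_of_mass(atlas)
  expect_equal(unname(geom$centers["1", ]), c(2, 3, 4))
  expect_equal(unname(geom$centers["2", ]), c(1, 0, 0))

  # 2 mm voxels: transform each voxel, then average
  aff <- diag(c(2, 2, 2, 1))
  atlas2 <- fc_atlas(lab, aff, atlas$lookup)
  geom2 <- centers_of_mass(atlas2)
  expect_equal(unname(geom2$centers["2", ]), c(2, 0, 0))
  expect_equal(unname(geom2$centers["1", ]), c(4, 6, 8))

  d <- geom$distance
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 2))
})

test_that("distance matrix satisfies the triangle inequality", {
  atlas <- tiny_atlas(c(6, 6, 6), 3)
  d <- centers_of_mass(atlas)$distance
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})
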