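# Shape-complexity mathematics: standardized pair differences, scaled
# distances, SC = g*h, the analytic gradient, and the identities that tie
# them together.

test_that("standardized squared pair differences match the defining formula", {
  # two samples, two equal columns: sd per column is 1/sqrt(2), so each
  # standardized squared difference is (1 / (1/sqrt(2)))^2 = 2
  d <- sc_data(rbind(c(0, 0), c(1, 1)))
  rho2 <- standardized_sq_diffs(d)
  expect_equal(dim(rho2), c(1L, 2L))
  expect_equal(as.vector(rho2), c(2, 2))

  # direct formula on random data
  X <- rand_data(7, 3, seed = 101)
  d <- sc_data(X)
  rho2 <- standardized_sq_diffs(d)
  k <- 1L
  row <- 0L
  for (j in 1:6) for (i in (j + 1):7) {
    row <- row + 1L
    expect_equal(rho2[row, k], ((X[j, k] - X[i, k]) / d$sigma[k])^2)
  }
  expect_true(all(rho2 >= 0))
})

test_that("pair sums of rho2 equal N on duplicate-free data", {
  for (seed in 1:5) {
    X <- rand_data(12, 4, seed)
    d <- sc_data(X)
    expect_identical(d$n, d$n_orig)
    rho2 <- standardized_sq_diffs(d)
    expect_equal(colSums(rho2), rep(d$N, 4), tolerance = 1e-10)
  }
})

test_that("constant columns are rejected with the dimension named", {
  X <- cbind(rnorm(5), rep(2, 5), rnorm(5))
  expect_error(sc_data(X), "2")
  expect_error(standardized_sq_diffs(X), "constant")
})

test_that("pair distances: unit alpha gives standardized Euclidean, scaling is homogeneous", {
  X <- rand_data(9, 3, seed = 7)
  d <- sc_data(X)
  rho2 <- standardized_sq_diffs(d)
  r1 <- pair_distances(rho2, rep(1, 3))
  expect_equal(r1, as.vector(dist(sweep(X, 2, d$sigma, "/"))))
  expect_equal(pair_distances(rho2, rep(2, 3)), 2 * r1)
  a <- c(0.3, 1.4, 2.2)
  expect_equal(pair_distances(rho2, 3 * a), 3 * pair_distances(rho2, a))
})

test_that("zero pair distances are caught with advice to deduplicate", {
  bad <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  bad[3, ] <- bad[1, ]  # cannot happen through sc_data; force via raw rho2
  rho2 <- structure(rbind(c(0, 0), c(1, 1), c(1, 1)), N = 6)
  expect_error(pair_distances(rho2, c(1, 1)), "duplicate")
})

test_that("shape complexity: single pair gives exactly 1; three-point oracle", {
  # n = 2: one pair of any positive distance r has SC = r * (1/r) = 1
  for (seed in 1:3) {
    X <- rand_data(2, 3, seed)
    expect_equal(shape_complexity(sc_data(X), runif(3, 0.2, 5))$sc, 1)
  }
  # pair distances {1, 1, 2}: g = sqrt(6), h = 2.5, SC = 2.5 sqrt(6)
  rho2 <- structure(rbind(c(0.5, 0.5), c(0.5, 0.5), c(2, 2)), N = 6)
  out <- shape_complexity(rho2, c(1, 1))
  expect_equal(out$g, sqrt(6))
  expect_equal(out$h, 2.5)
  expect_equal(out$sc, 6.123724356957945)
})

test_that("SC is radially invariant", {
  for (seed in 1:100) {
    set.seed(seed)
    X <- matrix(rnorm(6 * 3), 6, 3)
    rho2 <- standardized_sq_diffs(sc_data(X))
    a <- runif(3, 0.1, 4)
    t <- sample(c(0.1, 3.7, 10, runif(1, 0.01, 50)), 1)
    s1 <- shape_complexity(rho2, a)$sc
    s2 <- shape_complexity(rho2, t * a)$sc
    expect_lt(abs(s2 - s1) / s1, 1e-9)
  }
})

test_that("gradient satisfies the zero directional derivative along alpha", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(8 * 4), 8, 4)
    rho2 <- standardized_sq_diffs(sc_data(X))
    a <- runif(4, 0.2, 3)
    g <- sc_gradient(rho2, a)
    expect_lt(abs(sum(a * g$grad)), 1e-8 * abs(g$sc))
  }
})

test_that("analytic gradient agrees with central finite differences", {
  for (seed in 1:10) {
    X <- rand_data(5, 3, seed)
    rho2 <- standardized_sq_diffs(sc_data(X))
    a <- runif(3, 0.5, 2)
    an <- sc_gradient(rho2, a)$grad
    fd <- fd_grad(function(v) shape_complexity(rho2, v)$sc, a)
    expect_equal(an, fd, tolerance = 1e-5)
  }
})

test_that("exchangeable columns give equal gradient components", {
  set.seed(33)
  col <- rnorm(8)
  X <- cbind(col, rev(col))  # column 2 a permutation of column 1
  g <- sc_gradient(sc_data(X), c(1, 1))
  expect_equal(g$grad[1], g$grad[2], tolerance = 1e-12)
})

test_that("increasing one pair distance raises g and lowers h", {
  set.seed(5)
  X <- matrix(rnorm(7 * 3), 7, 3)
  rho2 <- standardized_sq_diffs(sc_data(X))
  a <- rep(1, 3)
  base <- shape_complexity(rho2, a)
  for (p in c(1, 5, nrow(rho2))) {
    bumped <- rho2
    bumped[p, ] <- bumped[p, ] * 1.2  # raises r_p only
    out <- shape_complexity(structure(bumped, N = attr(rho2, "N")), a)
    expect_gt(out$g, base$g)
    expect_lt(out$h, base$h)
  }
})

test_that("closed form for g matches the direct sum on duplicate-free data", {
  for (seed in 1:5) {
    X <- rand_data(20, 4, seed)
    d <- sc_data(X)
    a <- runif(4, 0.2, 3)
    expect_equal(g_closed_form(d, a), shape_complexity(d, a)$g,
                 tolerance = 1e-10)
  }
  # on the sphere (and for all-ones alpha) g = sqrt(N d)
  X <- rand_data(10, 4, seed = 9)
  d <- sc_data(X)
  expect_equal(g_closed_form(d, rep(1, 4)), sqrt(d$N * 4))
  a <- runif(4); a <- a / sqrt(sum(a^2)) * 2
  expect_equal(g_closed_form(d, a), sqrt(d$N * 4))
})

test_that("direct-summation oracle confirms the vectorized SC", {
  X <- rand_data(9, 3, seed = 44)
  a <- c(0.7, 1.3, 2.1)
  brute <- brute_sc_parts(X, a)
  out <- shape_complexity(sc_data(X), a)
  expect_equal(out$g, brute$g, tolerance = 1e-12)
  expect_equal(out$h, brute$h, tolerance = 1e-12)
  expect_equal(out$sc, brute$sc, tolerance = 1e-12)
})
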