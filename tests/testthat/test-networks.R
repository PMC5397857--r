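test_that("Gilbert networks match the binomial edge expectation", {
  n <- 100; eps <- 0.1
  p <- (1 + eps) * log(n) / n
  nPairs <- n * (n - 1) / 2
  nets <- lapply(1:5, function(s) gilbertRandom(n, eps, seed = s))
  edges <- vapply(nets, function(x) sum(adjacency(x)) / 2, numeric(1))
  # mean edge count over 5 realizations within 3 SD of Binomial(nPairs, p)
  se <- sqrt(nPairs * p * (1 - p) / 5)
  expect_lt(abs(mean(edges) - nPairs * p), 3 * se)
  # homogeneous family: pooled degree distribution close to Poisson
  degs <- unlist(lapply(nets, degrees, mode = "binary"))
  expect_gt(var(degs) / mean(degs), 0.6)
  expect_lt(var(degs) / mean(degs), 1.4)
})

test_that("Gilbert generator honours edge probability limits and seeds", {
  expect_error(gilbertRandom(2, epsilon = 5), "exceeds 1")
  # epsilon chosen so p = 1: the single pair must be connected
  epsOne <- 2 / log(2) - 1
  expect_equal(sum(adjacency(gilbertRandom(2, epsOne, seed = 1))) / 2, 1)
  expect_identical(adjacency(gilbertRandom(50, seed = 7)),
                   adjacency(gilbertRandom(50, seed = 7)))
})

test_that("scale-free networks are simple with the prescribed power law", {
  net <- scaleFree(1000, gamma = 2.5, seed = 11)
  A <- adjacency(net)
  expect_true(all(diag(A) == 0))
  expect_identical(A, t(A))
  expect_true(all(A %in% c(0, 1)))
  k <- degrees(net, "binary")
  expect_true(all(k >= 3))
  # structural cutoff sqrt(<k> N)
  expect_lte(max(k), sqrt(mean(k) * 1000) * 1.5)
  # survival function S(k) ~ k^(1 - gamma): log-log slope near -1.5
  # (fit above the structural-cutoff roll-off, i.e. survival >= 0.02)
  ks <- sort(unique(k))
  surv <- vapply(ks, function(x) mean(k >= x), numeric(1))
  sel <- surv >= 0.02
  fit <- lm(log(surv[sel]) ~ log(ks[sel]))
  expect_lt(abs(coef(fit)[2] - (-1.5)), 0.3)
})

test_that("scale-free exponent endpoints are accepted, outside warns", {
  expect_silent(scaleFree(50, gamma = 2, seed = 1))
  expect_silent(scaleFree(50, gamma = 3, seed = 1))
  expect_warning(scaleFree(50, gamma = 1.5, seed = 1), "outside")
})

test_that("degrees follow the row-sum convention", {
  star <- starNetwork(4)
  expect_equal(unname(degrees(star, "binary")), c(4, 1, 1, 1, 1))
  tri <- oscillatorNetwork(0.5 * (matrix(1, 3, 3) - diag(3)))
  expect_equal(unname(degrees(tri, "weighted")), rep(1, 3))
  expect_equal(unname(degrees(tri, "binary")), rep(2, 3))
})

test_that("network validity catches malformed adjacency", {
  expect_error(oscillatorNetwork(matrix(1, 3, 3)), "diagonal")
  expect_error(oscillatorNetwork(rbind(c(0, -1), c(-1, 0))), ">= 0")
  A <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_error(oscillatorNetwork(A, undirected = TRUE), "undirected")
  expect_silent(oscillatorNetwork(A)) # auto-detected as directed
})

test_that("save/load round-trips are lossless in both formats", {
  w <- rbind(c(0, 0.25, 1.75), c(0.25, 0, 3e-4), c(1.75, 3e-4, 0))
  net <- oscillatorNetwork(w, nodeIds = c("a", "b", "c"))
  for (fmt in c("dense", "edgelist")) {
    f <- tempfile(fileext = ".txt")
    saveNetwork(net, f, fmt)
    back <- loadNetwork(f, fmt)
    expect_equal(unname(adjacency(back)), unname(adjacency(net)),
                 tolerance = 0, info = fmt)
  }
})

test_that("edge lists default to unit weights and report bad rows", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\tc"), f)
  net <- loadNetwork(f, "edgelist")
  expect_true(all(adjacency(net)[adjacency(net) != 0] == 1))
  f2 <- tempfile(fileext = ".txt")
  writeLines(c("0 1 2", "1 0 3"), f2) # 2 x 3: not square
  expect_error(loadNetwork(f2, "dense"), "not square")
})

test_that("a 78-row dense matrix loads as a 78-node network", {
  A <- adjacency(gilbertRandom(78, 0.2, seed = 5))
  f <- tempfile(fileext = ".txt")
  saveNetwork(oscillatorNetwork(A), f, "dense")
  expect_equal(nNodes(loadNetwork(f)), 78)
})

test_that("largestComponent keeps the biggest block, order preserved", {
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1 # component {1,2,3}
  A[4, 5] <- A[5, 4] <- 1                       # component {4,5}
  lc <- largestComponent(oscillatorNetwork(A))
  expect_equal(nodeIds(lc), c("n1", "n2", "n3"))
})
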