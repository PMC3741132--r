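# Auto-CM training dynamics, distance conversion, MST, map semantics.

test_that("all-zero input is a fixed point of training", {
  x <- matrix(0, 1, 4)
  m <- train_autocm(x, C = 4)
  init <- 1e-3 * 4
  expect_equal(unname(m$v), rep(init, 4))            # no v update ever
  expect_equal(m$w, matrix(init, 4, 4))              # no w update ever
  expect_true(all(m$trace == 0))
  expect_true(m$converged)
  expect_equal(m$epochs, 1)
})

test_that("training converges and v saturates toward C on random input", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(runif(40 * 35), 40, 35)
    m <- train_autocm(x)
    expect_true(m$converged)
    expect_equal(m$C, 35)
    # contraction saturation for active variables
    expect_true(all(m$v > 0.999 * m$C))
    expect_true(all(m$v <= m$C + 1e-9))
    expect_true(all(m$w >= 0 & m$w <= m$C + 1e-9))
    # the |dv| trace tail decreases to the tolerance
    tail_tr <- tail(m$trace, 5)
    expect_true(all(diff(tail_tr) <= 0))
    expect_lt(tail(m$trace, 1), 1e-6)
  }
})

test_that("input domain and parameters are validated", {
  expect_error(train_autocm(matrix(c(0, 1.5), 1)), "\\[0, 1\\]")
  expect_error(train_autocm(matrix(0.5, 2, 3), C = -1), "C must be")
  expect_error(train_autocm(matrix(0.5, 2, 1)), ">= 2 variables")
})

test_that("an identical column binds most strongly within its row", {
  # duplicated column j of i: converged w[i, j] should top row i
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(runif(20 * 6), 20, 6)
    x[, 2] <- x[, 1]
    m <- train_autocm(x)
    if (all(m$w[1, 2] >= m$w[1, -c(1, 2)])) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("duplicated indicator columns attain the minimal distance", {
  # indicator-style fixtures (the Auto-CM input is predominantly one-hot)
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rbinom(40 * 12, 1, 0.5), 40, 12)
    x[, 2] <- x[, 1]
    colnames(x) <- paste0("V", 1:12)
    m <- train_autocm(x)
    d <- weights_to_distances(m)
    off <- d[upper.tri(d)]
    if (d[1, 2] == min(off)) {
      wins <- wins + 1
      mst <- minimum_spanning_tree(d)
      expect_true(any((mst$from == "V1" & mst$to == "V2") |
                        (mst$from == "V2" & mst$to == "V1")))
    }
  }
  expect_gte(wins, 19)
})

test_that("weight-to-distance conversion follows the formula", {
  fake <- structure(list(w = matrix(c(0, 2, 4, 0), 2, 2), C = 5,
                         variables = c("a", "b")), class = "autocm_model")
  d <- weights_to_distances(fake)
  expect_equal(d[1, 2], 5 - (2 + 4) / 2)   # symmetrized mean
  expect_equal(diag(d), c(a = 0, b = 0))
  # maximal weight -> zero distance; zero weights -> distance C
  sat <- structure(list(w = matrix(5, 2, 2), C = 5, variables = c("a", "b")),
                   class = "autocm_model")
  expect_equal(weights_to_distances(sat)[1, 2], 0)
  zero <- structure(list(w = matrix(0, 3, 3), C = 5,
                         variables = c("a", "b", "c")), class = "autocm_model")
  dz <- weights_to_distances(zero)
  expect_true(all(dz[upper.tri(dz)] == 5))
  # monotone: higher mean weight => strictly smaller distance
  expect_error(weights_to_distances(list(w = 1)), "autocm_model")
})

test_that("MST handles the textbook 3-node case and validates input", {
  d <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  mst <- minimum_spanning_tree(d)
  expect_equal(nrow(mst), 2)
  expect_setequal(paste(mst$from, mst$to), c("A B", "B C"))
  expect_equal(sum(mst$weight), 3)
  bad <- d; bad[1, 2] <- Inf
  expect_error(minimum_spanning_tree(bad), "finite")
  asym <- d; asym[1, 2] <- 0.5
  expect_error(minimum_spanning_tree(asym), "symmetric")
})

test_that("Kruskal equals the exhaustive spanning-tree minimum", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(4:6, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    mst <- minimum_spanning_tree(d)
    expect_equal(nrow(mst), n - 1)
    expect_equal(sum(mst$weight), mst_oracle_weight(d), tolerance = 1e-12)
  }
})

test_that("map normalization, hubs, and permutation equivariance hold", {
  set.seed(10)
  x <- matrix(rbinom(40 * 8, 1, 0.5), 40, 8)
  colnames(x) <- paste0("V", 1:8)
  m <- train_autocm(x)
  map <- build_map(m)
  expect_equal(nrow(map$edges), 7)
  expect_true(all(map$edges$ls >= 0 & map$edges$ls <= 1))
  # strongest pair in the dataset scores ls = 1 when it is an MST edge
  sym <- (m$w + t(m$w)) / 2
  diag(sym) <- -Inf
  top <- which(sym == max(sym), arr.ind = TRUE)[1, ]
  in_mst <- any((map$edges$from == paste0("V", top[1]) &
                   map$edges$to == paste0("V", top[2])) |
                  (map$edges$from == paste0("V", top[2]) &
                     map$edges$to == paste0("V", top[1])))
  if (in_mst) expect_equal(max(map$edges$ls), 1)
  expect_equal(map$hubs, names(map$degree)[map$degree == max(map$degree)])
  # permuting input columns permutes the map: hub set matches under renaming
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  m2 <- train_autocm(x[, perm])
  map2 <- build_map(m2)
  expect_setequal(map2$hubs, map$hubs)
  expect_equal(sort(map2$edges$ls), sort(map$edges$ls), tolerance = 1e-9)
})

test_that("a star topology yields a single central hub", {
  # hand-built distances: V1 close to everyone, others far apart
  n <- 6
  d <- matrix(10, n, n)
  d[1, ] <- d[, 1] <- 1
  diag(d) <- 0
  dimnames(d) <- list(paste0("V", 1:n), paste0("V", 1:n))
  mst <- minimum_spanning_tree(d)
  fake <- structure(list(w = 10 - d, C = 10,
                         variables = paste0("V", 1:n)),
                    class = "autocm_model")
  map <- build_map(fake, distances = d, mst = mst)
  expect_equal(map$hubs, "V1")
  expect_equal(unname(map$degree["V1"]), n - 1)
})

test_that("GraphML export round-trips and DOT is well-formed", {
  set.seed(4)
  x <- matrix(rbinom(30 * 6, 1, 0.5), 30, 6)
  colnames(x) <- c("folate", "folate_LOW", "AD", "control", "g1", "g2")
  map <- build_map(train_autocm(x))
  gml <- tempfile(fileext = ".graphml")
  export_map(map, gml, "graphml")
  back <- import_map_graphml(gml)
  expect_setequal(back$nodes, map$nodes)
  expect_setequal(back$hubs, map$hubs)
  expect_equal(nrow(back$edges), nrow(map$edges))
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  ord1 <- order(key(map$edges)); ord2 <- order(key(back$edges))
  expect_equal(back$edges$ls[ord2], map$edges$ls[ord1], tolerance = 1e-9)
  dot <- tempfile(fileext = ".dot")
  export_map(map, dot, "dot")
  lines <- readLines(dot)
  expect_equal(lines[1], "graph connectivity_map {")
  expect_equal(tail(lines, 1), "}")
  # edge labels carry two-decimal link strengths
  edge_lines <- grep(" -- ", lines, value = TRUE)
  expect_length(edge_lines, nrow(map$edges))
  expect_true(all(grepl('label="[01]\\.[0-9]{2}"', edge_lines)))
  expect_error(export_map(map, tempfile(), "png"), "should be one of|arg")
})
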