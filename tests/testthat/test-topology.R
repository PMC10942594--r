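test_that("placed neurons lie inside their stratum polygon", {
  geo <- slice_geometry()
  counts <- data.frame(area = c("CA1", "DG"), n_exc = c(150, 100),
                       n_inh = c(30, 10))
  lay <- place_neurons(geo, counts, seed = 2, lloyd_iter = 40)
  expect_equal(nrow(lay), 290)
  for (a in counts$area) for (cl in c("exc", "inh")) {
    sub <- lay[lay$area == a & lay$cell == cl, ]
    poly <- geo$regions[[a]][[cl]]
    inside <- points_in_polygon_cpp(sub$x, sub$y, poly$x, poly$y)
    expect_true(all(inside))
  }
  # z-coordinates uniform over the slice thickness
  ks <- suppressWarnings(stats::ks.test(lay$z / geo$z_extent_um, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(lay$z >= 0 & lay$z <= geo$z_extent_um))
})

test_that("Lloyd relaxation monotonically decreases the quantisation energy", {
  set.seed(9)
  poly <- slice_geometry()$regions$CA1$exc
  pts <- poisson_disk_cpp(80, 60, poly$x, poly$y, 100000L)
  samples <- matrix(c(runif(4000, min(poly$x), max(poly$x)),
                      runif(4000, min(poly$y), max(poly$y))), ncol = 2)
  keep <- points_in_polygon_cpp(samples[, 1], samples[, 2], poly$x, poly$y)
  rel <- lloyd_relax_cpp(pts, samples[keep, ], 40, 0)
  expect_true(all(diff(rel$energy) <= 1e-9))
})

test_that("placement is reproducible and fails on impossible densities", {
  counts <- data.frame(area = "CA3", n_exc = 60, n_inh = 10)
  a <- place_neurons(counts = counts, seed = 5, lloyd_iter = 20)
  b <- place_neurons(counts = counts, seed = 5, lloyd_iter = 20)
  expect_identical(a, b)
  expect_error(place_neurons(counts = data.frame(area = "CA3", n_exc = 1e6,
                                                 n_inh = 10), seed = 1),
               "too small")
})

test_that("intra-area wiring follows the distance-decayed Bernoulli rule", {
  n <- 60
  set.seed(1)
  pts <- data.frame(x = runif(n, 0, 500), y = runif(n, 0, 500),
                    z = runif(n, 0, 500))
  expect_equal(nrow(connect_intra(pts, pts, 0, 350, seed = 1)), 0)

  # Monte-Carlo oracle for the expected edge count on a fixed layout
  d2 <- as.matrix(dist(pts))^2
  diag(d2) <- Inf
  pm <- 0.7 * exp(-d2 / (2 * 350^2))
  expected <- sum(pm)
  vv <- sum(pm * (1 - pm))
  counts <- vapply(1:40, function(s)
    nrow(connect_intra(pts, pts, 0.7, 350, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(vv / 40))

  # no self-connections ever
  ed <- connect_intra(pts, pts, 0.9, 1e5, seed = 3)
  expect_true(all(ed$pre != ed$post))

  # edge counts scale linearly with the amplitude in expectation
  c1 <- mean(vapply(1:30, function(s)
    nrow(connect_intra(pts, pts, 0.3, 350, seed = s)), numeric(1)))
  expect_lt(abs(c1 - 0.3 / 0.7 * expected), 4 * sqrt(vv / 30))
})

test_that("inter-area wiring depends only on z and clips at probability 1", {
  src <- data.frame(x = runif(40), y = runif(40), z = rep(100, 40))
  tgt <- data.frame(x = runif(50) + 5000, y = runif(50), z = rep(100, 50))
  # amplitude 13 at zero z-distance: every ordered pair connected
  ed <- connect_inter(src, tgt, 13, 1000, seed = 1)
  expect_equal(nrow(ed), 40 * 50)
  # amplitude 0.2 at zero z-distance: plain Bernoulli(0.2)
  n_ed <- vapply(1:40, function(s)
    nrow(connect_inter(src, tgt, 0.2, 1000, seed = s)), numeric(1))
  expect_lt(abs(mean(n_ed) - 0.2 * 2000), 3 * sqrt(2000 * 0.2 * 0.8 / 40))
  # monotone non-increasing connection fraction in z-distance
  fr <- vapply(c(0, 500, 1000, 2000, 4000), function(dz) {
    tg2 <- tgt; tg2$z <- 100 + dz
    mean(vapply(1:10, function(s)
      nrow(connect_inter(src, tg2, 0.9, 1000, seed = s)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(connect_inter(src, tgt, 1, source_class = "inh"),
               "excitatory")
})

test_that("the assembled graph respects the areal wiring diagram", {
  net <- tiny_network()
  ed <- net$topology$edges
  lay <- net$layout
  pairs <- unique(data.frame(from = lay$area[ed$pre], to = lay$area[ed$post],
                             rule = ed$rule))
  inter <- pairs[pairs$rule == "inter", ]
  got <- sort(paste(inter$from, inter$to, sep = ">"))
  expect_equal(got, sort(c("EC>DG", "EC>CA3", "EC>CA1", "DG>CA3",
                           "CA3>CA1", "CA1>EC")))
  # inter-area projections originate from excitatory cells only
  expect_true(all(lay$cell[ed$pre[ed$rule == "inter"]] == "exc"))
  # intra rules absent from the tables yield no edges (e.g. EC E->E, CA3 I->I)
  intra <- pairs[pairs$rule == "intra", ]
  ecee <- ed$rule == "intra" & lay$area[ed$pre] == "EC" &
    lay$cell[ed$pre] == "exc" & lay$cell[ed$post] == "exc"
  expect_equal(sum(ecee), 0)

  # same seed, same graph
  net2 <- build_network(network_config(scale = 0.02, seed = 3,
                                       lloyd_iter = 50))
  expect_identical(net$topology$edges, net2$topology$edges)
})
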