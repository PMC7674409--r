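test_that("circular lattice construction matches brute-force enumeration", {
  # minimal disc: central node plus its 6-neighbor ring
  lat <- hex_lattice(34.7, 20)
  expect_equal(lat$n, 7L)
  expect_equal(sort(lat$degree), c(rep(3L, 6L), 6L))

  expect_error(hex_lattice(10, 20), "radius > side")

  # full 5 mm domain: node count equals an independent brute-force count of
  # hex centers within the disc (axial coordinates, pointy-top)
  lat5 <- hex_lattice(5000, 20)
  pitch <- 20 * sqrt(3)
  qr <- expand.grid(q = -200:200, r = -200:200)
  x <- pitch * (qr$q + qr$r / 2)
  y <- pitch * sqrt(3) / 2 * qr$r
  expect_equal(lat5$n, sum(x^2 + y^2 <= 5000^2))
  expect_true(all(lat5$x^2 + lat5$y^2 <= 5000^2))
})

test_that("adjacency is symmetric with correct degrees and rim flags", {
  lat <- ring_lattice(5)
  # exhaustive symmetry check
  for (i in seq_len(lat$n))
    for (j in lat$nbr[i, ][lat$nbr[i, ] > 0L])
      expect_true(i %in% lat$nbr[j, ])
  # interior nodes have exactly 6 neighbors; rim nodes fewer
  expect_true(all(lat$degree[!lat$is_boundary] == 6L))
  expect_true(all(lat$degree[lat$is_boundary] < 6L))
  # neighbor distances all equal the pitch
  i <- rep(seq_len(lat$n), 6L)
  j <- as.vector(lat$nbr)
  keep <- j > 0L
  d <- sqrt((lat$x[i[keep]] - lat$x[j[keep]])^2 +
              (lat$y[i[keep]] - lat$y[j[keep]])^2)
  expect_equal(d, rep(lat$pitch, sum(keep)), tolerance = 1e-12)

  # sampled symmetry on a large lattice
  lat2 <- hex_lattice(1000, 20)
  for (i in sample(lat2$n, 100))
    for (j in lat2$nbr[i, ][lat2$nbr[i, ] > 0L])
      expect_true(i %in% lat2$nbr[j, ])
})

test_that("regular obstacle layouts match direct enumeration", {
  lat <- hex_lattice(5000, 20)
  spec <- obstacle_spec("regular", diameter = 100, spacing = 500)
  lato <- apply_obstacles(lat, spec, clear_radius = 2000)

  # brute force: grid centers in the annulus outside the inoculation disc,
  # nodes within 50 um of any center (and outside the protected disc)
  cc <- expand.grid(cx = 500 * (-11:11), cy = 500 * (-11:11))
  cr <- sqrt(cc$cx^2 + cc$cy^2)
  cc <- cc[cr > 2000 & cr <= 5050, ]
  expected <- rep(FALSE, lat$n)
  for (i in seq_len(nrow(cc))) {
    hit <- (lat$x - cc$cx[i])^2 + (lat$y - cc$cy[i])^2 <= 50^2
    expected <- expected | hit
  }
  expected <- expected & lat$x^2 + lat$y^2 > 2000^2
  expect_equal(lato$is_obstacle, expected)
  expect_gt(sum(lato$is_obstacle), 0)
  # inoculation disc stays obstacle-free
  expect_false(any(lato$is_obstacle[lat$x^2 + lat$y^2 <= 2000^2]))
})

test_that("obstacle modes: identity, degenerate stochastic, validation", {
  lat <- hex_lattice(1000, 20)
  expect_identical(apply_obstacles(lat, obstacle_spec("none")), lat)

  reg <- apply_obstacles(lat, obstacle_spec("regular", spacing = 400),
                         clear_radius = 400)
  st0a <- apply_obstacles(lat, obstacle_spec("stochastic", spacing = 400,
                                             spread = 0, seed = 1),
                          clear_radius = 400)
  st0b <- apply_obstacles(lat, obstacle_spec("stochastic", spacing = 400,
                                             spread = 0, seed = 999),
                          clear_radius = 400)
  expect_identical(st0a$is_obstacle, reg$is_obstacle)
  expect_identical(st0b$is_obstacle, reg$is_obstacle)

  # stochastic layouts are reproducible given the seed
  s1 <- apply_obstacles(lat, obstacle_spec("stochastic", spacing = 400,
                                           seed = 7), clear_radius = 400)
  s2 <- apply_obstacles(lat, obstacle_spec("stochastic", spacing = 400,
                                           seed = 7), clear_radius = 400)
  expect_identical(s1$is_obstacle, s2$is_obstacle)

  expect_error(obstacle_spec("regular", diameter = 500, spacing = 400),
               "spacing > diameter")

  # a layout smothering the whole rim is rejected
  small <- hex_lattice(150, 20)
  expect_error(
    apply_obstacles(small, obstacle_spec("regular", diameter = 399,
                                         spacing = 400)),
    "boundary rim")
})

test_that("periphery returns occupied nodes touching vacancies", {
  lat <- ring_lattice(4)
  center <- which.min(lat$x^2 + lat$y^2)

  st1 <- manual_state(lat, center)
  expect_equal(periphery(lat, st1$strain), center)

  # filled 7-node disc: the 6 ring nodes, center excluded
  d7 <- disc_nodes(lat, 1)
  st7 <- manual_state(lat, d7)
  expect_setequal(periphery(lat, st7$strain), setdiff(d7, center))

  # filled 3-ring disc vs brute-force neighbor scan
  d3 <- disc_nodes(lat, 3)
  st3 <- manual_state(lat, d3)
  occ <- logical(lat$n); occ[d3] <- TRUE
  brute <- Filter(function(i) {
    nb <- lat$nbr[i, ]; nb <- nb[nb > 0L]
    any(!occ[nb] & !lat$is_obstacle[nb])
  }, d3)
  expect_setequal(periphery(lat, st3$strain), brute)
  # and these are exactly the ring-3 nodes
  expect_setequal(periphery(lat, st3$strain), setdiff(d3, disc_nodes(lat, 2)))

  expect_length(periphery(lat, integer(lat$n)), 0)

  # obstacle nodes never appear, nor count as vacancies
  lato <- lat
  ring1 <- setdiff(disc_nodes(lat, 1), center)
  lato$is_obstacle[ring1] <- TRUE
  sto <- manual_state(lato, center)
  expect_length(periphery(lato, sto$strain), 0)  # enclosed by obstacles
})

test_that("shortest path to periphery matches a BFS oracle", {
  lat <- ring_lattice(5)
  center <- which.min(lat$x^2 + lat$y^2)

  d3 <- disc_nodes(lat, 3)
  st <- manual_state(lat, d3)

  # origin already on the periphery
  rim <- periphery(lat, st$strain)
  expect_equal(shortest_path_to_periphery(lat, st$strain, rim[1]), rim[1])

  # center of the filled 3-ring disc: graph distance 3, path of 4 nodes
  set.seed(1)
  p <- shortest_path_to_periphery(lat, st$strain, center)
  expect_length(p, 4L)
  expect_equal(p[1], center)
  expect_true(p[4] %in% rim)
  # consecutive path nodes are lattice neighbors, all occupied
  for (k in seq_len(3)) expect_true(p[k + 1] %in% lat$nbr[p[k], ])
  expect_true(all(st$strain[p] > 0L))

  # path length equals independent BFS distance for every node of the disc
  dist_to_rim <- bfs_distances(lat, rim, allowed = d3)
  for (i in d3) {
    pi <- shortest_path_to_periphery(lat, st$strain, i)
    expect_equal(length(pi) - 1L, dist_to_rim[i])
  }

  expect_error(shortest_path_to_periphery(lat, st$strain, lat$n),
               "occupied")

  # fully enclosed by obstacles: no periphery reachable
  lato <- lat
  lato$is_obstacle[setdiff(disc_nodes(lat, 1), center)] <- TRUE
  sto <- manual_state(lato, center)
  expect_null(shortest_path_to_periphery(lato, sto$strain, center))

  # max_depth cutoff
  expect_null(shortest_path_to_periphery(lat, st$strain, center,
                                         max_depth = 2))
})

test_that("lattice construction is deterministic and exportable", {
  a <- hex_lattice(300, 20)
  b <- hex_lattice(300, 20)
  expect_identical(a, b)
  tab <- lattice_table(a)
  expect_equal(nrow(tab), a$n)
  expect_named(tab, c("node", "x", "y", "boundary", "obstacle"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lattice(a, f)
  expect_equal(nrow(utils::read.table(f, header = TRUE)), a$n)
})
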