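# Lattice cluster construction, penetration classification and slicing.

test_that("a 1-D pair is two cells at the requested spacing", {
  pop <- build_population(cluster_spec("pair", spacing_um = 13,
                                       cell = ref_cell()))
  expect_equal(nrow(pop), 2L)
  expect_equal(sqrt(sum((pop[2, c("x", "y", "z")] -
                           pop[1, c("x", "y", "z")])^2)), 13)
})

test_that("the reference spheroid fills to exactly 3473 cells", {
  spec <- cluster_spec("sphere", list(radius = 125), 13, ref_cell())
  pop <- build_population(spec)
  expect_equal(nrow(pop), 3473L)
  # continuum sanity: (4/3) pi R^3 / spacing^3 ~ 3.7e3
  expect_equal(nrow(pop), 4 / 3 * pi * 125^3 / 13^3, tolerance = 0.1)
  # no two cells closer than the lattice pitch
  i <- sample.int(nrow(pop), 200)
  P <- as.matrix(pop[, c("x", "y", "z")])
  dmin <- min(as.matrix(dist(P[i, ]))[upper.tri(diag(200))])
  expect_gte(dmin, 13 - 1e-9)
})

test_that("a cluster radius below the spacing yields exactly one central cell", {
  pop <- build_population(cluster_spec("sphere", list(radius = 12.5), 13,
                                       ref_cell()))
  expect_equal(nrow(pop), 1L)
  expect_lt(pop$r, 13 / 2)
})

test_that("zero-cell specifications are rejected with a diagnostic", {
  expect_error(build_population(cluster_spec("sphere", list(radius = 3.5),
                                             13, cell_model(1.5, 1))),
               "zero cells")
})

test_that("penetration classification marks the outer rim only", {
  spec <- cluster_spec("sphere", list(radius = 125), 13, ref_cell(),
                       penetration_depth_um = 12)
  pop <- build_population(spec)
  # a single 13-um lattice shell: eligible cells within 12 um of the
  # surface, everything deeper is cold
  expect_true(all(pop$surface_distance[pop$eligible] <= 12))
  expect_true(all(pop$surface_distance[!pop$eligible] > 12))
  expect_gt(sum(pop$eligible), 0)
  expect_lt(sum(pop$eligible), nrow(pop) / 3)
  # the eligible set is one lattice layer: no eligible cell has another
  # eligible cell directly beneath it (radially) within one spacing
  expect_gt(min(pop$r[pop$eligible]), max(pop$r[!pop$eligible]))

  # full penetration labels everything
  pop2 <- classify_penetration(pop, Inf)
  expect_true(all(pop2$eligible))
  # reclassification with depth >= radius also labels everything
  pop3 <- classify_penetration(pop, 125)
  expect_true(all(pop3$eligible))
  # zero depth: nothing eligible, labeling then errors
  pop4 <- classify_penetration(pop, 0)
  expect_false(any(pop4$eligible))
  expect_error(select_labeled(pop4, 100, seed = 1), "eligible")
})

test_that("slices partition the population and peak at the equator", {
  spec <- cluster_spec("sphere", list(radius = 125), 13, ref_cell())
  pop <- build_population(spec)
  sl <- slice_population(pop, axial_height = 1)
  expect_equal(sort(as.integer(unlist(tapply(sl$index, sl$layer, c)))),
               pop$index)
  # one layer per lattice plane: the equatorial plane holds the most cells
  sl13 <- slice_population(pop, axial_height = 13 / 12)
  counts <- table(sl13$layer)
  mid <- as.integer(names(which.max(counts)))
  expect_true(abs(mid - mean(range(as.integer(names(counts))))) <= 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_slices(sl, f)
  expect_equal(nrow(read.csv(f)), nrow(pop))
  expect_error(slice_population(build_population(
    cluster_spec("pair", spacing_um = 13, cell = ref_cell()))), "3-D")
})

test_that("non-spherical shapes build with exact interior surface distances", {
  cm <- ref_cell()
  rod <- build_population(cluster_spec("rod", list(radius = 40, length = 120),
                                       13, cm, penetration_depth_um = 12))
  expect_gt(nrow(rod), 10)
  expect_true(all(rod$surface_distance >= 0))
  expect_true(all(abs(rod$z) <= 60))

  ell <- build_population(cluster_spec(
    "ellipsoid", list(semi_x = 60, semi_y = 45, semi_z = 45), 13, cm))
  expect_gt(nrow(ell), 10)
  expect_true(all(ell$surface_distance >= -1e-9))
  # surface distance never exceeds the shortest semi-axis
  expect_true(all(ell$surface_distance <= 45))

  cone <- build_population(cluster_spec("cone",
                                        list(radius = 50, height = 90),
                                        13, cm))
  expect_gt(nrow(cone), 10)
  expect_true(all(cone$z >= 0 & cone$surface_distance >= 0))

  disc <- build_population(cluster_spec("circle", list(radius = 60), 13, cm))
  expect_true(all(disc$z == 0))
  expect_equal(nrow(disc), sum(disc$r <= 60))
})

test_that("lattice distances enumerate the realizable pair separations", {
  spec <- cluster_spec("sphere", list(radius = 40), 13, ref_cell())
  pop <- build_population(spec)
  d <- celldose:::lattice_distances(pop, 40)
  expect_true(all(diff(d) > 0))
  expect_true(13 %in% d)
  expect_true(all(round((d / 13)^2) %in%
                    rowSums(expand.grid(0:3, 0:3, 0:3)^2)))
  # every realized pair distance is in the table
  P <- as.matrix(pop[, c("x", "y", "z")])
  dd <- as.vector(dist(P))
  dd <- dd[dd <= max(d) + 1e-9]
  expect_true(all(vapply(dd, function(x) any(abs(x - d) < 1e-6), logical(1))))
})
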