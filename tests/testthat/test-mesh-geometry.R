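test_that("two-region concentric-circle geometry meshes with a closed membrane", {
  spec <- cell_geometry_spec(disc(0, 0, 15), disc(0, 0, 6), h = 1.5)
  mesh <- build_synthetic_cell(spec)
  expect_true(all(mesh$compartment %in% c("cytoplasm", "nucleus")))
  expect_true(all(triangle_areas(mesh) > 0))

  edges <- classify_edges(mesh)
  mem <- edges[edges$class == "membrane", ]
  expect_gt(nrow(mem), 0)
  # closed chain: every membrane vertex touches an even number of chain edges
  expect_true(all(table(c(mem$v1, mem$v2)) %% 2 == 0))

  # total area within 2% of the analytic circle area
  expect_lt(abs(region_areas(mesh)$total - pi * 15^2) / (pi * 15^2), 0.02)
})

test_that("a full cell geometry at imaging resolution has interface edges and O(10^3) triangles", {
  mesh <- fixture_cell_mesh()
  expect_gt(nrow(mesh$triangles), 100)
  expect_lt(nrow(mesh$triangles), 5000)
  edges <- classify_edges(mesh)
  expect_gt(sum(edges$class == "membrane"), 0)
  expect_gt(sum(edges$class == "aggregate"), 0)
  expect_gt(sum(mesh$bleach), 0)
  expect_true(all(mesh$compartment[mesh$bleach] == "nucleus"))
})

test_that("edge classes partition all edges and interface chains are closed", {
  for (mesh in list(fixture_cell_mesh(), unit_square_mesh(4),
                    two_triangle_mesh(c("cytoplasm", "nucleus")))) {
    edges <- classify_edges(mesh)
    # disjoint and exhaustive by construction of the table: check counts
    expect_equal(sum(table(edges$class)), nrow(edges))
    expect_true(all(edges$class %in% c("boundary", "interior", "membrane", "aggregate")))
    # boundary edges have one adjacent triangle, the rest two
    expect_true(all(is.na(edges$tri_plus[edges$class == "boundary"])))
    expect_true(all(!is.na(edges$tri_plus[edges$class != "boundary"])))
    # area additivity
    ra <- region_areas(mesh)
    expect_equal(ra$cytoplasm + ra$nucleus + sum(ra$aggregate), ra$total,
                 tolerance = 1e-12)
  }
  agg <- classify_edges(fixture_cell_mesh())
  ae <- agg[agg$class == "aggregate", ]
  expect_true(all(table(c(ae$v1, ae$v2)) %% 2 == 0))
})

test_that("unit square split into two triangles classifies as 1 interior + 4 boundary", {
  edges <- classify_edges(two_triangle_mesh(c("cytoplasm", "cytoplasm")))
  expect_equal(sort(as.vector(table(edges$class))), c(1, 4))
  expect_equal(sum(edges$class == "interior"), 1)
})

test_that("aggregate boundary length approximates the analytic circumference", {
  spec <- cell_geometry_spec(disc(0, 0, 7), disc(-3.5, 0, 2),
                             aggregates = list(disc(2.5, 0, 2)), h = 0.4)
  mesh <- build_synthetic_cell(spec)
  per <- interface_perimeters(classify_edges(mesh))
  expect_lt(abs(per$aggregate[["1"]] - 2 * pi * 2) / (2 * pi * 2), 0.03)
})

test_that("invalid geometry specs are rejected", {
  expect_error(cell_geometry_spec(disc(0, 0, 10), disc(8, 0, 4), h = 1),
               "nucleus")
  expect_error(cell_geometry_spec(disc(0, 0, 10), disc(-4, 0, 3),
                                  aggregates = list(disc(-2, 0, 2)), h = 1),
               "overlaps the nucleus")
  expect_error(cell_geometry_spec(disc(0, 0, 10), disc(-4, 0, 3),
                                  aggregates = list(disc(4, 0, 2), disc(5, 0, 2)),
                                  h = 1),
               "aggregates overlap")
  expect_error(cell_geometry_spec(disc(0, 0, 10), disc(-4, 0, 3),
                                  bleach = disc(0, 0, 1), h = 1),
               "bleach")
})

test_that("nucleus-aggregate adjacency is rejected at edge classification", {
  mesh <- two_triangle_mesh(c("nucleus", "aggregate"))
  expect_error(classify_edges(mesh), "aggregate touching the nucleus")
})

test_that("pixel lengths convert to micrometers", {
  # 25-pixel bleach-spot diameter at 0.0461847 um/px is about 1.15 um
  expect_equal(round(pixel_to_physical(25, 0.0461847), 2), 1.15)
  expect_equal(pixel_to_physical(18, 0.0624404), 1.1239272, tolerance = 1e-7)
  expect_equal(pixel_to_physical(0, 0.05), 0)
  expect_error(pixel_to_physical(-1, 0.05), ">= 0")
  expect_error(pixel_to_physical(5, 0), "> 0")
})
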