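test_that("structured mesh of the unit square conserves area exactly", {
  geo <- vessel_geometry(length = 1, height = 1, has_sac = FALSE,
                         has_orifice = FALSE)
  msh <- generate_mesh(build_geometry(geo), mesh_sizing(h_max = 0.3, h_min = 0.1))
  q <- quality_report(msh)
  expect_equal(q$total_area, 1, tolerance = 1e-10)
  expect_equal(sort(unique(msh$boundary$tag)), c("INLET", "OUTLET", "WALL"))
})

test_that("rectangle mesh with study sizing reproduces L * H", {
  geo <- vessel_geometry(has_sac = FALSE, has_orifice = FALSE)
  msh <- generate_mesh(build_geometry(geo), mesh_sizing())
  expect_equal(quality_report(msh)$total_area, 0.7 * 0.09, tolerance = 1e-8)
})

test_that("triangle quality metric matches closed forms", {
  equilateral <- hemofem:::new_mesh(
    rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
    matrix(c(1, 2, 3), 1),
    data.frame(n1 = c(1, 2, 3), n2 = c(2, 3, 1), tag = "WALL"),
    region = 1L, mode = "planar")
  expect_equal(quality_report(equilateral)$min_quality, 1, tolerance = 1e-12)
  right <- hemofem:::new_mesh(
    rbind(c(0, 0), c(1, 0), c(0, 1)),
    matrix(c(1, 2, 3), 1),
    data.frame(n1 = c(1, 2, 3), n2 = c(2, 3, 1), tag = "WALL"),
    region = 1L, mode = "planar")
  expect_equal(quality_report(right)$min_quality, 4 * sqrt(3) * 0.5 / 4,
               tolerance = 1e-12)
})

test_that("sac mesh conserves area, covers tags, and refines near the orifice", {
  msh <- rupture_mesh_coarse()
  q <- quality_report(msh)
  bnd <- build_geometry(vessel_geometry())
  pg <- boundary_polygon(bnd, 2e-4)
  # the triangulation partitions its own polygonal boundary; the polygon
  # area differs from the smooth-arc area only by boundary discretisation
  expect_equal(q$total_area, polygon_area(pg$points), tolerance = 2e-3)
  expect_true(q$min_quality > 0.2)
  expect_true(q$avg_quality > 0.8)
  expect_true(q$min_quality <= q$avg_quality)
  expect_gte(length(unique(msh$boundary$tag)), 4L)
  # graded refinement: median boundary-adjacent edge length near the
  # orifice below the median far away
  apex <- c(0.30, 0.09 + hemofem:::sac_center_height(0.025, 0.035) + 0.025)
  mids <- (msh$nodes[msh$tri[, 1], ] + msh$nodes[msh$tri[, 2], ] +
             msh$nodes[msh$tri[, 3], ]) / 3
  d <- sqrt((mids[, 1] - apex[1])^2 + (mids[, 2] - apex[2])^2)
  area <- abs(hemofem:::triangle_areas(msh))
  h_eff <- sqrt(area)
  expect_lt(median(h_eff[d < 0.024]), median(h_eff[d > 0.1]))
})

test_that("meshing is deterministic and monotone under refinement", {
  m1 <- rupture_mesh_coarse()
  m2 <- rupture_mesh_coarse()
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tri, m2$tri)
  expect_identical(m1$boundary$tag, m2$boundary$tag)
  geo <- vessel_geometry(has_sac = FALSE, has_orifice = FALSE)
  bnd <- build_geometry(geo)
  n_coarse <- nrow(generate_mesh(bnd, mesh_sizing(h_max = 0.02, h_min = 0.005))$tri)
  n_fine <- nrow(generate_mesh(bnd, mesh_sizing(h_max = 0.01, h_min = 0.005))$tri)
  expect_gte(n_fine, n_coarse)
})

test_that("boundary edges belong to exactly one triangle and close up", {
  msh <- rupture_mesh_coarse()
  et <- hemofem:::edge_table(msh$tri)
  expect_equal(sum(et$count == 1L), nrow(msh$boundary))
  # boundary edges form closed loops: every boundary vertex has even degree
  deg <- table(c(msh$boundary$n1, msh$boundary$n2))
  expect_true(all(deg %% 2 == 0))
})

test_that("mesh sizing invariants are enforced", {
  expect_error(mesh_sizing(h_max = 0.001, h_min = 0.01), "h_max >= h_min")
  expect_error(mesh_sizing(growth_rate = 0.9), "growth_rate")
})
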