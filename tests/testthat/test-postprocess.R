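test_that("line sampling reproduces constant and linear nodal fields exactly", {
  fe <- fe_space(channel_mesh(L = 1, H = 1, h = 0.22))
  const <- rep(3.5, fe$nv)
  ls <- sample_line(const, fe, c(0.1, 0.1), c(0.9, 0.8), n = 37)
  expect_true(all(abs(ls$value - 3.5) < 1e-12))
  lin <- fe$mesh$nodes[, 1] + fe$mesh$nodes[, 2]
  ls <- sample_line(lin, fe, c(0.05, 0.9), c(0.95, 0.1), n = 41)
  expect_equal(ls$value, ls$z + ls$x, tolerance = 1e-12)
  expect_equal(nrow(ls), 41L)
  expect_true(all(diff(ls$s) > 0))
  expect_equal(diff(range(diff(ls$s))), 0, tolerance = 1e-12)
  expect_error(sample_line(const, fe, c(-1, 0), c(2, 0), n = 5),
               "outside the mesh")
})

test_that("a sampled Poiseuille profile is symmetric and peaks at the midline", {
  fe <- fe_space(channel_mesh(h = 0.015))
  st <- flow_state(fe)
  x <- fe$p2xy[, 2]
  st$velocity[, 1] <- 6 * 0.08 * (x / 0.09) * (1 - x / 0.09)
  prof <- sample_line(st, fe, c(0.35, 0), c(0.35, 0.09), n = 101)
  expect_equal(which.max(prof$value), 51L)
  expect_equal(prof$value, rev(prof$value), tolerance = 1e-6)
  expect_equal(max(prof$value), 1.5 * 0.08, tolerance = 1e-10)
})

make_toy_trajectory <- function() {
  fe <- fe_space(channel_mesh(L = 0.3, h = 0.03))
  props <- blood_props()
  snaps <- lapply(c(0, 0.1, 0.2), function(tt) {
    fs <- flow_state(fe, t = tt)
    fs$velocity[, 1] <- 0.05 * (1 + tt)
    fs$pressure[] <- 13000 - 10 * tt
    ts <- thermal_state(fe, t = tt, temperature = rep(310 + tt, fe$nv))
    list(t = tt, flow = fs, thermal = ts)
  })
  structure(list(snapshots = snaps, fe = fe, props = props, dt = 0.1),
            class = "run_trajectory")
}

test_that("extremes tables equal a direct re-scan of the stored fields", {
  traj <- make_toy_trajectory()
  ext <- extremes(traj)
  expect_equal(nrow(ext), 3L)
  for (i in seq_len(3)) {
    sn <- traj$snapshots[[i]]
    expect_equal(ext$v_max[i], max(sqrt(rowSums(sn$flow$velocity^2))))
    expect_equal(ext$v_min[i], min(sqrt(rowSums(sn$flow$velocity^2))))
    expect_equal(ext$p_max[i], max(sn$flow$pressure))
    expect_equal(ext$p_min[i], min(sn$flow$pressure))
    expect_equal(ext$T_max[i], max(sn$thermal$temperature))
  }
  expect_true(all(diff(ext$t) > 0))
  # single-snapshot selection keeps row invariants
  one <- extremes(traj, times = 0.1)
  expect_equal(nrow(one), 1L)
  expect_lte(one$v_min, one$v_max)
  expect_error(extremes(traj, times = 5), "within dt/2")
  expect_error(extremes(structure(list(snapshots = list(), fe = traj$fe),
                                  class = "run_trajectory")), "empty")
})

test_that("rest-state extremes collapse to zero speed and the outlet pressure", {
  fe <- fe_space(channel_mesh(L = 0.3, h = 0.03))
  fs <- flow_state(fe); fs$pressure[] <- 13000
  traj <- structure(list(snapshots = list(list(t = 0, flow = fs, thermal = NULL)),
                         fe = fe, props = blood_props(), dt = 0.01),
                    class = "run_trajectory")
  ext <- extremes(traj)
  expect_equal(ext$v_max, 0)
  expect_equal(ext$v_min, 0)
  expect_equal(ext$p_max, 13000)
  expect_equal(ext$p_min, 13000)
})

test_that("comparison against the bundled reference behaves as a signed deviation", {
  ref <- reference_extremes()
  expect_equal(ref$t, c(0.4, 0.8, 1.2, 2.4))
  expect_equal(ref$v_max[1], 0.082)
  expect_equal(ref$v_min[1], 0.063)
  expect_equal(ref$p_max[1], 13120)
  expect_equal(ref$p_min[1], 13000)
  # a report identical to the reference has zero deviations
  fake <- ref
  fake$v_max_line <- ref$v_max; fake$v_min_line <- ref$v_min
  dev <- compare_extremes(fake, ref)
  expect_true(all(abs(unlist(dev[, -1])) < 1e-14))
  # deviations flip sign (to first order) when report and reference swap
  fake2 <- fake
  fake2$v_max_line <- fake$v_max_line * 1.05
  d1 <- compare_extremes(fake2, ref)$dv_max
  ref2 <- ref; ref2$v_max <- fake2$v_max_line
  fake3 <- fake
  d2 <- compare_extremes(fake3, ref2)$dv_max
  expect_equal(d1, -d2 * (1 + d1), tolerance = 1e-10)
  expect_error(compare_extremes(fake[1:2, ], ref), "lacks times")
})

test_that("VTK export round-trips fields and writes the documented CSV schemas", {
  traj <- make_toy_trajectory()
  dir <- withr::local_tempdir()
  files <- export_fields(traj, dir)
  vtks <- list.files(dir, pattern = "\\.vtk$")
  expect_length(vtks, 3L)   # one per stored output time
  back <- hemofem:::read_vtk_snapshot(file.path(dir, vtks[1]))
  sn <- traj$snapshots[[1]]
  nv <- nrow(traj$fe$mesh$nodes)
  expect_equal(back$points, unname(traj$fe$mesh$nodes), tolerance = 1e-12)
  expect_equal(back$velocity[, 1], unname(sn$flow$velocity[seq_len(nv), 1]),
               tolerance = 1e-9)
  expect_equal(back$pressure, sn$flow$pressure, tolerance = 1e-6)
  expect_equal(back$temperature, sn$thermal$temperature, tolerance = 1e-9)
  ext <- utils::read.csv(file.path(dir, "extremes.csv"))
  expect_true(all(c("t", "v_max", "v_min", "p_max", "p_min",
                    "v_max_line", "v_min_line", "T_max", "T_min") %in% names(ext)))
  ls <- utils::read.csv(file.path(dir, "line_samples.csv"))
  expect_identical(names(ls), c("t", "s", "z", "x", "value"))
})
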