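test_that("bundled material table carries the tabulated constants", {
  tab <- material_table()
  expect_equal(nrow(tab), 3L)
  blood <- material_record("blood", tab)
  expect_equal(blood$rho, 1063)
  expect_equal(blood$mu, 0.003)
  expect_equal(blood$k, 0.52)
  expect_equal(blood$cp, 3746)
  gold <- material_record("gold", tab)
  expect_equal(gold$rho, 19300)
  expect_equal(gold$k, 310)
  expect_equal(gold$cp, 129)
  silver <- material_record("silver", tab)
  expect_equal(silver$rho, 10500)
  expect_equal(silver$k, 429)
  expect_equal(silver$cp, 2354)   # printed value; see silver_cp option
  expect_equal(material_record("silver", material_table(silver_cp = "handbook"))$cp,
               235)
})

test_that("user-supplied material CSVs are validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,cp,k,mu,rho\nwater,4180,0.6,0.001,998", f)
  tab <- material_table(f)
  expect_equal(tab$rho, 998)
  writeLines("name,cp,k,mu,rho\nbad,-1,0.6,0.001,998", f)
  expect_error(material_table(f), "strictly positive")
  writeLines("name,cp,k\nbad,1,0.6", f)
  expect_error(material_table(f), "columns")
})

test_that("loading validation rejects unphysical volume fractions", {
  expect_error(loading(-0.01, 0), "nonnegative")
  expect_error(loading(0, 1), "below 1")
  expect_error(loading(0.3, 0.3), "below 0.5")
  expect_silent(loading(0, 0))
})

test_that("zero loading reduces every effective property to the base fluid", {
  tab <- material_table()
  b <- material_record("blood", tab)
  g <- material_record("gold", tab)
  s <- material_record("silver", tab)
  l0 <- loading(0, 0)
  expect_equal(effective_density(b, g, s, l0), 1063, tolerance = 1e-14)
  expect_equal(effective_heat_capacity(b, g, s, l0), 1063 * 3746,
               tolerance = 1e-14)
  expect_equal(effective_viscosity(b, l0), 0.003, tolerance = 1e-14)
  expect_equal(effective_conductivity(b, g, s, l0), 0.52, tolerance = 1e-14)
  # continuity at vanishing loading
  expect_equal(effective_density(b, g, s, loading(1e-16, 0)), 1063,
               tolerance = 1e-9)
})

test_that("mixture laws match hand-evaluated values at phi1 = phi2 = 0.01", {
  tab <- material_table()
  b <- material_record("blood", tab)
  g <- material_record("gold", tab)
  s <- material_record("silver", tab)
  l <- loading(0.01, 0.01)
  # direct arithmetic: 0.99*(0.99*1063 + 0.01*19300) + 0.01*10500
  expect_equal(effective_density(b, g, s, l), 1337.9163, tolerance = 1e-10)
  expect_equal(effective_viscosity(b, l), 0.003 / 0.99^5, tolerance = 1e-14)
  # two Maxwell steps evaluated in sequence by hand
  expect_equal(effective_conductivity(b, g, s, l), 0.5518, tolerance = 1e-3)
  # volumetric heat capacity with the printed silver cp (2354):
  # 0.99*(0.99*1063*3746 + 0.01*19300*129) + 0.01*10500*2354
  expect_equal(effective_heat_capacity(b, g, s, l), 4174574.2698,
               tolerance = 1e-10)
  # with the handbook silver cp the same formula lands at ~3.952e6
  tab2 <- material_table(silver_cp = "handbook")
  expect_equal(effective_heat_capacity(material_record("blood", tab2),
                                       material_record("gold", tab2),
                                       material_record("silver", tab2), l),
               3.952079e6, tolerance = 1e-6)
})

test_that("effective properties are strictly monotone in each loading", {
  tab <- material_table()
  b <- material_record("blood", tab)
  g <- material_record("gold", tab)
  s <- material_record("silver", tab)
  phis <- seq(0, 0.1, by = 0.02)
  for (fixed in c(0, 0.05)) {
    rho1 <- vapply(phis, function(p)
      effective_density(b, g, s, loading(p, fixed)), numeric(1))
    rho2 <- vapply(phis, function(p)
      effective_density(b, g, s, loading(fixed, p)), numeric(1))
    mu1 <- vapply(phis, function(p)
      effective_viscosity(b, loading(p, fixed)), numeric(1))
    k1 <- vapply(phis, function(p)
      effective_conductivity(b, g, s, loading(p, fixed)), numeric(1))
    k2 <- vapply(phis, function(p)
      effective_conductivity(b, g, s, loading(fixed, p)), numeric(1))
    expect_true(all(diff(rho1) > 0))
    expect_true(all(diff(rho2) > 0))
    expect_true(all(diff(mu1) > 0))
    expect_true(all(diff(k1) > 0))   # particle k exceeds carrier k
    expect_true(all(diff(k2) > 0))
  }
})

test_that("species order is fixed: gold first, silver second", {
  tab <- material_table()
  b <- material_record("blood", tab)
  g <- material_record("gold", tab)
  s <- material_record("silver", tab)
  l <- loading(0.02, 0.01)
  # the two-step laws are not symmetric under species exchange
  k_fixed <- effective_conductivity(b, g, s, l)
  k_swapped <- effective_conductivity(b, s, g, loading(0.01, 0.02))
  expect_false(isTRUE(all.equal(k_fixed, k_swapped, tolerance = 1e-12)))
  # the bundle documents the (gold, silver) convention
  bun <- props_from_names(load = l, table = tab)
  expect_equal(bun$k, k_fixed, tolerance = 1e-14)
})

test_that("implementation matches an independent arithmetic oracle on random loadings", {
  tab <- material_table()
  b <- material_record("blood", tab)
  g <- material_record("gold", tab)
  s <- material_record("silver", tab)
  set.seed(42)
  for (i in 1:100) {
    p1 <- runif(1, 0, 0.1); p2 <- runif(1, 0, 0.1)
    o <- oracle_mixture(p1, p2, tab)
    bun <- effective_bundle(b, g, s, loading(p1, p2))
    expect_equal(bun$rho, o$rho, tolerance = 1e-12)
    expect_equal(bun$rho_cp, o$rho_cp, tolerance = 1e-12)
    expect_equal(bun$mu, o$mu, tolerance = 1e-12)
    expect_equal(bun$k, o$k, tolerance = 1e-12)
  }
})

test_that("bundle fields are mutually consistent", {
  bun <- hybrid_props()
  expect_equal(bun$nu, bun$mu / bun$rho, tolerance = 1e-14)
  expect_equal(bun$alpha, bun$k / bun$rho_cp, tolerance = 1e-14)
  expect_true(all(unlist(bun[c("rho", "rho_cp", "mu", "k", "nu", "alpha")]) > 0))
})
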