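test_that("the tissue energy matches its definition term by term", {
  mp <- mechanics_params(lambda_area = 1, lambda_wall = 0)
  m <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(1:4))
  expect_equal(tissue_energy(m, mechanics_params()), 0)   # built at rest

  m$rest_area <- 2
  expect_equal(tissue_energy(m, mp), (1 - 2)^2)

  set.seed(21)
  m5 <- build_grid_tissue(1, 5)
  m5$rest_area <- runif(5, 0.5, 2)
  m5$wall_rest <- runif(nrow(m5$walls), 0.5, 2)
  mp2 <- mechanics_params(lambda_area = 3.3, lambda_wall = 0.7)
  expect_equal(tissue_energy(m5, mp2), oracle_energy(m5, 3.3, 0.7),
               tolerance = 1e-9)
})

test_that("zero-temperature relaxation never raises the energy", {
  mp <- mechanics_params(mc_temperature = 0)
  m <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(1:4))
  set.seed(1)
  expect_equal(tissue_energy(relax(m, mp), mp), 0)        # already minimal

  set.seed(2)
  m2 <- build_grid_tissue(2, 2)
  m2$rest_area <- rep(4, 4)                               # strong tension
  h <- tissue_energy(m2, mp)
  for (i in 1:60) {
    m2 <- relax(m2, mp)
    h2 <- tissue_energy(m2, mp)
    expect_lte(h2, h + 1e-12)
    h <- h2
  }
  ## area approaches the resting area (walls resist a little)
  expect_gt(mean(cell_areas(m2)), 3.5)
  expect_equal(validate_mesh(m2), character(0))
})

test_that("relaxation is bit-reproducible under a fixed seed", {
  mp <- mechanics_params()
  m <- build_grid_tissue(2, 3)
  m$rest_area <- m$rest_area * 1.8
  set.seed(99); a <- relax(relax(m, mp), mp)
  set.seed(99); b <- relax(relax(m, mp), mp)
  expect_identical(a$pos, b$pos)
})

test_that("target growth follows the saturating auxin response", {
  mp <- mechanics_params(g0 = 0.1, gA = 0.04, hA = 2)
  m <- build_grid_tissue(1, 3)
  m$auxin <- c(0, 2, 1e9)                                 # zero, half-max, saturated
  g <- grow_targets(m, mp, dt = 0.5)
  inc <- g$rest_area - m$rest_area
  expect_equal(inc[1], 0.5 * 0.1)
  expect_equal(inc[2], 0.5 * (0.1 + 0.04 / 2))
  expect_equal(inc[3], 0.5 * (0.1 + 0.04), tolerance = 1e-8)
  expect_error(grow_targets(m, mp, dt = -1))
})

test_that("division fires at area doubling and inherits state per the rules", {
  mp <- mechanics_params()
  m <- build_grid_tissue(1, 2)
  m$auxin <- c(0.8, 0.1)
  m$area_last_div <- c(0.502, 1)                          # 1.99x: below doubling
  set.seed(4)
  expect_identical(length(divide_if_ready(m, 1, mp)$cells), 2L)

  m$area_last_div[1] <- 0.5                               # 2.0x: divides
  d <- divide_if_ready(m, 1, mp, pin_mode = "conserve")
  expect_length(d$cells, 3L)
  ## both daughters carry the parent's auxin concentration unchanged
  expect_equal(d$auxin[1], 0.8)
  expect_equal(d$auxin[3], 0.8)
  expect_equal(validate_mesh(d), character(0))
  ## division counters reset to the daughters' current areas
  expect_equal(d$area_last_div[c(1, 3)], cell_areas(d)[c(1, 3)])
})

test_that("division conserves area and, in conserve mode, total PIN", {
  mp <- mechanics_params()
  tp <- transport_params()
  set.seed(12)
  m <- build_grid_tissue(2, 2)
  m <- init_state(m, tp)
  m$pin_endo <- c(10, 1, 1, 1)
  e12 <- which(m$edge_from == 1)
  m$pin_edge[e12] <- 0.5                                  # some wall PIN too
  area0 <- sum(cell_areas(m))
  pin0 <- cell_pin_total(m, 1)
  m$area_last_div[1] <- cell_areas(m)[1] / 2
  d <- divide_if_ready(m, 1, mp, pin_mode = "conserve")
  expect_length(d$cells, 5L)
  daughters <- c(1L, 5L)
  expect_equal(sum(cell_areas(d)), area0, tolerance = 1e-9)
  expect_equal(sum(vapply(daughters, function(i) cell_pin_total(d, i),
                          numeric(1))), pin0, tolerance = 1e-12)
  ## endosomal PIN is split in proportion to daughter area
  a <- cell_areas(d)[daughters]
  expect_equal(d$pin_endo[daughters], 10 * a / sum(a), tolerance = 1e-9)
  ## the new shared wall starts PIN-free
  enew <- which(d$edge_from == 1L & d$edge_to == 5L)
  expect_equal(d$pin_edge[enew], 0)
  ## other cells' PIN books are untouched
  expect_equal(cell_pin_total(d, 2), cell_pin_total(m, 2), tolerance = 1e-12)
})

test_that("renormalize mode restores the fixed per-cell PIN pool", {
  mp <- mechanics_params()
  tp <- transport_params(pin_total = 3)
  set.seed(13)
  m <- init_state(build_grid_tissue(2, 2), tp)
  m$area_last_div[2] <- cell_areas(m)[2] / 2
  d <- divide_if_ready(m, 2, mp, pin_mode = "renormalize", pin_total = 3)
  expect_length(d$cells, 5L)
  expect_equal(cell_pin_total(d, 2), 3, tolerance = 1e-12)
  expect_equal(cell_pin_total(d, 5), 3, tolerance = 1e-12)
})

test_that("a full division sweep keeps the mesh valid and reproducible", {
  mp <- mechanics_params()
  tp <- transport_params()
  run <- function(seed) {
    set.seed(seed)
    m <- init_state(build_grid_tissue(2, 2), tp)
    m$rest_area <- m$rest_area * 4
    for (i in 1:80) m <- relax(m, mp)
    m <- divide_ready(m, mp, pin_total = tp$pin_total)
    m
  }
  a <- run(31); b <- run(31)
  expect_identical(a$pos, b$pos)
  expect_identical(a$cells, b$cells)
  expect_gt(length(a$cells), 4L)
  expect_equal(validate_mesh(a), character(0))
})
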