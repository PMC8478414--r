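test_that("parameter validation enforces the model ranges", {
  expect_error(mechanics_params(g = 0), "invalid configuration")
  expect_error(mechanics_params(g = 1.2), "invalid configuration")
  expect_error(mechanics_params(rho = -0.1), "invalid configuration")
  expect_error(mechanics_params(lambda = -1), "invalid configuration")
  expect_error(confinement_spec(outer_radius = -5), "invalid configuration")
  expect_error(confinement_spec("annulus", 100, 150),
               "invalid configuration")
})

test_that("per-cell energies match independent term-by-term recomputation", {
  set.seed(11)
  st <- make_confined_state(11)
  st$params$g <- 0.8; st$params$rho <- 0.6
  ce <- cell_energies(st, "main")
  tess <- build_tessellation(st$centers)
  cls <- st$centers$class
  eps <- st$params$edge_eps
  ext <- cls == "exterior"
  j <- tess$junctions
  sl <- sqrt(j$length^2 + eps^2) - eps
  for (i in which(!ext)) {
    bnd <- cls[i] == "boundary"
    K <- st$params$K * if (bnd) st$params$rho else 1
    gA0 <- st$params$g * (if (bnd) st$params$rho_g else 1) *
      st$params$A0[i]
    elast <- 0.5 * K * gA0 * (tess$areas[i] / gA0 - 1)^2
    mine <- j$cell1 == i | j$cell2 == i
    other <- ifelse(j$cell1 == i, j$cell2, j$cell1)
    tens <- sum(st$params$lambda * sl[mine & !ext[other]])
    expect_equal(ce[i], elast + tens, tolerance = 1e-10)
  }
  ## a relaxed cell with A = gA0 and no tension has zero energy
  st0 <- st
  st0$params$lambda <- 0
  st0$params$g <- 1
  st0$params$A0 <- tess$areas     # reference = current areas
  ce0 <- cell_energies(st0, "main")
  expect_equal(max(abs(ce0[!ext])), 0, tolerance = 1e-12)
})

test_that("a shared tissue junction contributes twice its tension to the total", {
  st <- make_confined_state(12)
  E1 <- total_energy(st, "main")
  st0 <- st; st0$params$lambda <- 0
  E0 <- total_energy(st0, "main")
  tess <- build_tessellation(st$centers)
  ext <- st$centers$class == "exterior"
  j <- tess$junctions
  tissue <- !ext[j$cell1] & !ext[j$cell2]
  eps <- st$params$edge_eps
  sl <- sqrt(j$length[tissue]^2 + eps^2) - eps
  expect_equal(E1 - E0, 2 * st$params$lambda * sum(sl),
               tolerance = 1e-10)
})

test_that("analytic forces match central finite differences in both phases", {
  for (seed in c(21, 22)) {
    st <- make_confined_state(seed)
    st$params$g <- 0.7; st$params$rho <- 0.5
    mi <- which(st$centers$mobile)
    ids <- mi[seq(1, length(mi), length.out = min(6, length(mi)))]
    for (phase in c("main", "initialization")) {
      Fa <- forces(st, phase)[ids, , drop = FALSE]
      Ff <- fd_forces(st, phase, ids)
      expect_true(all(abs(Fa - Ff) <= pmax(1e-5 * abs(Ff), 2e-7)),
                  info = paste("phase", phase, "seed", seed))
    }
    expect_true(all(forces(st, "main")[!st$centers$mobile, ] == 0))
  }
})

test_that("energy is invariant under rigid translation of all centers", {
  st <- make_confined_state(13)
  E1 <- total_energy(st, "main")
  st$centers$x <- st$centers$x + 1.3
  st$centers$y <- st$centers$y - 0.4
  st$pattern$center <- st$pattern$center + c(1.3, -0.4)
  expect_equal(total_energy(st, "main"), E1, tolerance = 1e-10)
})

test_that("energies rescale as s^2 (elastic) and s (tension) under length scaling", {
  st <- make_confined_state(14)
  s <- 2.5
  st2 <- st
  st2$centers$x <- st$centers$x * s
  st2$centers$y <- st$centers$y * s
  st2$pattern$center <- st$pattern$center * s
  st2$pattern$outer_radius <- st$pattern$outer_radius * s
  st2$domain_side <- st$domain_side * s
  st2$cell_scale <- st$cell_scale * s
  st2$params$A0 <- st$params$A0 * s^2
  st2$params$A0_init <- st$params$A0_init * s^2
  st2$params$A0_total <- st$params$A0_total * s^2
  st2$params$A0_total_init <- st$params$A0_total_init * s^2
  st2$params$edge_eps <- st$params$edge_eps * s
  ## elastic part only
  a <- st; a$params$lambda <- 0
  a2 <- st2; a2$params$lambda <- 0
  expect_equal(total_energy(a2, "main"), s^2 * total_energy(a, "main"),
               tolerance = 1e-9)
  ## tension part only
  b <- st; b$params$K <- 0
  b2 <- st2; b2$params$K <- 0
  expect_equal(total_energy(b2, "main"), s * total_energy(b, "main"),
               tolerance = 1e-9)
})

test_that("gradient flow is monotone and finds the symmetric minimum", {
  st <- make_confined_state(15, jiggle = 0.12)
  E0 <- total_energy(st, "main")
  out <- suppressWarnings(relax(st, "main", dt = 1e-4, tol = 1e-4,
                                max_steps = 800, dt_max = 0.02))
  expect_true(all(diff(out$energy_trace) <= 0))
  expect_lt(out$energy, E0)
  expect_true(is.finite(out$max_force))
  ## relaxing again from the solution returns immediately
  again <- relax(out, "main", dt = 1e-4, tol = 1e-4, max_steps = 800,
                 dt_max = 0.02)
  expect_lte(again$step_count, 1L)
})

test_that("confinement initialization reproduces the protocol structure", {
  st <- cached_init(1)
  cls <- st$centers$class
  expect_equal(st$n_demarcated, 121L)
  expect_equal(sum(cls != "exterior"), 121L)
  expect_true(st$converged)
  expect_true(all(diff(st$energy_trace) <= 0))
  ## boundary cells touch the exterior and are fixed; interior cells move
  expect_true(all(!st$centers$mobile[cls %in% c("boundary", "exterior")]))
  expect_true(all(st$centers$mobile[cls == "interior"]))
  tess <- build_tessellation(st$centers)
  j <- tess$junctions
  ext <- cls == "exterior"
  touches_ext <- unique(c(j$cell1[ext[j$cell2]], j$cell2[ext[j$cell1]]))
  expect_setequal(which(cls == "boundary"),
                  intersect(touches_ext, which(cls != "exterior")))
  ## a pattern too small to hold 20 cells is rejected
  expect_error(initialize_pattern(confinement_spec(outer_radius = 50),
                                  seed = 1),
               "invalid configuration")
})

test_that("the rounded state is an exact equilibrium of the null main phase", {
  st <- cached_init(2)
  F <- forces(st, "main")
  expect_lt(max(abs(F)), 0.01)
  eq <- cached_run(1, 1, 1, 2)
  expect_equal(eq$step_count, 0L)
})

test_that("with zero tension and reference areas reset, the state is force free", {
  st <- cached_init(1)
  tess <- build_tessellation(st$centers)
  st$params$lambda <- 0
  st$params$g <- 1; st$params$rho <- 1; st$params$rho_g <- 1
  st$params$A0 <- tess$areas
  expect_lt(max(abs(forces(st, "main"))), 1e-8)
})

test_that("equilibria are deterministic in the seed", {
  a <- suppressWarnings(run_equilibrium(g = 0.8, rho = 0.7, seed = 31,
                                        max_steps = 4000))
  b <- suppressWarnings(run_equilibrium(g = 0.8, rho = 0.7, seed = 31,
                                        max_steps = 4000))
  expect_identical(a$centers, b$centers)
  expect_identical(a$energy, b$energy)
})

test_that("annular patterns fix the hole and carry two boundary rings", {
  an <- suppressWarnings(
    initialize_pattern(confinement_spec("annulus", outer_radius = 200,
                                        inner_radius = 100),
                       seed = 1, max_steps = 150))
  cls <- an$centers$class
  ctr <- an$pattern$center
  ## class labels are assigned at demarcation (seeded positions)
  pts <- generate_seed_points(25, 693.1, 0.08, 1)
  d0 <- sqrt((pts$x - ctr[1])^2 + (pts$y - ctr[2])^2)
  expect_true(all(cls[d0 < 100] == "exterior"))
  expect_true(all(!an$centers$mobile[cls == "exterior"]))
  ## boundary cells exist on both rims
  bnd <- which(cls == "boundary")
  db <- d0[bnd]
  expect_gt(sum(db < 150), 5)
  expect_gt(sum(db > 150), 5)
})
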