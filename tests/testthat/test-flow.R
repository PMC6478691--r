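p_tab <- fluid_parameters()

test_that("parameter defaults carry the literature values and validate", {
  expect_equal(p_tab$mu, 1.2e-3)
  expect_equal(p_tab$k, 4.4e-18)
  expect_equal(p_tab$K_L, 1.9e-12)
  expect_equal(p_tab$K_B, 2.71e-12)
  expect_equal(p_tab$p_int, -1064)
  expect_error(fluid_parameters(mu = -1), "positive")
  expect_error(fluid_parameters(phi = 0), "phi")
})

test_that("an all-interstitium slab assembles the 7-point Darcy stencil", {
  slab <- generate_validation_geometry("slab", shape = c(5L, 5L, 5L),
                                       voxel_pitch_um = 10)
  m <- prep1(slab)
  sys <- assemble_flow_system(m, openings_by_face(m, list()), p_tab,
    interstitial_bc = list("z-" = 100, "z+" = 0, "y-" = "sealed",
                           "y+" = "sealed", "x-" = "sealed", "x+" = "sealed"))
  A <- sys$A
  Td <- p_tab$k / (p_tab$mu * 10e-6)
  # centre cell: diagonal 6T, six off-diagonals -T
  ctr <- sys$pidx[3, 3, 3]
  row <- A[ctr, ]
  expect_equal(row[ctr], 6 * Td)
  nb <- c(sys$pidx[2, 3, 3], sys$pidx[4, 3, 3], sys$pidx[3, 2, 3],
          sys$pidx[3, 4, 3], sys$pidx[3, 3, 2], sys$pidx[3, 3, 4])
  expect_equal(unname(as.vector(row[nb])), rep(-Td, 6))
  # a sealed-lateral boundary cell keeps only its Darcy neighbours
  expect_equal(sum(row != 0), 7L)
})

test_that("1D Darcy slab matches k dp / (mu L) to 1e-8 relative", {
  slab <- generate_validation_geometry("slab", shape = c(10L, 8L, 8L),
                                       voxel_pitch_um = 10)
  m <- prep1(slab)
  sys <- assemble_flow_system(m, openings_by_face(m, list()), p_tab,
    interstitial_bc = list("z-" = 100, "z+" = 0, "y-" = "sealed",
                           "y+" = "sealed", "x-" = "sealed", "x+" = "sealed"))
  sol <- solve_flow(sys, method = "direct")
  uan <- p_tab$k * 100 / (p_tab$mu * 1e-4)
  expect_lt(abs(mean(sol$u$z, na.rm = TRUE) / uan - 1), 1e-8)
  expect_lt(diff(range(sol$u$z, na.rm = TRUE)), 1e-8 * uan)
})

test_that("the membrane face velocity is K times the transmural difference", {
  sw <- generate_validation_geometry("sandwich", shape = c(9L, 4L, 4L),
                                     voxel_pitch_um = 10, thickness = 3)
  m <- prep1(sw)
  b <- openings_by_face(m, list(blood = c("z-" = "outlet"),
                                lymph = c("z+" = "outlet")))
  sys <- assemble_flow_system(m, b, p_tab)
  mt <- sys$membrane
  expect_true(all(mt$K[mt$class == "blood"] == p_tab$K_B))
  expect_true(all(mt$K[mt$class == "lymph"] == p_tab$K_L))
  # with cell pressures pinned at (p_B, p_int) the face flux is
  # K_B * (2000 - (-1064)) = 8.30e-9 m/s
  x <- numeric(length(sys$b))
  x[mt$p_lum[mt$class == "blood"]] <- 2000
  x[mt$p_int[mt$class == "blood"]] <- -1064
  ns <- asNamespace("pulmolymph")
  fv <- ns$face_velocities(sys, x, mt$axis[mt$class == "blood"][1])
  u <- fv[mt$fpos[mt$class == "blood"][1]]
  expect_equal(abs(u), 2.71e-12 * 3064, tolerance = 1e-12)
})

test_that("grids without lumen cells allocate no Stokes unknowns", {
  slab <- generate_validation_geometry("slab", shape = c(6L, 6L, 6L))
  m <- prep1(slab)
  sys <- assemble_flow_system(m, openings_by_face(m, list()), p_tab)
  expect_equal(sys$NU, 0L)
  expect_equal(length(sys$b), sys$NI)
})

test_that("a fully sealed system without pressure reference is rejected", {
  slab <- generate_validation_geometry("slab", shape = c(6L, 6L, 6L))
  m <- prep1(slab)
  expect_error(assemble_flow_system(
    m, openings_by_face(m, list()), p_tab,
    interstitial_bc = stats::setNames(as.list(rep("sealed", 6)),
                                      c("z-", "z+", "y-", "y+", "x-", "x+"))),
    "unforced")
})

test_that("membrane sandwich matches the series-resistance closed form", {
  sw <- generate_validation_geometry("sandwich", shape = c(30L, 16L, 16L),
                                     voxel_pitch_um = 5, thickness = 10)
  m <- prep1(sw)
  b <- openings_by_face(m, list(blood = c("z-" = "outlet"),
                                lymph = c("z+" = "outlet")))
  sys <- assemble_flow_system(m, b, p_tab,
    interstitial_bc = list("y-" = "sealed", "y+" = "sealed",
                           "x-" = "sealed", "x+" = "sealed"))
  sol <- solve_flow(sys, method = "direct", max_backflow_iters = 0L)
  area <- 16 * 16 * (5e-6)^2
  Rtot <- 1 / p_tab$K_B + p_tab$mu * 50e-6 / p_tab$k + 1 / p_tab$K_L
  fan <- (p_tab$p_B - p_tab$p_L) / Rtot
  expect_lt(abs(sol$Q_L_in / area / fan - 1), 0.02)
  expect_lt(abs(sol$Q_B_out / area / fan - 1), 0.02)
  # discrete conservation on an analytic geometry
  for (dmn in sol$mass_balance)
    expect_lt(unname(dmn["relative"]), 1e-8)
})

test_that("scaling all drivers by two scales all fluxes by two", {
  case <- std_flow_case()
  p2 <- fluid_parameters(p_int = 2 * p_tab$p_int, u_L = 2 * p_tab$u_L,
                         p_L = 2 * p_tab$p_L, u_B = 2 * p_tab$u_B,
                         p_B = 2 * p_tab$p_B)
  s1 <- solve_flow(assemble_flow_system(case$model, case$boundaries, p_tab),
                   max_backflow_iters = 0L)
  s2 <- solve_flow(assemble_flow_system(case$model, case$boundaries, p2),
                   max_backflow_iters = 0L)
  expect_equal(s2$Q_L_in / s1$Q_L_in, 2, tolerance = 1e-6)
  expect_equal(s2$Q_B_out / s1$Q_B_out, 2, tolerance = 1e-6)
})

test_that("backflow at an outlet is suppressed to a wall", {
  # straight tube with a high-pressure side arm: the arm outlet initially
  # draws fluid inward and must end up sealed
  a <- array(1L, c(32, 20, 20))
  ns <- asNamespace("pulmolymph")
  a <- ns$rasterize_brush(a, cbind(1:32, 10, 10), 3, 2L, clamp = TRUE)
  a <- ns$rasterize_brush(a, cbind(16, 10:20, 10), 2, 2L, clamp = TRUE)
  vol <- label_volume(a, 10)
  m <- prep1(vol)
  b <- openings_by_face(m, list(blood = c("z-" = "inlet", "z+" = "outlet",
                                          "y+" = "outlet")))
  pp <- fluid_parameters(K_B = 1e-30, K_L = 1e-30)
  sys <- assemble_flow_system(m, b, pp,
                              outlet_pressures = c("z+" = 0, "y+" = 1e4))
  sol <- solve_flow(sys, tol = 1e-10)
  expect_gt(sol$suppressed_outlet_faces, 0L)
  expect_true(sol$backflow_converged)
  ot <- sol$system$outlets
  expect_true(all(ot$out_sign * sol$x[ot$uidx] >
                    -1e-10 * max(abs(sol$x[ot$uidx]))))
})

test_that("the coupled synthetic VOI drains blood to interstitium to lymph", {
  case <- std_flow_case()
  sol <- solve_flow(assemble_flow_system(case$model, case$boundaries, p_tab))
  expect_gt(sol$Q_B_out, 0)
  expect_gt(sol$Q_L_in, 0)
  for (dmn in sol$mass_balance)
    expect_lt(unname(dmn["relative"]), 1e-8)
  # pressures bounded by the driving conditions (small viscous margins)
  expect_gt(min(sol$p, na.rm = TRUE), p_tab$p_L - 50)
  expect_lt(max(sol$p, na.rm = TRUE), p_tab$p_B + 50)
})

test_that("shrinkage-scaled geometry keeps flow directions, changes flux", {
  case <- std_flow_case()
  g <- case$g
  m2 <- prepare_model_volume(g$volume, voi = NULL, upsample = 1L,
                             median_window = 1L, shrinkage_scale = 2)
  b2 <- identify_vessel_openings(m2)
  s1 <- solve_flow(assemble_flow_system(case$model, case$boundaries, p_tab),
                   max_backflow_iters = 0L)
  s2 <- solve_flow(assemble_flow_system(m2, b2, p_tab),
                   max_backflow_iters = 0L)
  num <- s1$u$z * s2$u$z + s1$u$y * s2$u$y + s1$u$x * s2$u$x
  n1 <- sqrt(s1$u$z^2 + s1$u$y^2 + s1$u$x^2)
  n2 <- sqrt(s2$u$z^2 + s2$u$y^2 + s2$u$x^2)
  sel <- !is.na(num) & n1 > stats::quantile(n1, 0.5, na.rm = TRUE) & n2 > 0
  cosang <- (num / (n1 * n2))[sel]
  expect_gt(stats::quantile(cosang, 0.05), 0.99)
  expect_gt(abs(s2$Q_L_in / s1$Q_L_in - 1), 0.5)  # flux magnitude changes
})

test_that("exported fields round-trip through legacy VTK", {
  case <- std_flow_case()
  sol <- solve_flow(assemble_flow_system(case$model, case$boundaries, p_tab))
  f <- tempfile(fileext = ".vtk")
  export_fields(sol, f)
  rt <- read_vtk_fields(f)
  pz <- sol$p; pz[is.na(pz)] <- 0
  expect_equal(rt$pressure, pz, tolerance = 1e-9)
  expect_equal(dim(rt$velocity$z), dim(sol$p))
  expect_true(all(rt$domain %in% 0:3))
  # empty solutions are refused
  fake <- sol; fake$p <- array(NA_real_, dim(sol$p))
  expect_error(export_fields(fake, tempfile(fileext = ".vtk")), "empty")
})
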