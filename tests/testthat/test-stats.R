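test_that("separated samples give U = 0 and exact p = 0.1", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")
})

test_that("identical samples give the central U and p = 1", {
  mw <- mann_whitney_u(c(5, 7, 9), c(5, 7, 9))
  expect_equal(mw$U, 9 / 2)
  expect_equal(mw$p, 1)
})

test_that("exact p equals brute-force enumeration on random data", {
  set.seed(101)
  for (rep in 1:25) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- sample(1:200, n1); y <- sample(setdiff(1:200, x), n2)
    expect_equal(mann_whitney_u(x, y)$p, exact_p_enum(x, y))
  }
})

test_that("our test agrees with the base-R implementation", {
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(9)
    expect_equal(mann_whitney_u(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # tie-corrected continuity-corrected normal approximation
  for (rep in 1:10) {
    x <- round(rnorm(15), 1); y <- round(rnorm(14), 1)
    expect_equal(mann_whitney_u(x, y)$p,
                 suppressWarnings(stats::wilcox.test(
                   x, y, exact = FALSE, correct = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("exact and approximate p agree within 0.02 at n = 12", {
  set.seed(77)
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    pe <- mann_whitney_u(x, y)$p
    pa <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE)$p.value)
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("U_xy + U_yx = n1 n2 on random inputs", {
  set.seed(31)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(11)
    expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U,
                 length(x) * length(y))
  }
  expect_error(mann_whitney_u(numeric(), 1:3), "empty")
})

test_that("distance regression recovers exact linear relations", {
  x <- c(1, 2, 3, 5, 8)
  r1 <- correlate_with_distance(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_equal(r1$slope, 2)
  expect_equal(r1$intercept, 1)
  r2 <- correlate_with_distance(x, -x)
  expect_equal(r2$r, -1)
  expect_equal(r2$abs_r, 1)
  # exclusions counted; degenerate inputs rejected
  r3 <- correlate_with_distance(c(x, 9), c(2 * x, NA),
                                excluded = c(rep(FALSE, 5), TRUE))
  expect_equal(r3$n_excluded, 1L)
  expect_error(correlate_with_distance(1:2, 1:2), "fewer than 3")
  expect_error(correlate_with_distance(1:5, rep(1, 5)), "zero variance")
})

test_that("group comparison flags a shifted measure, spares an equal one", {
  set.seed(12)
  mk <- function(vf_shift) data.frame(
    volume_fraction = rnorm(22, 0.03 + vf_shift, 0.004),
    sa_per_tissue_volume_per_um = rnorm(22, 0.01, 0.002),
    fractal_dimension = rnorm(22, 2.1, 0.2),
    branch_count = rpois(22, 20),
    junction_count = rpois(22, 6),
    mean_tortuosity = rnorm(22, 1.15, 0.05))
  ctrl <- mk(0)
  dis <- mk(0.02)
  cmp <- compare_groups(ctrl, dis)
  expect_lt(cmp$p[cmp$measure == "volume_fraction"], 0.01)
  expect_gt(cmp$p[cmp$measure == "mean_tortuosity"], 0.05)
  same <- compare_groups(ctrl, ctrl)
  expect_true(all(same$p == 1))
  cb <- compare_groups(ctrl, dis, bonferroni = TRUE)
  expect_true(all(cb$p_bonferroni >= cb$p))
  expect_error(compare_groups(ctrl[0, ], dis), "non-empty")
})

test_that("sensitivity with factor 1 reports exactly zero change", {
  sw <- generate_validation_geometry("sandwich", shape = c(15L, 6L, 6L),
                                     voxel_pitch_um = 10, thickness = 5)
  m <- prep1(sw)
  b <- openings_by_face(m, list(blood = c("z-" = "outlet"),
                                lymph = c("z+" = "outlet")))
  rep1 <- run_sensitivity(m, b, fluid_parameters(), factors = 1,
                          targets = "K_L", refine = FALSE)
  expect_equal(rep1$runs$pct_change, 0)
  rep2 <- run_sensitivity(m, b, fluid_parameters(), factors = 1,
                          targets = "K_L", refine = FALSE)
  expect_identical(rep1$runs, rep2$runs)   # deterministic
})

test_that("sandwich K_L x100 matches the series-resistance prediction", {
  p <- fluid_parameters()
  sw <- generate_validation_geometry("sandwich", shape = c(30L, 12L, 12L),
                                     voxel_pitch_um = 5, thickness = 10)
  m <- prep1(sw)
  b <- openings_by_face(m, list(blood = c("z-" = "outlet"),
                                lymph = c("z+" = "outlet")))
  sys <- assemble_flow_system(m, b, p,
    interstitial_bc = list("y-" = "sealed", "y+" = "sealed",
                           "x-" = "sealed", "x+" = "sealed"))
  base <- solve_flow(sys, method = "direct", max_backflow_iters = 0L)
  p100 <- p; p100$K_L <- p$K_L * 100
  s100 <- solve_flow(assemble_flow_system(m, b, p100,
    interstitial_bc = list("y-" = "sealed", "y+" = "sealed",
                           "x-" = "sealed", "x+" = "sealed")),
    method = "direct", max_backflow_iters = 0L)
  R0 <- 1 / p$K_B + p$mu * 50e-6 / p$k + 1 / p$K_L
  R1 <- 1 / p$K_B + p$mu * 50e-6 / p$k + 1 / (100 * p$K_L)
  expect_lt(abs((s100$Q_L_in / base$Q_L_in) / (R0 / R1) - 1), 0.03)
})

test_that("synthetic cohorts recover the negative distance gradient", {
  coh <- generate_cohort(cohort_base_spec(), n_voi = 25L, gradient = -8e-6,
                         noise_sd = 0.005, seed = 61L)
  vf <- vapply(coh$volumes, function(v)
    measure_volume_surface(v, smooth = FALSE)$volume_fraction, numeric(1))
  reg <- correlate_with_distance(coh$truth$distance_um, vf)
  expect_lt(reg$r, 0)
  expect_lt(reg$p, 0.01)
})
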