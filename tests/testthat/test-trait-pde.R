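# coarse grid keeps the unit tests fast; the acceptance suite exercises the
# production grid
coarse_grid <- function(params) trait_grid(params, n_points = 201L)

test_that("the mutation operator conserves mass exactly under no-flux boundaries", {
  params <- sim_params(selection_on = TRUE)
  grid <- coarse_grid(params)
  set.seed(11)
  q <- abs(rnorm(grid$n_points))
  d2 <- graphevo:::second_diff_noflux(q, grid$ds)
  expect_equal(sum(d2) * grid$ds, 0, tolerance = 1e-12 * max(abs(q)) / grid$ds)
})

test_that("a logistic point mass at the optimum is stationary without mutation or migration", {
  params <- sim_params(m = 0, mu = 0, selection_on = TRUE)
  grid <- coarse_grid(params)
  i_opt <- which.min(abs(grid$s - params$theta))  # +theta is on the grid
  n <- matrix(0, grid$n_points, 2)
  # habitat II (optimum +theta): mass b(theta_II) * K = K concentrated at the optimum
  n[i_opt, 2] <- params$K / grid$ds
  i_optI <- which.min(abs(grid$s + params$theta))
  n[i_optI, 1] <- params$K / grid$ds
  rhs <- pde_rhs_two_habitat(n, 0, params, grid)
  expect_equal(max(abs(rhs)) / max(n), 0, tolerance = 1e-12)
})

test_that("the dynamics commute with the habitat swap s -> -s, I <-> II", {
  params <- sim_params(m = 0.2, selection_on = TRUE)
  grid <- coarse_grid(params)
  set.seed(12)
  base <- abs(rnorm(grid$n_points)) * exp(-grid$s^2)
  n <- cbind(base, rev(base))   # symmetric state: n_I(s) = n_II(-s)
  d <- pde_rhs_two_habitat(n, -0.3, params, grid)
  expect_equal(d[, 1], rev(d[, 2]), tolerance = 1e-10)
})

test_that("assortativity limits decouple or fully mix the migrant streams", {
  params <- sim_params(m = 0.4, selection_on = TRUE)
  grid <- coarse_grid(params)
  n <- initial_density(grid, params, 2L)
  n[, 2] <- n[, 2] * 1.3  # break symmetry so cross terms are visible
  bI <- birth_profile(grid$s, -params$theta, params)
  bII <- birth_profile(grid$s, params$theta, params)
  N <- graphevo:::grid_mass(n, grid$ds)
  D <- 0.5 * params$mu * params$sigma_mu^2
  # r = 1: habitat I evolves as if habitat II did not exist
  d1 <- pde_rhs_two_habitat(n, 1, params, grid)
  solo <- n[, 1] * (bI * (1 - params$m) - N[1] / params$K) +
    D * graphevo:::second_diff_noflux(bI * n[, 1], grid$ds) +
    params$m * bI * n[, 1]
  expect_equal(d1[, 1], solo, tolerance = 1e-12)
  # r = -1: the returning stream is entirely cross-habitat
  dm1 <- pde_rhs_two_habitat(n, -1, params, grid)
  cross <- n[, 1] * (bI * (1 - params$m) - N[1] / params$K) +
    D * graphevo:::second_diff_noflux(bI * n[, 1], grid$ds) +
    params$m * bII * n[, 2]
  expect_equal(dm1[, 1], cross, tolerance = 1e-12)
})

test_that("the graph form reduces to the two-habitat form on a balanced 4-cycle", {
  # 4-cycle labeled (I, I, II, II): every vertex has one like and one unlike
  # neighbour, r_theta = 0, degrees regular -- the mean-field is exact here
  params <- sim_params(m = 0.3, selection_on = TRUE)
  grid <- coarse_grid(params)
  g <- cycle(4)
  theta_v <- c(-0.5, -0.5, 0.5, 0.5)
  expect_equal(habitat_assortativity(g, theta_v), 0)
  nh <- initial_density(grid, params, 2L)
  nh[, 1] <- nh[, 1] * exp(-(grid$s + 0.3)^2)  # asymmetric test state
  nh[, 2] <- nh[, 2] * exp(-(grid$s - 0.1)^2)
  ng <- nh[, c(1, 1, 2, 2)]
  d_graph <- pde_rhs_graph(ng, g, theta_v, params, grid)
  d_two <- pde_rhs_two_habitat(nh, 0, params, grid)
  expect_equal(d_graph[, 1], d_two[, 1], tolerance = 1e-10)
  expect_equal(d_graph[, 2], d_two[, 1], tolerance = 1e-10)
  expect_equal(d_graph[, 3], d_two[, 2], tolerance = 1e-10)
})

test_that("steady states isolate adaptation below the threshold and lose it above", {
  params_lo <- sim_params(m = 0.1, selection_on = TRUE)
  grid <- coarse_grid(params_lo)
  lo <- two_habitat_steady_state(params_lo, r_theta = 0, grid = grid, tol = 1e-7)
  expect_gt(lo$qst_s, 0.3)
  expect_lt(lo$mean_s[1], -0.2)   # habitat I adapted towards -theta
  expect_gt(lo$mean_s[2], 0.2)
  expect_true(all(lo$n >= 0))
  params_hi <- sim_params(m = 0.9, selection_on = TRUE)
  hi <- two_habitat_steady_state(params_hi, r_theta = 0, grid = grid, tol = 1e-7)
  expect_lt(hi$qst_s, 1e-2)
  # demographic equilibrium above threshold: bK(1 - p theta^2) per habitat
  expect_equal(hi$N, rep(112.5, 2), tolerance = 0.03)
})

test_that("steady-state differentiation is monotone in assortativity below threshold", {
  params <- sim_params(m = 0.25, selection_on = TRUE)
  grid <- coarse_grid(params)
  q <- vapply(c(-0.5, 0, 0.5), function(r)
    two_habitat_steady_state(params, r, grid = grid, tol = 1e-7)$qst_s, numeric(1))
  expect_true(all(diff(q) > 0))
})

test_that("m = 0 steady state is fully adapted with N = bK per habitat", {
  params <- sim_params(m = 0, selection_on = TRUE)
  grid <- coarse_grid(params)
  ss <- two_habitat_steady_state(params, r_theta = 0, grid = grid, tol = 1e-7)
  expect_equal(ss$N, rep(150, 2), tolerance = 0.02)
  expect_equal(ss$mean_s, c(-0.5, 0.5), tolerance = 0.02)
  expect_gt(ss$qst_s, 0.95)
})
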