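test_that("birth rate follows the stabilising-selection parabola, clamped at zero", {
  ps <- sim_params(p = 1, theta = 0.5, selection_on = TRUE)
  expect_equal(birth_rate(0.5, 0.5, ps), 1)          # at the optimum: maximum b
  expect_equal(birth_rate(0, 0.5, ps), 0.75)         # b(1 - p * 0.5^2)
  expect_equal(birth_rate(3, 0.5, ps), 0)            # clamped, not negative
  psn <- sim_params(selection_on = FALSE)
  expect_equal(birth_rate(c(-2, 0, 2), 0.5, psn), rep(1, 3))  # neutral: constant
})

test_that("death rate is local density over carrying capacity", {
  expect_equal(death_rate(0, 150), 0)
  expect_equal(death_rate(150, 150), 1)
  expect_equal(death_rate(300, 150), 2)
})

test_that("mutation displaces each component independently with the right variance", {
  ps0 <- sim_params(mu = 0)
  x <- rnorm(50)
  set.seed(1)
  expect_identical(mutate_traits(x, ps0), x)
  ps1 <- sim_params(mu = 1, sigma_mu = 0.05)
  set.seed(2)
  disp <- mutate_traits(rep(0, 1e5), ps1)
  expect_equal(var(disp), 0.05^2, tolerance = 0.05)
  # intermediate mu: displacement variance is mu * sigma^2
  psh <- sim_params(mu = 0.1, sigma_mu = 0.05)
  set.seed(3)
  disp <- mutate_traits(rep(0, 2e5), psh)
  expect_equal(mean(disp != 0), 0.1, tolerance = 0.05)
  expect_equal(var(disp), 0.1 * 0.05^2, tolerance = 0.05)
})

test_that("offspring migration is a one-step random walk taken with probability m", {
  g <- star7()
  expect_equal(choose_migration_target(3, g, sim_params(m = 0)), 3)
  k2 <- complete(2)
  set.seed(4)
  expect_true(all(replicate(50, choose_migration_target(1, k2, sim_params(m = 1))) == 2))
  # from the star centre at m = 0.5 each leaf receives ~ 1/12 of draws
  set.seed(5)
  draws <- replicate(2e4, choose_migration_target(1, g, sim_params(m = 0.5)))
  expect_equal(mean(draws == 1), 0.5, tolerance = 0.05)
  freq_leaf <- tabulate(draws, 7)[2:7] / 2e4
  expect_equal(freq_leaf, rep(1 / 12, 6), tolerance = 0.25)
})

test_that("gillespie step draws exponential waiting times at the total event rate", {
  g <- complete(2)
  ps <- sim_params(K = 10, m = 0, mu = 0)
  st <- population_state(vertex = c(1, 2), u = matrix(0, 2, 1))
  # frozen two-individual state: total rate = 2 b + 2 * (1/K)
  total <- 2 * 1 + 2 * (1 / 10)
  set.seed(6)
  waits <- replicate(3000, {
    out <- gillespie_step(st, g, params = ps)
    out$t
  })
  expect_equal(mean(waits), 1 / total, tolerance = 0.05)
})

test_that("gillespie event frequencies match the rate ratios", {
  g <- complete(2)
  ps <- sim_params(K = 2, m = 0, mu = 0)
  st <- population_state(vertex = c(1, 1), u = matrix(0, 2, 1))
  # vertex 1 holds 2 individuals: birth rate 2b = 2, death rate 2 * (2/2) = 2
  set.seed(7)
  ev <- replicate(4000, attr(gillespie_step(st, g, params = ps), "event"))
  expect_equal(mean(ev == "birth"), 0.5, tolerance = 0.05)
})

test_that("a death of the last individual signals extinction", {
  g <- complete(2)
  ps <- sim_params(K = 0.01, m = 0, mu = 0)  # death rate overwhelms birth
  st <- population_state(vertex = 1L, u = matrix(0, 1, 1))
  set.seed(8)
  out <- gillespie_step(st, g, params = ps)
  expect_identical(attr(out, "event"), "death")
  expect_true(attr(out, "extinct"))
  expect_length(out$vertex, 0L)
  expect_error(gillespie_step(out, g, params = ps), "extinct")
})

test_that("population counts track stored individuals and change by one per event", {
  g <- path_graph(3)
  ps <- sim_params(K = 20, m = 0.3, mu = 0.5, d_neutral = 2)
  st <- population_state(vertex = rep(1:3, each = 5), u = matrix(rnorm(30), 15, 2))
  set.seed(9)
  for (i in 1:200) {
    n_before <- length(st$vertex)
    st <- gillespie_step(st, g, params = ps)
    expect_equal(abs(length(st$vertex) - n_before), 1L)
    expect_equal(state_counts(st, 3), tabulate(st$vertex, 3))
    expect_equal(nrow(st$u), length(st$vertex))
  }
})

test_that("simulated single-vertex population fluctuates around bK", {
  g1 <- as_spatial_graph(make_empty_graph(1, directed = FALSE))
  tr <- simulate_ibm(g1, sim_params(m = 0, d_neutral = 1), t_end = 300, seed = 17)
  expect_false(tr$extinct)
  burn <- tr$time > 50
  expect_equal(mean(tr$N[burn, 1]), 150, tolerance = 0.05)
})

test_that("fixed seeds reproduce trajectories bit for bit", {
  g <- star7()
  ps <- sim_params(m = 0.2, d_neutral = 3)
  a <- simulate_ibm(g, ps, t_end = 20, seed = 33, final_traits = TRUE)
  b <- simulate_ibm(g, ps, t_end = 20, seed = 33, final_traits = TRUE)
  expect_identical(a$N, b$N)
  expect_identical(a$u_mean, b$u_mean)
  expect_identical(a$final_state, b$final_state)
  c_ <- simulate_ibm(g, ps, t_end = 20, seed = 34)
  expect_false(identical(a$N, c_$N))
})

test_that("without mutation a single founder lineage stays monomorphic", {
  g1 <- as_spatial_graph(make_empty_graph(1, directed = FALSE))
  ps <- sim_params(K = 1, m = 0, mu = 0, d_neutral = 4)
  tr <- simulate_ibm(g1, ps, t_end = 40, seed = 12, final_traits = TRUE)
  if (!tr$extinct) {
    u <- tr$final_state$u
    for (j in seq_len(ncol(u))) expect_equal(var(u[, j]), 0)
  }
  # and the recorded within-vertex variance is identically zero
  expect_true(all(tr$u_var[!is.na(tr$u_var)] == 0))
})

test_that("under selection without migration local means converge to the optima", {
  # adaptation from the founding trait 0 to the optima proceeds by
  # mutation-sized steps; a long horizon is needed for convergence
  g2 <- complete(2)
  th <- c(-0.5, 0.5)
  ps <- sim_params(m = 0, selection_on = TRUE, d_neutral = 1)
  tr <- simulate_ibm(g2, ps, theta_v = th, t_end = 800, seed = 55)
  keep <- tr$time > 600
  expect_equal(mean(tr$s_mean[keep, 1]), -0.5, tolerance = 0.15)
  expect_equal(mean(tr$s_mean[keep, 2]), 0.5, tolerance = 0.15)
})

test_that("selection-off ensemble mean population matches the deterministic equilibrium", {
  g <- star7()
  ps <- sim_params(m = 0.5, d_neutral = 1)
  eq <- solve_equilibrium(g, ps)
  means <- vapply(1:3, function(r) {
    tr <- simulate_ibm(g, ps, t_end = 150, seed = 60 + r)
    mean(tr$N[tr$time > 50, ])
  }, numeric(1))
  expect_equal(mean(means), eq$N_bar, tolerance = 0.05)
})
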