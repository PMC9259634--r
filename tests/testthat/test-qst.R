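test_that("Q_ST hits the exact limits and the hand-computed example", {
  expect_equal(qst(list(c(0, 0), c(1, 1))), 1)     # all variance between vertices
  expect_equal(qst(list(c(0, 1), c(0, 1))), 0)     # all variance within
  # vertices {0,2} and {1,3}: sigma2_B = 0.25, sigma2_W = 1
  expect_equal(qst(list(c(0, 2), c(1, 3))), 0.2)
  expect_equal(qst(list(c(0, 2), c(1, 3))), qst_oracle(list(c(0, 2), c(1, 3))))
})

test_that("Q_ST is undefined for identical values and needs two occupied vertices", {
  expect_warning(v <- qst(list(c(1, 1), c(1, 1))), "undefined")
  expect_true(is.na(v))
  expect_error(qst(list(numeric(0), c(1, 2))), "two vertices")
  # empty vertices are excluded, not treated as zeros
  expect_equal(qst(list(c(0, 2), numeric(0), c(1, 3))), 0.2)
})

test_that("Q_ST is invariant under shift and scale and monotone in between-variance", {
  set.seed(31)
  for (i in 1:20) {
    sample <- lapply(1:4, function(j) rnorm(sample(2:8, 1), mean = j))
    q <- qst(sample)
    expect_gte(q, 0); expect_lte(q, 1)
    expect_equal(qst(lapply(sample, function(x) x + 3.7)), q, tolerance = 1e-12)
    expect_equal(qst(lapply(sample, function(x) x * -2.5)), q, tolerance = 1e-12)
  }
  # spreading the vertex means apart (fixed within-variance) raises Q_ST
  base <- list(c(-1, 1), c(-1, 1))
  spread <- function(delta) qst(list(c(-1, 1) - delta, c(-1, 1) + delta))
  qs <- vapply(c(0.5, 1, 2, 4), spread, numeric(1))
  expect_true(all(diff(qs) > 0))
})

test_that("trait-averaged Q_ST reduces to the single-trait value and averages correctly", {
  s <- list(c(0, 2), c(1, 3))
  expect_equal(qst_mean(list(s)), qst(s))
  s2 <- list(c(0, 0), c(1, 1))   # qst 1
  s3 <- list(c(0, 2), c(1, 3))   # qst 0.2
  expect_equal(qst_mean(list(s2, s3)), 0.6)
  # undefined traits are dropped with a warning
  s4 <- list(c(1, 1), c(1, 1))
  expect_warning(v <- qst_mean(list(s3, s4)), "undefined")
  expect_equal(v, 0.2)
})

test_that("averaging over many independent traits shrinks the variance of mean Q_ST", {
  set.seed(77)
  draw_qst <- function(d) {
    samples <- lapply(seq_len(d), function(j) lapply(1:5, function(v) rnorm(6, mean = rnorm(1))))
    qst_mean(samples)
  }
  single <- replicate(40, draw_qst(1))
  avg25 <- replicate(40, draw_qst(25))
  expect_lt(var(avg25), var(single) / 10)
})

test_that("windowed trajectory summaries average the closing window only", {
  # hand-built trajectory: 10 records, constant traits, sawtooth N on vertex 1
  saw <- c(100, 120, 140, 160, 180, 100, 120, 140, 160, 180)
  traj <- structure(list(
    time = 1:10,
    N = cbind(saw, rep(100, 10)),
    s_mean = NULL, s_var = NULL,
    u_mean = array(rep(c(0, 1), each = 10), dim = c(10, 2, 1)),
    u_var = array(0.5, dim = c(10, 2, 1)),
    extinct = FALSE, t_final = 10,
    params = sim_params(), graph = NULL
  ), class = "ibm_trajectory")
  s_all <- time_averaged_summary(traj, window = 9)
  expect_equal(s_all$N_bar, mean((saw + 100) / 2))
  s_last <- time_averaged_summary(traj, window = 0)
  expect_equal(s_last$N_bar, (180 + 100) / 2)
  expect_equal(s_last$n_records, 1L)
  # constant trait structure: qst equals the instantaneous value at any window
  q_inst <- qst_from_expected <- 0.25 / (0.25 + 0.5)
  expect_equal(s_all$qst_u, q_inst)
  expect_equal(s_last$qst_u, q_inst)
})

test_that("extinct trajectories are flagged and yield missing summaries", {
  traj <- structure(list(
    time = 1:3, N = matrix(0, 3, 2), s_mean = NULL, s_var = NULL,
    u_mean = array(NA_real_, c(3, 2, 1)), u_var = array(NA_real_, c(3, 2, 1)),
    extinct = TRUE, t_final = 2.5, params = sim_params(), graph = NULL
  ), class = "ibm_trajectory")
  s <- time_averaged_summary(traj, window = 1)
  expect_true(s$extinct)
  expect_true(is.na(s$qst_u))
})
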