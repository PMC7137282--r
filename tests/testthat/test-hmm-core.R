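test_that("emission log-likelihoods equal the Bernoulli product", {
  n <- 4
  p <- hmm_params(matrix(0.5, 2, n), matrix(0.5, 2, 2), c(0.5, 0.5))
  le <- emission_loglik(p, matrix(c(1, 0, 1, 0), 1))
  expect_equal(le[1, ], rep(n * log(0.5), 2))

  eps <- 1e-6
  p2 <- hmm_params(matrix(c(1 - eps, eps), 1), matrix(1, 1, 1), 1)
  le2 <- emission_loglik(p2, matrix(c(1, 0), 1))
  expect_equal(le2[1, 1], 2 * log(1 - eps), tolerance = 1e-9)

  set.seed(12)
  p3 <- rand_hmm(4, 3)
  obs <- rand_obs(6, 3)
  le3 <- emission_loglik(p3, obs)
  direct <- sapply(1:4, function(s)
    sapply(1:6, function(t)
      log(prod(ifelse(obs[t, ] == 1, p3$emission[s, ], 1 - p3$emission[s, ])))))
  expect_equal(le3, direct, tolerance = 1e-12)
})

test_that("forward-backward matches exhaustive path enumeration", {
  p1 <- hmm_params(matrix(c(0.3, 0.8), 1), matrix(1, 1, 1), 1)
  obs1 <- matrix(rbinom(10, 1, 0.5), 5)
  fb1 <- forward_backward(p1, obs1)
  expect_equal(fb1$loglik, sum(emission_loglik(p1, obs1)))
  expect_true(all(fb1$posterior == 1))

  set.seed(77)
  for (i in 1:30) {
    k <- sample(2:4, 1); n <- sample(1:3, 1); T <- sample(2:7, 1)
    p <- rand_hmm(k, n)
    obs <- rand_obs(T, n)
    fb <- forward_backward(p, obs)
    expect_equal(fb$loglik, enum_loglik(p, obs), tolerance = 1e-10)
    expect_lt(max(abs(rowSums(fb$posterior) - 1)), 1e-9)
  }
})

test_that("structural zeros exclude their paths from the likelihood", {
  set.seed(99)
  for (i in 1:15) {
    k <- 3
    zm <- matrix(FALSE, k, k)
    zm[1, 3] <- zm[3, 2] <- TRUE
    p <- rand_hmm(k, 2, zero_mask = zm)
    obs <- rand_obs(6, 2)
    expect_equal(forward_backward(p, obs)$loglik, enum_loglik(p, obs),
                 tolerance = 1e-10)
    expect_equal(viterbi(p, obs)$logprob, enum_best(p, obs), tolerance = 1e-12)
  }
})

test_that("Viterbi finds the enumerated optimum and breaks ties low", {
  set.seed(31)
  for (i in 1:30) {
    k <- sample(2:4, 1); n <- sample(1:3, 1); T <- sample(2:7, 1)
    p <- rand_hmm(k, n)
    obs <- rand_obs(T, n)
    expect_equal(viterbi(p, obs)$logprob, enum_best(p, obs), tolerance = 1e-12)
  }
  # two exchangeable states: every path has the same probability; the
  # low-index tie-break must pick state 1 throughout
  p_tie <- hmm_params(matrix(0.5, 2, 2), matrix(0.5, 2, 2), c(0.5, 0.5))
  vt <- viterbi(p_tie, rand_obs(6, 2))
  expect_equal(vt$path, rep(1L, 6))
})

test_that("near-deterministic emissions recover a planted path", {
  set.seed(8)
  k <- 3; n <- 3; T <- 200
  eps <- 1e-6
  E <- matrix(eps, k, n); E[1, 1] <- E[2, 2] <- E[3, 3] <- 1 - eps
  A <- matrix(0.1, k, k); diag(A) <- 0.8
  p <- hmm_params(E, A, rep(1/3, 3))
  planted <- sample_path <- integer(T)
  s <- 1L
  for (t in 1:T) {
    planted[t] <- s
    if (runif(1) < 0.2) s <- sample(1:3, 1)
  }
  obs <- matrix(0L, T, n)
  obs[cbind(1:T, planted)] <- 1L
  expect_equal(viterbi(p, obs)$path, planted)
})

test_that("fully clamped models pass through Baum-Welch untouched", {
  set.seed(4)
  p <- rand_hmm(3, 2)
  p$free_transition[] <- FALSE
  p$free_emission[] <- FALSE
  p$free_initial[] <- FALSE
  obs <- rand_obs(50, 2)
  fit <- baum_welch(p, obs, max_iter = 20, tol = 1e-6)
  expect_identical(fit$params$emission, p$emission)
  expect_identical(fit$params$transition, p$transition)
  expect_identical(fit$params$initial, p$initial)
  expect_equal(diff(range(fit$loglik_trace)), 0)
})

test_that("EM log-likelihood is monotone and clamped entries stay bit-identical", {
  set.seed(21)
  k <- 4; n <- 3
  zm <- matrix(FALSE, k, k); zm[1, 4] <- TRUE
  p <- rand_hmm(k, n, zero_mask = zm)
  # clamp emissions of states 1-2 and the transitions out of state 1
  p$free_emission[1:2, ] <- FALSE
  p$free_transition[1, ] <- FALSE
  obs <- rand_obs(2000, n)
  fit <- baum_welch(p, obs, max_iter = 100, tol = 0)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_identical(fit$params$emission[1:2, ], p$emission[1:2, ])
  expect_identical(fit$params$transition[1, ], p$transition[1, ])
  expect_identical(fit$params$transition[zm], 0)
  expect_lt(max(abs(rowSums(fit$params$transition) - 1)), 1e-9)
})

test_that("a fully free 2-state model recovers its generating emissions", {
  truth <- hmm_params(matrix(c(0.9, 0.2, 0.15, 0.8), 2),
                      matrix(c(0.95, 0.10, 0.05, 0.90), 2),
                      c(0.5, 0.5))
  g <- bin_grid(c(sim = 5e4 * 200), 200)
  sim <- simulate_class_matrix(truth, g, seed = 303)
  init <- hmm_params(matrix(c(0.7, 0.4, 0.3, 0.6), 2),
                     matrix(c(0.8, 0.3, 0.2, 0.7), 2),
                     c(0.5, 0.5))
  fit <- baum_welch(init, unname(sim$classes), max_iter = 200, tol = 1e-6)
  E <- fit$params$emission
  # resolve label switching by matching the first emission row
  if (abs(E[1, 1] - 0.9) > abs(E[2, 1] - 0.9)) E <- E[2:1, ]
  expect_lt(max(abs(E - truth$emission)), 0.02)
})

test_that("model JSON serialization round-trips parameters and metadata", {
  tm <- make_truth_model(seed = 6, contig_bp = 4e5)
  path <- withr::local_tempfile(fileext = ".json")
  hmm_write_json(tm$params, path)
  back <- hmm_read_json(path)
  expect_equal(back$emission, unname(tm$params$emission), tolerance = 1e-12)
  expect_equal(back$transition, unname(tm$params$transition), tolerance = 1e-12)
  expect_equal(back$initial, tm$params$initial)
  expect_equal(unname(back$zero_mask), unname(tm$params$zero_mask))
  expect_equal(unname(back$free_transition), unname(tm$params$free_transition))
  expect_equal(back$state_meta$role, tm$params$state_meta$role)
  expect_equal(back$marks, tm$params$marks)
  expect_error(hmm_read_json(withr::local_tempfile(lines = "{}",
                                                   fileext = ".json")),
               "not a chromTU model")
})

test_that("invalid parameter configurations are rejected at construction", {
  A <- matrix(c(0.5, 0.4, 0.5, 0.6), 2)
  expect_error(hmm_params(matrix(0.5, 2, 2), matrix(c(0.6, 0.5, 0.5, 0.5), 2),
                          c(0.5, 0.5)), "sum to 1")
  # clamped mass 1 with a free entry left over
  zm <- matrix(FALSE, 2, 2)
  ft <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2)
  expect_error(hmm_params(matrix(0.5, 2, 2),
                          matrix(c(1, 0.5, 0, 0.5), 2), c(0.5, 0.5),
                          zero_mask = zm, free_transition = ft),
               "clamped mass")
  # structural zero cannot be free
  zm2 <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2)
  expect_error(hmm_params(matrix(0.5, 2, 2),
                          matrix(c(1, 0.5, 0, 0.5), 2), c(0.5, 0.5),
                          zero_mask = zm2,
                          free_transition = matrix(TRUE, 2, 2)),
               "structural zero")
})
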