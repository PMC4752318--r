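test_that("interaction probabilities match the scalar logistic", {
  expect_equal(interaction_probability(matrix(0, 1, 1), matrix(1, 1, 1))[1, 1], 0.5)
  expect_equal(interaction_probability(matrix(log(3), 1, 1), matrix(1, 1, 1))[1, 1], 0.75)

  set.seed(1)
  U <- matrix(rnorm(12), 4, 3)
  V <- matrix(rnorm(15), 5, 3)
  P <- interaction_probability(U, V)
  for (i in 1:4) for (j in 1:5) {
    x <- sum(U[i, ] * V[j, ])
    expect_equal(P[i, j], exp(x) / (1 + exp(x)))
  }
  expect_error(interaction_probability(matrix(0, 2, 3), matrix(0, 2, 4)),
               class = "nrlmf_validation_error")
})

test_that("probabilities stay in (0,1) without NaN across extreme inner products", {
  x <- c(-700, -100, -1, 0, 1, 100, 700)
  P <- interaction_probability(matrix(x, ncol = 1), matrix(1, 1, 1))
  expect_true(all(is.finite(P) & P > 0 & P < 1))
  expect_true(all(is.finite(nrlmf:::log1pexp(x))))
})

test_that("importance weighting identity holds for binary labels", {
  for (c_val in c(1, 2, 5, 10)) {
    expect_equal(1 + c_val * 1 - 1, c_val)
    expect_equal(1 + c_val * 0 - 0, 1)
  }
})

test_that("objective at the origin has its closed form", {
  Y <- matrix(c(1, 0, 0, 0), 2, 2)
  hp <- nrlmf_hyperparams(c = 5, r = 2, alpha = 0, beta = 0)
  val <- nrlmf_objective(matrix(0, 2, 2), matrix(0, 2, 2), Y, hp)
  expect_equal(val, 8 * log(2))
  expect_equal(val, 5.5452, tolerance = 1e-4)

  # general shape: (mn + (c-1)|positives|) * ln 2
  set.seed(3)
  Y2 <- matrix(rbinom(20, 1, .3), 4, 5)
  val2 <- nrlmf_objective(matrix(0, 4, 3), matrix(0, 5, 3), Y2,
                          nrlmf_hyperparams(c = 5, r = 3, alpha = 0, beta = 0))
  expect_equal(val2, (20 + 4 * sum(Y2)) * log(2))
})

test_that("unweighted objective equals the scalar Bernoulli oracle", {
  set.seed(11)
  U <- matrix(rnorm(8), 4, 2)
  V <- matrix(rnorm(6), 3, 2)
  Y <- matrix(rbinom(12, 1, .4), 4, 3)
  hp <- nrlmf_hyperparams(c = 1, r = 2, lambda_d = .7, lambda_t = .3,
                          alpha = 0, beta = 0)
  expect_equal(nrlmf_objective(U, V, Y, hp),
               objective_scalar_oracle(U, V, Y, 1, .7, .3))
})

test_that("constant-row latents contribute nothing through the Laplacian term", {
  S <- matrix(c(1, .9, .2, .9, 1, .4, .2, .4, 1), 3, 3, byrow = TRUE)
  Ld <- build_laplacian(build_adjacency(S, 1))
  U <- matrix(rep(c(.3, -.2), each = 3), 3, 2)
  Y <- matrix(0, 3, 3)
  hp0 <- nrlmf_hyperparams(c = 1, r = 2, alpha = 0, beta = 0)
  hp1 <- nrlmf_hyperparams(c = 1, r = 2, alpha = 5, beta = 0)
  expect_equal(nrlmf_objective(U, matrix(0, 3, 2), Y, hp1, Ld, Ld),
               nrlmf_objective(U, matrix(0, 3, 2), Y, hp0))
})

test_that("gradients vanish at the origin and match the scalar derivative", {
  Y <- matrix(c(1, 0, 0, 0), 2, 2)
  hp <- nrlmf_hyperparams(c = 5, r = 2, lambda_d = 1e-12, lambda_t = 1e-12,
                          alpha = 0, beta = 0)
  g <- nrlmf_gradients(matrix(0, 2, 2), matrix(0, 2, 2),
                       matrix(0, 2, 2), hp)
  expect_equal(g$Gd, matrix(0, 2, 2))
  expect_equal(g$Gt, matrix(0, 2, 2))

  # m = n = r = 1, y = 1, c = 1, no priors: dL/du = v (p - 1)
  hp1 <- nrlmf_hyperparams(c = 1, r = 1, lambda_d = 1e-300, lambda_t = 1e-300,
                           alpha = 0, beta = 0)
  g1 <- nrlmf_gradients(matrix(1), matrix(1), matrix(1), hp1)
  expect_equal(g1$Gd[1, 1], -1 / (1 + exp(1)), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(23)
  m <- 8; n <- 6; r <- 3
  Sd <- matrix(runif(m * m), m, m)
  St <- matrix(runif(n * n), n, n)
  Ld <- build_laplacian(build_adjacency(Sd, 3))$L
  Lt <- build_laplacian(build_adjacency(St, 3))$L
  Y <- matrix(rbinom(m * n, 1, .25), m, n)
  U <- matrix(rnorm(m * r, 0, .6), m, r)
  V <- matrix(rnorm(n * r, 0, .6), n, r)
  for (c_val in c(1, 5)) {
    for (ab in c(0, .5)) {
      hp <- nrlmf_hyperparams(c = c_val, r = r, lambda_d = .5, lambda_t = .25,
                              alpha = ab, beta = ab)
      exact <- nrlmf_gradients(U, V, Y, hp, Ld, Lt)
      approx <- fd_gradients(U, V, Y, hp, Ld, Lt)
      expect_lt(max(abs(exact$Gd - approx$Gd)) / max(abs(exact$Gd)), 1e-5)
      expect_lt(max(abs(exact$Gt - approx$Gt)) / max(abs(exact$Gt)), 1e-5)
    }
  }
})

test_that("initialization is seed-reproducible with the prescribed spread", {
  a <- initialize_latents(5, 4, 3, seed = 99)
  b <- initialize_latents(5, 4, 3, seed = 99)
  expect_identical(a, b)
  d <- initialize_latents(5, 4, 3, seed = 100)
  expect_false(identical(a$U, d$U))

  big <- initialize_latents(200, 1, 1e4, seed = 1)
  expect_equal(sd(big$U), 1 / sqrt(1e4), tolerance = 0.02)
})

test_that("training reduces the objective and is seed-deterministic", {
  g <- generate_planted_dataset(m = 25, n = 20, seed = 5)
  hp <- nrlmf_hyperparams(r = 5, max_iter = 30)
  m1 <- nrlmf(g$dataset, hp)
  expect_lt(tail(m1$objective_trace, 1), m1$objective_trace[1])
  m2 <- nrlmf(g$dataset, hp)
  expect_identical(m1$U, m2$U)
  expect_identical(m1$V, m2$V)
})

test_that("prior-dominated training shrinks the latents on empty data", {
  Y <- matrix(0, 8, 6)
  ds <- dti_dataset(Y, diag(8), diag(6))
  hp <- nrlmf_hyperparams(c = 1, r = 4, lambda_d = 50, lambda_t = 50,
                          alpha = 0, beta = 0, max_iter = 50, gamma = 0.1)
  model <- suppressWarnings(nrlmf(ds, hp))
  init <- initialize_latents(8, 6, 4, hp$seed)
  expect_lt(norm(model$U, "F"), norm(init$U, "F"))
  expect_lt(norm(model$V, "F"), norm(init$V, "F"))
})

test_that("divergence raises a classed error mentioning the step size", {
  g <- generate_planted_dataset(m = 10, n = 10, seed = 2)
  hp <- nrlmf_hyperparams(r = 3, gamma = 1e200, max_iter = 5)
  expect_error(nrlmf(g$dataset, hp), "gamma", class = "nrlmf_divergence_error")
})

test_that("smoothing passes positives through and weight-averages cold rows", {
  ds <- tiny_dataset()  # drug 3 has no interactions
  hp <- nrlmf_hyperparams(r = 3, K2 = 2, max_iter = 5)
  model <- nrlmf(ds, hp)
  sm <- smooth_latents(model)
  for (i in c(1, 2, 4)) expect_identical(sm$U[i, ], model$U[i, ])
  expect_identical(sm$V, model$V)  # all targets are positive

  # drug 3's positive neighbors by Sd row 3 (.2, .3, .6): top-2 are D4, D2
  w <- c(.6, .3) / .9
  expect_equal(sm$U[3, ], w[1] * model$U[4, ] + w[2] * model$U[2, ])

  # K2 = 1 copies the single nearest positive neighbor
  model1 <- nrlmf(ds, nrlmf_hyperparams(r = 3, K2 = 1, max_iter = 5))
  sm1 <- smooth_latents(model1)
  expect_equal(sm1$U[3, ], model1$U[4, ])
})

test_that("zero-similarity cold rows smooth to zero with a warning", {
  Y <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  Sd <- diag(2)  # b has similarity 0 to the only positive drug a
  St <- matrix(c(1, .5, .5, 1), 2, 2)
  ds <- dti_dataset(Y, Sd, St)
  expect_warning(model <- nrlmf(ds, nrlmf_hyperparams(r = 2, max_iter = 3)),
                 "zero")
  expect_equal(model$U_smooth[2, ], c(0, 0))
})

test_that("prediction uses smoothed vectors and matches the scalar path", {
  ds <- tiny_dataset()
  model <- nrlmf(ds, nrlmf_hyperparams(r = 3, max_iter = 10))
  P <- predict(model)
  for (i in 1:4) for (j in 1:3) {
    expect_equal(predict(model, i, j), P[i, j])
  }
  # positive drug x positive target equals the unsmoothed probability
  P_raw <- interaction_probability(model$U, model$V)
  expect_equal(P[1, 1], P_raw[1, 1])
  expect_error(predict(model, 9, 1), class = "nrlmf_validation_error")
  expect_equal(predict(model, "D2", "T3"), P["D2", "T3"])
})

test_that("model serialization round-trips predictions bit-identically", {
  ds <- tiny_dataset()
  model <- nrlmf(ds, nrlmf_hyperparams(r = 4, max_iter = 10))
  dir <- withr::local_tempdir()
  write_nrlmf_model(model, dir)
  back <- read_nrlmf_model(dir)
  expect_identical(predict(back), predict(model))
  expect_equal(back$hyper, model$hyper)
  expect_identical(back$pos$positive_drugs, unname(model$pos$positive_drugs))
})

test_that("tidy and glance summarize a fitted model", {
  ds <- tiny_dataset()
  model <- nrlmf(ds, nrlmf_hyperparams(r = 2, max_iter = 5))
  td <- tidy(model)
  expect_equal(nrow(td), 2 * (4 * 2 + 3 * 2))
  gl <- glance(model)
  expect_equal(gl$n_drugs, 4)
  expect_lt(gl$objective_final, gl$objective_initial)
})
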