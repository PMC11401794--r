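# ---- objective ------------------------------------------------------------

test_that("the weighted objective equalises blocks on different scales", {
  # two convex blocks with SDs [1,2,3] and [100,200,300]; with no model
  # part (A = 0, mean-matching intercepts) each block of indicators must
  # contribute (1+4+9)/4 = (100^2+...)/200^2 = 3.5
  m <- gsca_model(list(g1 = c("x1", "x2", "x3"), g2 = c("y1", "y2", "y3")))
  sds <- c(1, 2, 3, 100, 200, 300)
  mo <- gsca_moments_set(setNames(seq(2, 12, 2), m$indicators),
                         diag(sds^2), 50)
  W <- m$W_pattern * rep(1 / 3, 6)
  f <- gsca_objective(m, mo, W)
  expect_equal(f, 7)  # 3.5 + 3.5; exogenous components carry no penalty

  # with g2 a structural outcome its variance enters through its block SD
  m2 <- gsca_model(list(g1 = c("x1", "x2", "x3"), g2 = c("y1", "y2", "y3")),
                   edges = "g1 -> g2")
  f2 <- gsca_objective(m2, mo, W)
  var_g2 <- sum((c(100, 200, 300) / 3)^2)
  expect_equal(f2, 7 + var_g2 / 200^2)
})

test_that("moment-form objective equals the raw-data sum of squares / (N-1)", {
  set.seed(21)
  m <- gsca_model(list(g = c("x1", "x2")))
  X <- rand_data(m, N = 40)
  mo <- gsca_moments(X)
  W <- matrix(c(0.3, 0.7), 2, 1)
  C <- matrix(c(0.8, 1.1), 1, 2)
  f <- gsca_objective(m, mo, W, C = C)   # mean-matching intercepts
  # brute force on rows with the same (least-squares) intercepts
  pen <- build_penalty_matrix(m, mo)
  o <- c(pen$O_z, pen$O_gamma)
  G <- X %*% W
  obs <- cbind(X, G)
  lin <- G %*% cbind(C, 0)
  a0 <- colMeans(obs) - colMeans(lin)
  pred <- matrix(a0, 40, 3, byrow = TRUE) + lin
  ss <- sum(((obs - pred) %*% diag(o))^2)
  expect_equal(f, ss / (40 - 1), tolerance = 1e-10)
  # shifting an intercept adds exactly the weighted squared mean residual
  a0_off <- a0 + c(0.5, 0, 0)
  f_off <- gsca_objective(m, mo, W, C = C, a0 = a0_off)
  expect_equal(unname(f_off - f), unname(o[1]^2 * 0.5^2), tolerance = 1e-10)
})

test_that("a saturated single-indicator chain has zero objective", {
  m <- gsca_model(list(a = "x1", b = "x2"), edges = "a -> b")
  set.seed(5)
  x <- rnorm(30); X <- cbind(x1 = x, x2 = 2 * x + 3 + rnorm(30, sd = 1e-8))
  f <- gsca_fit(X, m)
  expect_lt(f$objective, 1e-12)
  expect_equal(f$indices$fit_ud, 1, tolerance = 1e-10)
})

# ---- coefficient updates --------------------------------------------------

test_that("loadings at convergence solve their simple regressions exactly", {
  set.seed(31)
  m <- gsca_model(list(g = c("x1", "x2", "x3")))
  X <- rand_data(m, 80)
  f <- gsca_fit(X, m, tol = 1e-12)
  S <- f$pre$S
  w <- f$weights[, 1]
  gvar <- as.numeric(crossprod(w, S %*% w))
  for (j in 1:3) {
    expect_equal(unname(f$loadings[1, j]),
                 sum(S[j, ] * w) / gvar, tolerance = 1e-10)
    expect_equal(unname(f$c0[j]),
                 f$pre$mu[[j]] - f$loadings[1, j] * f$component_mean[[1]],
                 tolerance = 1e-10)
  }
})

test_that("re-solving the structural side at the optimum is a fixed point", {
  f <- gsca_fit(acsi_moments(), acsi_model(), tol = 1e-10)
  A2 <- convexgsca:::update_A(f$weights, f$pre$S, f$est_model)
  expect_equal(unname(A2[, f$est_model$J + seq_len(f$est_model$P)]),
               unname(f$paths), tolerance = 1e-8)
})

test_that("the convex weight update matches a dense grid search", {
  set.seed(41)
  m <- gsca_model(list(g1 = c("x1", "x2", "x3"), g2 = "y1"),
                  edges = "g1 -> g2")
  X <- rand_data(m, 60)
  f <- gsca_fit(X, m, tol = 1e-12)
  o <- c(f$penalty$O_z, f$penalty$O_gamma)
  A <- cbind(f$loadings, f$paths)
  # independent oracle: evaluate the full objective on a dense sum-to-one
  # grid around the solution for the g1 weight column (w3 = 1 - w1 - w2;
  # negatives allowed, the constraint is sum-to-one only)
  w_hat <- f$weights[1:3, 1]
  grid <- expand.grid(
    w1 = seq(w_hat[1] - 0.3, w_hat[1] + 0.3, by = 0.005),
    w2 = seq(w_hat[2] - 0.3, w_hat[2] + 0.3, by = 0.005)
  )
  best <- Inf; best_w <- NULL
  Wg <- f$weights
  vals <- apply(as.matrix(grid), 1L, function(g) {
    Wg[1:3, 1] <- c(g[1], g[2], 1 - g[1] - g[2])
    convexgsca:::als_objective(Wg, A, f$pre$S, o)
  })
  i <- which.min(vals)
  expect_lte(f$objective, vals[i] + 1e-12)
  w_grid <- c(grid$w1[i], grid$w2[i], 1 - grid$w1[i] - grid$w2[i])
  expect_equal(unname(f$weights[1:3, 1]), w_grid, tolerance = 0.01)
})

test_that("degenerate weight columns behave: fixed, symmetric, bounded", {
  # single-indicator convex block: weight 1 regardless of data
  set.seed(51)
  m <- gsca_model(list(a = "x1", b = c("x2", "x3")), edges = "b -> a")
  X <- rand_data(m, 50)
  f <- gsca_fit(X, m)
  expect_identical(unname(f$weights["x1", "a"]), 1)

  # two exchangeable indicators get equal weights
  m2 <- gsca_model(list(g = c("x1", "x2"), h = "y"), edges = "g -> h")
  Sb <- rbind(c(2, 0.8, 0.7), c(0.8, 2, 0.7), c(0.7, 0.7, 1.5))
  dimnames(Sb) <- list(c("x1", "x2", "y"), c("x1", "x2", "y"))
  mo <- gsca_moments_set(c(x1 = 1, x2 = 1, y = 0), Sb, 100)
  f2 <- gsca_fit(mo, m2)
  expect_equal(unname(f2$weights["x1", "g"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(f2$weights["x2", "g"]), 0.5, tolerance = 1e-8)
})

test_that("non-negativity constraints produce simplex weights matching a grid", {
  # craft a block where the unconstrained solution has a negative weight
  set.seed(61)
  found <- FALSE
  for (try in 1:25) {
    m <- gsca_model(list(g1 = c("x1", "x2", "x3"), g2 = "y1"),
                    edges = "g1 -> g2")
    X <- rand_data(m, 60)
    f_free <- gsca_fit(X, m, tol = 1e-12)
    if (any(f_free$weights[1:3, 1] < -0.02)) { found <- TRUE; break }
  }
  expect_true(found)
  mn <- gsca_model(m$blocks, edges = "g1 -> g2", nonneg = TRUE)
  f_nn <- gsca_fit(X, mn, tol = 1e-12)
  w <- f_nn$weights[1:3, 1]
  expect_true(all(w >= -1e-12))
  expect_equal(sum(w), 1, tolerance = 1e-10)
  expect_gte(f_nn$objective, f_free$objective - 1e-12)
  # oracle: dense grid restricted to the non-negative simplex
  o <- c(f_nn$penalty$O_z, f_nn$penalty$O_gamma)
  A <- cbind(f_nn$loadings, f_nn$paths)
  grid <- expand.grid(w1 = seq(0, 1, by = 0.004), w2 = seq(0, 1, by = 0.004))
  grid <- grid[grid$w1 + grid$w2 <= 1, ]
  Wg <- f_nn$weights
  vals <- apply(as.matrix(grid), 1L, function(g) {
    Wg[1:3, 1] <- c(g[1], g[2], 1 - g[1] - g[2])
    convexgsca:::als_objective(Wg, A, f_nn$pre$S, o)
  })
  expect_lte(f_nn$objective, min(vals) + 1e-12)
})

# ---- whole-fit properties -------------------------------------------------

test_that("ACSI weights and paths land on the published estimates", {
  f <- gsca_fit(acsi_moments(), acsi_model())
  expect_true(f$converged)
  expect_equal(unname(f$weights["z9", "CS"]), 0.422, tolerance = 0.015)
  expect_equal(unname(f$paths["PQ", "CS"]), 0.723, tolerance = 0.015)
})

test_that("classic standardized GSCA reproduces the intelligence-test toy", {
  d <- data.frame(t1 = c(49, 50, 51), t2 = c(0, 50, 100))
  m <- gsca_model(list(iq = c("t1", "t2")))
  f <- suppressWarnings(gsca_fit(d, m, method = "standardized"))
  expect_equal(unname(f$weights[, 1]), c(0.5, 0.5))
  rs <- rescale_weights_unstandardized(f)
  expect_equal(rs$weight_uni, c(0.5, 0.01))

  # one-indicator block: standardized weight exactly 1
  m1 <- gsca_model(list(a = "t1", b = "t2"), edges = "a -> b")
  f1 <- gsca_fit(d, m1, method = "standardized")
  expect_equal(unname(f1$weights["t1", "a"]), 1, tolerance = 1e-10)

  # all SDs already 1: rescaling is the identity
  set.seed(71)
  Z <- scale(matrix(rnorm(60), 20, 3)) * sqrt(19 / 19)
  colnames(Z) <- c("t1", "t2", "t3")
  mz <- gsca_model(list(g = c("t1", "t2", "t3")))
  fz <- gsca_fit(as.data.frame(Z), mz, method = "standardized")
  rz <- rescale_weights_unstandardized(fz)
  expect_equal(rz$weight_uni, rz$weight_std, tolerance = 1e-10)
})

test_that("fitting from raw data and from exact moments is identical", {
  set.seed(81)
  for (r in 1:5) {
    m <- rand_model()
    X <- rand_data(m, 90)
    f1 <- gsca_fit(X, m)
    f2 <- gsca_fit(gsca_moments(X), m)
    expect_equal(f1$weights, f2$weights, tolerance = 1e-10)
    expect_equal(f1$paths, f2$paths, tolerance = 1e-10)
    expect_equal(f1$objective, f2$objective, tolerance = 1e-10)
  }
})

test_that("per-block affine rescaling leaves weights and objective unchanged", {
  set.seed(91)
  for (r in 1:5) {
    m <- rand_model(p_std = 0)
    X <- rand_data(m, 80)
    f1 <- gsca_fit(X, m, tol = 1e-10)
    X2 <- X
    shifts <- list()
    for (p in m$components) {
      a <- stats::runif(1, 0.5, 20); b <- stats::runif(1, -5, 5)
      X2[, m$blocks[[p]]] <- a * X[, m$blocks[[p]]] + b
      shifts[[p]] <- c(a, b)
    }
    f2 <- gsca_fit(X2, m, tol = 1e-10)
    expect_equal(f2$weights, f1$weights, tolerance = 1e-8)
    expect_equal(f2$objective, f1$objective, tolerance = 1e-8)
    # convex component scores transform by the same affine map
    for (p in m$components) {
      a <- shifts[[p]][1]; b <- shifts[[p]][2]
      expect_equal(unname(f2$component_mean[p]),
                   a * unname(f1$component_mean[p]) + b, tolerance = 1e-8)
      expect_equal(unname(f2$component_sd[p]),
                   a * unname(f1$component_sd[p]), tolerance = 1e-8)
    }
  }
})

test_that("with every component standardized the two methods coincide", {
  set.seed(102)
  m <- rand_model(P = 3, p_std = 1)
  X <- rand_data(m, 100)
  f1 <- gsca_fit(X, m, method = "convex", tol = 1e-10)
  f2 <- gsca_fit(X, m, method = "standardized", tol = 1e-10)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-8)
  expect_equal(f1$loadings, f2$loadings, tolerance = 1e-8)
  expect_equal(f1$paths, f2$paths, tolerance = 1e-8)
})

test_that("random multistart never beats nor misses the equal-weight start badly", {
  set.seed(112)
  m <- rand_model(P = 2, p_std = 0)
  X <- rand_data(m, 80)
  f_eq <- gsca_fit(X, m, tol = 1e-10)
  f_rand <- gsca_fit(X, m, tol = 1e-10, init = "random", n_starts = 5,
                     seed = 9)
  expect_equal(f_rand$objective, f_eq$objective, tolerance = 1e-6)
})
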