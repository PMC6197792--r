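test_that("neighbor selection filters, ranks and tie-breaks deterministically", {
  R <- matrix(NA_real_, 3, 6)
  R[1, c(1, 2, 5, 6)] <- 1            # candidate drugs for target (1, 3)
  S <- matrix(0, 6, 6)
  S[3, ] <- c(0.9, 0.2, 1, 0, 0.9, 0.1)
  S <- (S + t(S))
  expect_equal(select_neighbors(1, 3, R, S, K = 10, "drug"), c(1, 5, 2, 6))
  # equal similarities break ties by ascending index
  S[3, ] <- c(0.9, 0.2, 1, 0, 0.9, 0.9); S[, 3] <- S[3, ]
  expect_equal(select_neighbors(1, 3, R, S, K = 2, "drug"), c(1, 5))
  # a drug unobserved in the target row is never a candidate
  expect_false(3 %in% select_neighbors(1, 3, R, S, K = 10, "drug"))
  expect_false(4 %in% select_neighbors(1, 3, R, S, K = 10, "drug"))
  # no candidates at all gives an empty selection
  expect_length(select_neighbors(3, 3, R, S, K = 5, "drug"), 0)
})

test_that("weight system matches an independent double-loop oracle", {
  set.seed(31)
  R <- matrix(rnorm(32), 8, 4)
  R[cbind(c(2, 5, 7), c(2, 3, 1))] <- NA
  R[1, 4] <- NA                          # the target entry
  for (beta in c(0, 5, 500)) {
    nb <- c(1, 2, 3)
    sys <- build_weight_system(1, 4, nb, R, beta, "drug")
    oracle <- weight_system_oracle(1, 4, nb, R, beta)
    expect_lt(max(abs(sys$A_hat - oracle$A_hat)), 1e-12)
    expect_lt(max(abs(sys$b_hat - oracle$b_hat)), 1e-12)
    expect_equal(sys$avg, oracle$avg)
    expect_equal(sys$A_hat, t(sys$A_hat))
  }
  # beta = 0 on dense data: no shrinkage at all
  Rd <- matrix(rnorm(32), 8, 4)
  sys0 <- build_weight_system(1, 4, c(1, 2, 3), Rd, 0, "drug")
  expect_equal(sys0$A_hat, sys0$A_bar)
  expect_equal(sys0$b_hat, sys0$b_bar)
  # beta -> infinity: everything collapses to avg
  sysInf <- build_weight_system(1, 4, c(1, 2, 3), Rd, 1e9, "drug")
  expect_lt(max(abs(sysInf$A_hat - sysInf$avg)), 1e-6 * abs(sysInf$avg))
  expect_lt(max(abs(sysInf$b_hat - sysInf$avg)), 1e-6 * abs(sysInf$avg))
})

test_that("cell-line orientation is the exact transpose of drug orientation", {
  set.seed(13)
  R <- matrix(rnorm(40), 8, 5)
  R[sample(40, 8)] <- NA
  R[2, 3] <- NA
  nb <- which(is.finite(R[, 3]))[1:3]
  a <- build_weight_system(2, 3, nb, R, 7, "cell_line")
  b <- build_weight_system(3, 2, nb, t(R), 7, "drug")
  expect_equal(a, b)
})

test_that("non-negative solver handles scalar and boundary cases", {
  expect_equal(solve_nonnegative_weights(matrix(4), 2), 0.5)
  expect_equal(solve_nonnegative_weights(matrix(4), -2), 0)
})

test_that("non-negative solver attains the enumeration optimum", {
  set.seed(17)
  for (case in 1:100) {
    M <- matrix(rnorm(9), 3, 3)
    A <- crossprod(M) + diag(0.1, 3)
    b <- rnorm(3)
    w <- solve_nonnegative_weights(A, b)
    expect_true(all(w >= 0))
    ref <- nnqp_enumeration_oracle(A, b)
    expect_lt(nnqp_objective(A, b, w) - ref$objective, 1e-9)
    # KKT: gradient nonnegative where w is at the bound, ~0 where free
    g <- 2 * (A %*% w - b)
    expect_true(all(g > -1e-6))
    if (any(w > 1e-8)) expect_lt(max(abs(g[w > 1e-8])), 1e-6)
  }
})

test_that("beta = 0 dense solve matches a generic NNLS oracle", {
  skip_if_not_installed("pracma")
  set.seed(23)
  for (case in 1:20) {
    X <- matrix(rnorm(12 * 4), 12, 4)    # neighbor residual columns
    y <- rnorm(12)
    R <- cbind(X, y)
    R <- rbind(R, NA)                    # target row, fully unobserved
    sys <- build_weight_system(13, 5, 1:4, R, 0, "drug")
    w <- solve_nonnegative_weights(sys)
    ref <- pracma::lsqnonneg(X, y)$x
    # same quadratic objective up to the 1/n normalization of the system
    obj <- function(w) sum((X %*% w - y)^2)
    expect_lt(obj(w) - obj(ref), 1e-9)
  }
})

test_that("predictions are invariant to neighbor input order", {
  set.seed(41)
  R <- matrix(rnorm(60), 10, 6)
  R[1, 6] <- NA
  nb <- c(2, 4, 5)
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    sys <- build_weight_system(1, 6, nb[perm], R, 50, "drug")
    w <- solve_nonnegative_weights(sys)
    p <- sum(w * R[1, nb[perm]])
    if (perm[1] == 1) p0 <- p
    expect_equal(p, p0, tolerance = 1e-10)
  }
})

test_that("hybrid prediction averages orientations and falls back cleanly", {
  sim <- simulate_response_data(m = 20, n = 8, missing_rate = 0.2, seed = 3)
  fit <- ncfger(sim$response, sim$expression, sim$fingerprints)
  idx <- which(!is.finite(sim$response), arr.ind = TRUE)[1, ]
  cfg <- fit$config; cfg$orientation <- "hybrid"
  pd <- ncfger:::predict_orientation(idx[1], idx[2], fit$residuals,
                                     fit$S_drug, cfg, "drug")
  pc <- ncfger:::predict_orientation(idx[1], idx[2], fit$residuals,
                                     fit$S_cell, cfg, "cell_line")
  p <- predict_entry(idx[1], idx[2], fit$residuals, fit$effects,
                     fit$S_cell, fit$S_drug, cfg)
  expect_equal(p$residual_value, mean(c(pd$value, pc$value)))
  expect_equal(p$final_value,
               restore_effects(fit$effects, idx[1], idx[2],
                               p$residual_value))
  # averaging on the residual scale or after restoration coincides,
  # because both orientations share one effects model
  expect_equal(p$final_value,
               mean(restore_effects(fit$effects, idx[1], idx[2],
                                    c(pd$value, pc$value))))
  # an isolated target with no candidates anywhere falls back to effects
  R <- fit$response
  R[idx[1], ] <- NA; R[, idx[2]] <- NA
  R[idx[1], idx[2]] <- NA
  fit2 <- ncfger(R, sim$expression, sim$fingerprints)
  p2 <- predict_entry(idx[1], idx[2], fit2$residuals, fit2$effects,
                      fit2$S_cell, fit2$S_drug, fit2$config)
  expect_true(p2$fallback)
  expect_equal(p2$residual_value, 0)
})

test_that("rank-1 responses with a duplicated drug column are recovered exactly", {
  set.seed(57)
  a <- rnorm(12)
  b <- runif(7, 0.5, 2)
  R <- outer(a, c(b, b[3]))             # drug 8 duplicates drug 3
  dimnames(R) <- list(sprintf("c%02d", 1:12), sprintf("d%d", 1:8))
  for (held in list(c(2, 8), c(5, 8), c(9, 3))) {
    Rm <- R
    Rm[held[1], held[2]] <- NA
    fit <- ncfger(Rm, similarity = "RPCC", orientation = "drug",
                  beta = 0, K = 3, alpha2 = 0, effects = "none")
    pred <- suppressMessages(predict(fit, entries = rbind(held)))
    expect_lt(abs(pred$predicted_value - R[held[1], held[2]]), 1e-6)
  }
})

test_that("repeated fits and predictions are bit-identical", {
  sim <- simulate_response_data(m = 25, n = 10, missing_rate = 0.25, seed = 9)
  f1 <- ncfger(sim$response, sim$expression, sim$fingerprints)
  f2 <- ncfger(sim$response, sim$expression, sim$fingerprints)
  expect_identical(predict(f1), predict(f2))
})
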