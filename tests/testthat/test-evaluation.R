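test_that("folds partition the entries into near-equal random blocks", {
  f <- make_folds(1:100, 10, seed = 1)
  expect_length(f, 10)
  expect_true(all(lengths(f) == 10))
  expect_setequal(unlist(f), 1:100)

  f2 <- make_folds(1:101, 10, seed = 1)
  expect_equal(sort(lengths(f2), decreasing = TRUE),
               c(11, rep(10, 9)))
  expect_setequal(unlist(f2), 1:101)
  expect_true(!anyDuplicated(unlist(f2)))

  # deterministic given the seed, different otherwise
  expect_identical(make_folds(1:100, 10, seed = 7),
                   make_folds(1:100, 10, seed = 7))
  expect_false(identical(make_folds(1:100, 10, seed = 7),
                         make_folds(1:100, 10, seed = 8)))
  expect_error(make_folds(1:5, 10), "fewer entries")
})

test_that("quartile sensitive/resistant labels follow the interpolation rule", {
  lab <- sr_labels(1:8)
  expect_equal(lab, c("sensitive", "sensitive", rep("neither", 4),
                      "resistant", "resistant"))
  # constant responses collapse the quartiles: nobody is labeled
  expect_true(all(sr_labels(rep(2, 10)) == "neither"))
  # fewer than 4 responses: drug ineligible
  expect_true(all(sr_labels(c(1, 5, 9)) == "neither"))
  # boundary ties join the extreme groups
  lab2 <- sr_labels(c(1, 1, 1, 2, 3, 4, 4, 4))
  expect_equal(sum(lab2 == "sensitive"), 3)
  expect_equal(sum(lab2 == "resistant"), 3)
})

test_that("scoring reproduces hand-computed PCC and RMSE", {
  truth <- c(1, 2, 3, 4, 5)
  drug <- rep("d1", 5)
  sr <- c("sensitive", "neither", "neither", "neither", "resistant")
  # perfect prediction
  s <- score_predictions(drug, truth, truth, sr)
  expect_equal(s$per_drug$pcc, 1)
  expect_equal(s$per_drug$rmse, 0)
  # a constant shift keeps PCC at 1 and sets RMSE to the shift
  s2 <- score_predictions(drug, truth, truth + 1, sr)
  expect_equal(s2$per_drug$pcc, 1)
  expect_equal(s2$per_drug$rmse, 1)
  # hand-computed RMSE on an error vector
  pred <- truth + c(0.5, -0.5, 1, 0, -1)
  s3 <- score_predictions(drug, truth, pred, sr)
  expect_equal(s3$per_drug$rmse, sqrt(mean(c(0.5, -0.5, 1, 0, -1)^2)))
  expect_equal(s3$per_drug$pcc, cor(pred, truth))
  expect_equal(s3$per_drug$rmse_sr, sqrt(mean(c(0.5, -1)^2)))
  # zero-variance predictions: PCC recorded as 0 with a warning
  expect_warning(s4 <- score_predictions(drug, truth, rep(2, 5), sr),
                 "zero-variance")
  expect_equal(s4$per_drug$pcc, 0)
  expect_equal(s4$per_drug$rmse, sqrt(mean((2 - truth)^2)))
})

test_that("drug-averaged metrics ignore entry and drug ordering", {
  set.seed(5)
  n <- 40
  drug <- sample(c("a", "b", "c", "d"), n, replace = TRUE)
  truth <- rnorm(n)
  pred <- truth + rnorm(n, 0, 0.3)
  sr <- sample(c("sensitive", "resistant", "neither"), n, replace = TRUE)
  s <- score_predictions(drug, truth, pred, sr)
  perm <- sample(n)
  s2 <- score_predictions(drug[perm], truth[perm], pred[perm], sr[perm])
  expect_equal(s$drug_averaged, s2$drug_averaged)
})

test_that("every observed entry is tested exactly once per repetition", {
  sim <- simulate_response_data(m = 25, n = 8, missing_rate = 0.25, seed = 21)
  cv <- cv_ncfger(sim$response, sim$expression, sim$fingerprints,
                  folds = 5, repeats = 2, seed = 21)
  obs <- which(is.finite(sim$response))
  for (r in 1:2) {
    p <- cv$predictions[cv$predictions$repetition == r, ]
    tested <- (p$i - 1L) * nrow(sim$response) + p$u
    expect_setequal(tested, obs)
    expect_equal(nrow(p), length(obs))
  }
})

test_that("test-fold values never leak into training (poison check)", {
  sim <- simulate_response_data(m = 20, n = 8, missing_rate = 0.2, seed = 33)
  R <- sim$response
  cv1 <- cv_ncfger(R, sim$expression, sim$fingerprints,
                   folds = 5, repeats = 1, seed = 2)
  # poison one fold's test entries in the input: because they are masked
  # before any fitting, predictions for that fold must be unchanged
  obs <- which(is.finite(R))
  fold1 <- make_folds(obs, 5, seed = 2)[[1]]
  Rp <- R
  Rp[fold1] <- 1e6
  cv2 <- cv_ncfger(Rp, sim$expression, sim$fingerprints,
                   folds = 5, repeats = 1, seed = 2)
  p1 <- cv1$predictions[cv1$predictions$fold == 1, ]
  p2 <- cv2$predictions[cv2$predictions$fold == 1, ]
  expect_identical(p1$pred_hybrid, p2$pred_hybrid)
  expect_identical(p1$pred_cell, p2$pred_cell)
  expect_identical(p1$pred_drug, p2$pred_drug)
})

test_that("identical config and seed give byte-identical CV reports", {
  sim <- simulate_response_data(m = 20, n = 8, missing_rate = 0.2, seed = 12)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  cv1 <- cv_ncfger(sim$response, sim$expression, sim$fingerprints,
                   folds = 5, repeats = 2, seed = 4, keep_predictions = FALSE)
  cv2 <- cv_ncfger(sim$response, sim$expression, sim$fingerprints,
                   folds = 5, repeats = 2, seed = 4, keep_predictions = FALSE)
  write_cv_report(cv1, f1)
  write_cv_report(cv2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
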