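test_that("separable classes give perfect training and CV accuracy", {
  w <- make_windows(120, rep(0, 6), rep(8, 6), sd = 0.5, seed = 1)
  m <- train_error_classifier(w)
  p <- predict_error_probability(m, w)
  acc <- mean((p >= m$tau) == (w$label == "error"))
  expect_equal(acc, 1)
  cv <- cross_validate_time(w, 8)
  expect_equal(cv$accuracy, 1)
  expect_true(all(cv$folds$accuracy == 1))
})

test_that("training requires both classes and flags degenerate variances", {
  w <- make_windows(50, rep(0, 4), rep(1, 4), seed = 2)
  w$label <- "correct"
  expect_error(train_error_classifier(w), "Both classes")
  w2 <- make_windows(50, rep(0, 4), rep(5, 4), sd = 1, seed = 3)
  w2$features[, 2] <- 3  # constant feature
  expect_warning(train_error_classifier(w2, shrink = 0), "floored")
})

test_that("posterior probability behaves like a calibrated naive Bayes", {
  w <- make_windows(200, rep(0, 4), rep(6, 4), sd = 1, seed = 4)
  m <- train_error_classifier(w)
  # window at the error-class mean: near-certain error
  expect_gt(predict_error_probability(m, m$class_means["error", ]), 0.99)
  # symmetric likelihoods with equal priors give 0.5
  w_bal <- make_windows(150, rep(-1, 4), rep(1, 4), sd = 1, seed = 5)
  mb <- train_error_classifier(w_bal, shrink = 0)
  mid <- (mb$class_means["error", ] + mb$class_means["correct", ]) / 2
  expect_equal(predict_error_probability(mb, mid), 0.5, tolerance = 1e-8)
  expect_error(predict_error_probability(m, rep(0, 3)), "features")
})

test_that("posteriors are bimodal on well-separated data", {
  w <- make_windows(250, rep(0, 8), rep(4, 8), sd = 1, seed = 6)
  cv <- cross_validate_time(w, 8)
  p <- cv$probability
  expect_gt(mean(p < 0.05 | p > 0.95), 0.9)
})

test_that("pre-error inclusion changes only the label mapping", {
  w <- make_windows(100, rep(0, 4), rep(4, 4), n_pre = 30,
                    mu_pre = rep(2, 4), seed = 7)
  m1 <- train_error_classifier(w, include_pre_error = TRUE)
  m0 <- train_error_classifier(w, include_pre_error = FALSE)
  expect_equal(m1$n_features, m0$n_features)
  # mapped class sizes differ by exactly the pre-error count
  expect_equal(sum(bcidamp:::map_error_labels(w$label, TRUE) == "error") -
                 sum(bcidamp:::map_error_labels(w$label, FALSE) == "error"), 30)
})

test_that("shuffled labels sit at greedy chance", {
  w <- make_windows(120, rep(0, 10), rep(3, 10), sd = 1, seed = 8)
  diffs <- vapply(1:20, function(i) {
    set.seed(i)
    ws <- w
    ws$label <- sample(ws$label)
    cv <- cross_validate_time(ws, 4)
    cv$accuracy - cv$chance
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.03)
})

test_that("greedy chance level is the majority-class frequency", {
  expect_equal(greedy_chance_level(c(rep("a", 70), rep("b", 30))), 0.70)
  expect_equal(greedy_chance_level(c("a", "b")), 0.5)
  expect_equal(greedy_chance_level(rep("a", 5)), 1)
  expect_error(greedy_chance_level(character(0)), "non-empty")
})

test_that("target cross-validation holds out whole target positions", {
  w <- make_windows(160, rep(0, 5), rep(4, 5), seed = 9)
  cv <- cross_validate_targets(w, 8)
  expect_equal(nrow(cv$folds), 8L)
  expect_gt(cv$accuracy, 0.95)
  w2 <- w[w$target_index != 3, ]
  expect_error(cross_validate_targets(w2, 8), "3")
})

test_that("detection delay follows the stated sign convention", {
  labs <- c("correct", "correct", "error", "error", "error", "correct")
  # flag 2 windows after onset
  dd <- detection_delay(c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE), labs)
  expect_equal(dd$mean_delay, 0.16)
  expect_equal(dd$detected_fraction, 1)
  # flag on the pre-error window before onset: negative delay
  dd2 <- detection_delay(c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE), labs)
  expect_equal(dd2$mean_delay, -0.08)
  # undetected bouts are excluded but reported
  labs2 <- c("error", "correct", "error", "correct")
  dd3 <- detection_delay(c(TRUE, FALSE, FALSE, FALSE), labs2)
  expect_equal(dd3$detected_fraction, 0.5)
  expect_equal(dd3$mean_delay, 0)
  expect_warning(out <- detection_delay(c(FALSE, TRUE), c("correct", "correct")),
                 "No error bouts")
  expect_true(is.na(out$mean_delay))
})

test_that("naive Bayes posterior matches the reference implementation", {
  skip_if_not_installed("e1071")
  w <- make_windows(150, c(0, 0, 0), c(2, 1, 3), sd = 1.5, seed = 10)
  m <- train_error_classifier(w, pooled = FALSE, shrink = 0)
  p_ours <- predict_error_probability(m, w)
  y <- factor(bcidamp:::map_error_labels(w$label, TRUE))
  ref <- e1071::naiveBayes(as.data.frame(w$features), y)
  p_ref <- predict(ref, as.data.frame(w$features), type = "raw")[, "error"]
  # e1071 uses n-1 variance normalization like ours
  expect_gt(cor(p_ours, p_ref), 0.999)
  expect_lt(max(abs(p_ours - p_ref)), 0.02)
})
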