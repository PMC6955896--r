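blobs <- function(n_per_class, sep, d = 2) {
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d) + sep / 2,
             matrix(rnorm(n_per_class * d), ncol = d) - sep / 2)
  list(x = x, y = rep(c("hand", "foot"), each = n_per_class))
}

test_that("the max-margin classifier separates well-separated blobs", {
  set.seed(61)
  b <- blobs(30, sep = 10)
  model <- train_classifier(b$x, b$y)
  pred <- predict(model, b$x)
  expect_equal(as.character(pred), b$y)
  # single feature row predicts a single label
  p1 <- predict(model, b$x[1, ])
  expect_length(p1, 1)
  # determinism: duplicated training set gives the same decision function
  model2 <- train_classifier(b$x, b$y)
  expect_equal(model$fit$rho, model2$fit$rho)
  expect_equal(model$fit$coefs, model2$fit$coefs)
  expect_identical(as.character(predict(model2, b$x)), as.character(pred))
})

test_that("shuffled labels give chance-level held-out accuracy", {
  set.seed(62)
  b <- blobs(200, sep = 0)
  y <- sample(b$y)
  model <- train_classifier(b$x[1:200, ], y[1:200])
  pred <- predict(model, b$x[201:400, ])
  acc <- accuracy(confusion(y[201:400], pred))
  band <- null_band(200)
  expect_gt(acc, band[1])
  expect_lt(acc, band[2])
})

test_that("predictions agree with an explicit dot-product decision oracle", {
  set.seed(63)
  b <- blobs(40, sep = 6)
  model <- train_classifier(b$x, b$y)
  z <- sweep(sweep(b$x, 2, model$center), 2, model$scale, "/")
  w <- crossprod(model$fit$coefs, model$fit$SV)
  dec <- drop(z %*% t(w)) - model$fit$rho
  pred <- predict(model, b$x, decision_values = TRUE)
  expect_equal(unname(attr(pred, "decision_values")), unname(dec),
               tolerance = 1e-10)
  lab_from_sign <- ifelse(dec > 0, model$fit$levels[1], model$fit$levels[2])
  expect_identical(as.character(pred), unname(lab_from_sign))
  expect_error(predict(model, b$x[, 1, drop = FALSE]), "dimension")
  expect_error(train_classifier(b$x, rep("hand", 80)), "both classes")
})

test_that("confusion counts match an independent tally", {
  # all correct: 5 hand + 3 foot
  cf <- confusion(rep(c("hand", "foot"), c(5, 3)),
                  rep(c("hand", "foot"), c(5, 3)))
  expect_equal(cf[c("TP", "FN", "TN", "FP")],
               list(TP = 5L, FN = 0L, TN = 3L, FP = 0L))
  # all hand predicted foot
  cf2 <- confusion(rep("hand", 4), rep("foot", 4))
  expect_equal(cf2$TP, 0L); expect_equal(cf2$FN, 4L)
  # random vectors against a counting oracle
  set.seed(64)
  tl <- sample(c("hand", "foot"), 100, replace = TRUE)
  pl <- sample(c("hand", "foot"), 100, replace = TRUE)
  cf3 <- confusion(tl, pl)
  tab <- table(factor(tl, c("hand", "foot")), factor(pl, c("hand", "foot")))
  expect_equal(cf3$TP, unname(tab["hand", "hand"]))
  expect_equal(cf3$FN, unname(tab["hand", "foot"]))
  expect_equal(cf3$TN, unname(tab["foot", "foot"]))
  expect_equal(cf3$FP, unname(tab["foot", "hand"]))
  expect_equal(cf3$TP + cf3$FN + cf3$TN + cf3$FP, 100)
  expect_error(confusion(c("hand", "left"), c("hand", "hand")), "unknown label")
  expect_error(confusion("hand", c("hand", "foot")), "equal length")
})

test_that("performance measures follow the exact percent formulas", {
  # 49 correct of 56 predictions is exactly 87.50%
  cf <- structure(list(TP = 24L, FN = 3L, TN = 25L, FP = 4L,
                       positive_class = "hand", negative_class = "foot"),
                  class = "confusion_counts")
  expect_equal(accuracy(cf), 87.5)
  expect_equal(sensitivity(structure(list(TP = 3L, FN = 1L, TN = 0L, FP = 0L),
                                     class = "confusion_counts")), 75)
  expect_error(specificity(structure(list(TP = 3L, FN = 1L, TN = 0L, FP = 0L),
                                     class = "confusion_counts")),
               "undefined")
  # exact rational identity before any rounding
  set.seed(65)
  tl <- sample(c("hand", "foot"), 37, replace = TRUE)
  pl <- sample(c("hand", "foot"), 37, replace = TRUE)
  cf2 <- confusion(tl, pl)
  expect_equal(accuracy(cf2) * 37, 100 * (cf2$TP + cf2$TN),
               tolerance = 1e-12)
})

test_that("swapping the positive class swaps sensitivity and specificity", {
  set.seed(66)
  tl <- sample(c("hand", "foot"), 60, replace = TRUE)
  pl <- sample(c("hand", "foot"), 60, replace = TRUE)
  swap <- function(x) ifelse(x == "hand", "foot", "hand")
  cf <- confusion(tl, pl)
  cf_sw <- confusion(swap(tl), swap(pl))
  expect_equal(sensitivity(cf), specificity(cf_sw))
  expect_equal(specificity(cf), sensitivity(cf_sw))
  expect_equal(accuracy(cf), accuracy(cf_sw))
})
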