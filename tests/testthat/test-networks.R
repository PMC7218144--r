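test_that("variant contracts: frequency path required exactly where specified", {
  expect_s3_class(model_spec("AT1", 20, 1), "model_spec")
  expect_s3_class(model_spec("AT2", 20, 1), "model_spec")
  expect_error(model_spec("AT_AR3", 20, 1), class = "ecogmapr_config_error")
  expect_error(model_spec("AT_AR3", 20, 1, ar_dim = NULL),
               class = "ecogmapr_config_error")
  spec <- model_spec("AT_AR3", 20, 1, ar_dim = 8)
  expect_identical(spec$ar_dim, 8L)
})

test_that("every variant builds and emits one probability per instance", {
  d <- toy_dataset(n_per_class = 3, T_ = 18, Fh = 2, P = 5, seed = 21)
  ds <- toy_dataset(n_per_class = 3, T_ = 18, Fh = 1, P = 5, seed = 22,
                    stories = 3)
  for (v in MODEL_VARIANTS) {
    data <- if (v == "PER_STORY") ds else d
    nf <- if (v == "PER_STORY") 1 else 2
    spec <- model_spec(v, 18, nf, ar_dim = 5, n_stories = 3,
                       hyper = tiny_hyper())
    m <- build_model(spec, seed = 1)
    preds <- suppressWarnings(predict_subblocks(m, data))
    expect_identical(nrow(preds), 6L)
    expect_true(all(preds$prob >= 0 & preds$prob <= 1))
    expect_true(all(preds$label %in% c("positive", "negative")))
  }
})

test_that("PER_STORY has one trunk per story plus a merge head", {
  spec <- model_spec("PER_STORY", 18, 1, ar_dim = 5, n_stories = 5,
                     hyper = tiny_hyper())
  m <- build_model(spec, seed = 2)
  expect_length(m$params$stories, 5)
  expect_identical(dim(m$params$head$W$value),
                   c(5L * tiny_hyper()$fc_units, 1L))
})

test_that("domain fusion is concatenation with a fixed argument order", {
  tr <- matrix(rnorm(12), 3, 4)
  fr <- matrix(rnorm(6), 3, 2)
  fused <- fuse_domains(tr, fr)
  expect_identical(dim(fused), c(3L, 6L))
  expect_identical(fused[, 1:4], tr)
  expect_identical(fused[, 5:6], fr)
  # zero frequency vector: time features pass through, fusion well-defined
  z <- fuse_domains(tr, matrix(0, 3, 2))
  expect_identical(z[, 5:6], matrix(0, 3, 2))
  # sequence + tiled vector
  seq_repr <- array(rnorm(3 * 7 * 2), dim = c(3, 7, 2))
  fused3 <- fuse_domains(seq_repr, fr)
  expect_identical(dim(fused3), c(3L, 7L, 4L))
  expect_equal(fused3[2, 5, 3:4], fr[2, ])
  expect_error(fuse_domains(matrix(NaN, 2, 2), matrix(0, 2, 1)),
               class = "ecogmapr_validation_error")
  expect_error(fuse_domains(tr, matrix(0, 5, 2)),
               class = "ecogmapr_validation_error")
})

test_that("a probability of exactly one half votes negative (strict rule)", {
  d <- toy_dataset(n_per_class = 2, T_ = 12, Fh = 1, P = 3, seed = 23)
  m <- build_model(model_spec("AT_AR3", 12, 1, ar_dim = 3,
                              hyper = tiny_hyper()), seed = 1)
  m$params$head$W$value[] <- 0
  m$params$head$b$value[] <- 0
  preds <- suppressWarnings(predict_subblocks(m, d))
  expect_true(all(preds$prob == 0.5))
  expect_true(all(preds$label == "negative"))
})

test_that("training is deterministic under a fixed seed", {
  d <- toy_dataset(n_per_class = 8, T_ = 15, Fh = 1, P = 4, seed = 24)
  run <- function() {
    m <- build_model(model_spec("AT_AR3", 15, 1, ar_dim = 4,
                                hyper = tiny_hyper()), seed = 5)
    train_model(m, d, epochs = 5, seed = 7)
  }
  m1 <- run(); m2 <- run()
  expect_identical(ecogmapr:::weights_signature(m1),
                   ecogmapr:::weights_signature(m2))
  expect_identical(predict_subblocks(m1, d)$prob,
                   predict_subblocks(m2, d)$prob)
  # duplicated instance, identical probability
  p <- predict_subblocks(m1, d)$prob
  d2 <- ecogmapr:::dataset_slice(d, c(1, 1, 2))
  p2 <- predict_subblocks(m1, d2)$prob
  expect_identical(p2[1], p2[2])
})

test_that("training errors are specific", {
  d <- toy_dataset(n_per_class = 4, T_ = 12, Fh = 1, P = 3, seed = 25)
  single <- ecogmapr:::dataset_slice(d, which(d$y == 1))
  m <- build_model(model_spec("AT_AR3", 12, 1, ar_dim = 3,
                              hyper = tiny_hyper()), seed = 1)
  expect_error(train_model(m, single), class = "ecogmapr_validation_error")
  # shape mismatch at prediction
  trained <- train_model(m, d, epochs = 2, seed = 1)
  wrong <- toy_dataset(n_per_class = 2, T_ = 12, Fh = 3, P = 3, seed = 26)
  expect_error(predict_subblocks(trained, wrong),
               class = "ecogmapr_validation_error")
})

test_that("separable feature clouds are learnt to near-perfect block accuracy", {
  d <- toy_dataset(n_per_class = 30, T_ = 20, Fh = 1, P = 4, shift = 2,
                   seed = 27)
  # logistic-regression oracle on the instance means separates this easily
  xm <- cbind(apply(d$time, 1, mean), d$freq)
  orc <- suppressWarnings(stats::glm(d$y ~ xm, family = stats::binomial()))
  expect_gte(mean((stats::fitted(orc) > 0.5) == (d$y == 1)), 0.99)

  m <- build_model(model_spec("AT_AR3", 20, 1, ar_dim = 4,
                              hyper = tiny_hyper()), seed = 3)
  m <- train_model(m, d, epochs = 50, seed = 3)
  expect_gte(tail(m$history$accuracy, 1), 0.95)
})

test_that("label permutation destroys the signal", {
  withr::local_seed(28)
  d <- toy_dataset(n_per_class = 20, T_ = 15, Fh = 1, P = 4, shift = 2,
                   seed = 29)
  d$y <- sample(d$y)
  test <- toy_dataset(n_per_class = 20, T_ = 15, Fh = 1, P = 4, shift = 2,
                      seed = 30)
  test$y <- sample(test$y)
  m <- build_model(model_spec("AT_AR3", 15, 1, ar_dim = 4,
                              hyper = tiny_hyper()), seed = 4)
  m <- train_model(m, d, epochs = 15, seed = 4)
  acc <- mean((predict_subblocks(m, test)$prob > 0.5) == (test$y == 1))
  # 95% binomial band around chance for n = 40
  expect_gt(acc, 0.5 - 1.96 * sqrt(0.25 / 40) - 0.05)
  expect_lt(acc, 0.5 + 1.96 * sqrt(0.25 / 40) + 0.05)
})

test_that("every variant can memorise a 20-instance toy set", {
  d20 <- toy_dataset(n_per_class = 10, T_ = 16, Fh = 2, P = 4, shift = 1,
                     seed = 31)
  ds20 <- toy_dataset(n_per_class = 10, T_ = 16, Fh = 1, P = 4, shift = 1,
                      seed = 32, stories = 2)
  for (v in MODEL_VARIANTS) {
    data <- if (v == "PER_STORY") ds20 else d20
    nf <- if (v == "PER_STORY") 1 else 2
    m <- build_model(model_spec(v, 16, nf, ar_dim = 4, n_stories = 2,
                                hyper = tiny_hyper()), seed = 6)
    m <- train_model(m, data, epochs = 250, batch_size = 10, lr = 5e-3,
                     seed = 6, patience = 250)
    acc <- mean((predict_subblocks(m, data)$prob > 0.5) == (data$y == 1))
    expect_gte(acc, 1.0)
  }
})

test_that("training history is exposed tidily", {
  d <- toy_dataset(n_per_class = 5, T_ = 12, Fh = 1, P = 3, seed = 33)
  m <- build_model(model_spec("AT2", 12, 1, hyper = tiny_hyper()), seed = 1)
  m <- train_model(m, d, epochs = 3, seed = 1)
  h <- tidy(m)
  expect_identical(nrow(h), 3L)
  expect_true(all(c("epoch", "loss", "accuracy") %in% names(h)))
  g <- glance(m)
  expect_identical(g$variant, "AT2")
  expect_s3_class(autoplot(m), "ggplot")
})
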