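test_that("zero epochs returns the seeded initial parameters unchanged", {
  ds <- toy_dataset(n_per_class = 6, length = 30, seed = 41)
  enc <- encoder_config(k = 2, d = 2)
  fit <- sfgcn_fit(ds, encoder = enc, model = micro_model(),
                   training = train_config(epochs = 0))
  expect_equal(nrow(fit$log), 0)
  init <- init_params(enc, micro_model())
  expect_equal(fit$params$gcn, init$gcn)
  expect_equal(fit$params$W1, init$W1)
})

test_that("identical seeds and data give identical training trajectories", {
  ds <- toy_dataset(n_per_class = 8, length = 40, seed = 42)
  sp <- list(train = ds[c(1:6, 9:14), ], val = ds[c(7, 8, 15, 16), ])
  args <- list(data = sp$train, validation = sp$val,
               encoder = encoder_config(k = 2, d = 2),
               model = micro_model(),
               training = train_config(epochs = 4, seed = 7))
  a <- do.call(sfgcn_fit, args)
  b <- do.call(sfgcn_fit, args)
  expect_identical(a$log, b$log)
  expect_identical(a$params, b$params)
  c <- do.call(sfgcn_fit, modifyList(args, list(
    training = train_config(epochs = 4, seed = 8))))
  expect_false(identical(a$params, c$params))
})

test_that("training descends on a strong planted signal", {
  ds <- generate_dataset(generator_config(n_per_class = 25, length = 150,
                                          signal_strength = 0.8, seed = 43))
  fit <- sfgcn_fit(ds, encoder = encoder_config(k = 3, d = 3),
                   model = micro_model(seed = 2),
                   training = train_config(epochs = 12, seed = 3))
  log <- tidy(fit)
  expect_lt(log$train_loss[nrow(log)], log$train_loss[1])
})

test_that("single-class training data is rejected", {
  ds <- toy_dataset(n_per_class = 6, length = 30, seed = 44)
  expect_error(sfgcn_fit(ds[ds$label == 1, ]), "both classes")
})

test_that("class weights follow inverse class frequency", {
  w <- sfgcn:::resolve_class_weights("balanced", c(1, 1, 1, 0))
  expect_equal(w, c(4 / (2 * 1), 4 / (2 * 3)))
  expect_equal(sfgcn:::resolve_class_weights("balanced", c(0, 0, 1, 1)),
               c(1, 1))
  expect_equal(sfgcn:::resolve_class_weights("none", c(0, 1)), c(1, 1))
  expect_equal(sfgcn:::resolve_class_weights(c(2, 3), c(0, 1)), c(2, 3))
})

test_that("a zero-parameter model scores 0.5 with ties to the negative class", {
  ds <- toy_dataset(n_per_class = 4, length = 30, seed = 45)
  enc <- encoder_config(k = 2, d = 2)
  fit <- sfgcn_fit(ds, encoder = enc, model = micro_model(),
                   training = train_config(epochs = 0))
  fit$params <- sfgcn:::vector_to_params(
    numeric(n_params(fit$params)), fit$params)
  pr <- predict(fit, ds)
  expect_equal(pr$score, rep(0.5, nrow(ds)))
  expect_equal(pr$pred, rep(0L, nrow(ds)))
})

test_that("scores lie in (0, 1) and ignore record order", {
  ds <- toy_dataset(n_per_class = 6, length = 40, seed = 46)
  fit <- sfgcn_fit(ds, encoder = encoder_config(k = 2, d = 2),
                   model = micro_model(),
                   training = train_config(epochs = 3))
  pr <- predict(fit, ds)
  expect_true(all(pr$score > 0 & pr$score < 1))
  perm <- sample(nrow(ds))
  pr2 <- predict(fit, ds[perm, ])
  expect_equal(pr2$score, pr$score[perm])
})

test_that("early stopping restores the best-validation parameters", {
  ds <- generate_dataset(generator_config(n_per_class = 15, length = 80,
                                          seed = 47))
  sp <- split_dataset(ds, seed = 1)
  fit <- sfgcn_fit(sp$train, validation = sp$validation,
                   encoder = encoder_config(k = 2, d = 2),
                   model = micro_model(),
                   training = train_config(epochs = 40, seed = 5,
                                           early_stopping_patience = 3))
  log <- tidy(fit)
  expect_lte(nrow(log), 40)
  best_epoch <- which.min(log$val_loss)
  expect_lte(nrow(log) - best_epoch, 3 + 1)
})

test_that("analytic gradients agree with central finite differences", {
  # micro-batch, 1 GCN layer, k = 2; checked at a generic (perturbed)
  # parameter point so no ReLU preactivation sits exactly at its kink
  tiny <- toy_dataset(n_per_class = 2, length = 30, seed = 48)[c(1, 2, 3), ]
  enc <- encoder_config(k = 2, d = 2)
  mc <- micro_model()
  caches <- sfgcn:::precompute_caches(tiny, enc, TRUE)
  params <- init_params(enc, mc)
  pidx <- sfgcn:::conv_pad_index(16L, 3L)
  theta <- sfgcn:::params_to_vector(params)
  set.seed(99)
  theta <- theta + runif(length(theta), -0.1, 0.1)
  cw <- c(1.2, 0.9)
  ga <- sfgcn:::batch_grad_at(theta, params, caches, pidx, cw)
  eps <- 1e-5
  idx <- sample(length(theta), 60)  # spot-check a spread of coordinates
  gn <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (sfgcn:::batch_loss_at(tp, params, caches, pidx, cw) -
       sfgcn:::batch_loss_at(tm, params, caches, pidx, cw)) / (2 * eps)
  }, numeric(1))
  rel <- abs(ga[idx] - gn) / pmax(abs(ga[idx]), abs(gn), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("parameter flattening round-trips exactly", {
  params <- init_params(encoder_config(k = 2, d = 2), micro_model())
  v <- sfgcn:::params_to_vector(params)
  back <- sfgcn:::vector_to_params(v, params)
  expect_equal(back, params)
  expect_equal(n_params(params), length(v))
})
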