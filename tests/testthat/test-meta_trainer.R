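test_that("meta_datasets materializes a consistent partition of usable rows", {
  net <- tiny_network(seed = 41)
  split <- zone_split(net)
  d <- meta_datasets(net, split, arch = "mlp")
  n_base_train <- sum(vapply(d$base, function(t) length(t$train$y), numeric(1)))
  expect_equal(length(d$pool_train$y),
               n_base_train + length(d$target_train$y))
  # normalization stats are fitted on training rows only
  tr <- do.call(rbind, lapply(names(net$stations), function(id)
    net$stations[[id]]$data[split$rows[[id]]$train, ]))
  expect_equal(d$stats$mean[["TA"]], mean(tr$TA))
  # windowed mode produces 3-d inputs
  dw <- meta_datasets(net, split, arch = "lstm", window = 10)
  expect_length(dim(dw$pool_train$x), 3)
  expect_equal(dim(dw$pool_train$x)[2], 10)
})

test_that("zero epochs return the initializations untouched", {
  net <- tiny_network(seed = 42)
  d <- meta_datasets(net, zone_split(net), arch = "mlp")
  lcfg <- learner_config("mlp", input_dim = 5, hidden_size = 3)
  mcfg <- meta_config(epochs = 0L, ensemble_size = 2L, seed = 3)
  for (fit in list(meta_train(d, lcfg, mcfg),
                   baseline_train(d$pool_train, d$pool_test, lcfg, mcfg))) {
    for (m in seq_along(fit$members)) {
      cfg <- lcfg; cfg$seed <- fluxmeta:::child_seed(3, m)
      expect_identical(get_params(fit$members[[m]]),
                       get_params(build_learner(cfg)))
    }
  }
})

test_that("training is deterministic under a fixed seed and descends", {
  net <- tiny_network(seed = 43)
  d <- meta_datasets(net, zone_split(net), arch = "mlp")
  lcfg <- learner_config("mlp", input_dim = 5, hidden_size = 4)
  mcfg <- meta_config(epochs = 3L, ensemble_size = 1L, outer_lr = 1e-2, seed = 5)
  b1 <- baseline_train(d$pool_train, d$pool_test, lcfg, mcfg)
  b2 <- baseline_train(d$pool_train, d$pool_test, lcfg, mcfg)
  expect_identical(get_params(b1$members[[1]]), get_params(b2$members[[1]]))
  m1 <- meta_train(d, lcfg, mcfg)
  m2 <- meta_train(d, lcfg, mcfg)
  expect_identical(get_params(m1$members[[1]]), get_params(m2$members[[1]]))
  # descent sanity: validation RMSE improves over the run
  expect_lt(b1$history[3, 1], b1$history[1, 1])
})

test_that("a diverging run fails loudly, naming the epoch", {
  net <- tiny_network(seed = 44)
  d <- meta_datasets(net, zone_split(net), arch = "mlp")
  lcfg <- learner_config("mlp", input_dim = 5, hidden_size = 4)
  mcfg <- meta_config(epochs = 5L, ensemble_size = 1L, outer_opt = "sgd",
                      outer_lr = 1e6, seed = 1)
  expect_error(baseline_train(d$pool_train, d$pool_test, lcfg, mcfg),
               "divergence: non-finite loss at epoch")
})

test_that("ensemble prediction: mean, population std, degenerate cases", {
  x <- matrix(rnorm(10), 5, 2)
  two <- structure(list(members = list(constant_learner(1), constant_learner(3)),
                        mode = "baseline"), class = "ensemble_model")
  pe <- predict_ensemble(two, x)
  expect_equal(pe$mean, rep(2, 5))
  expect_equal(pe$std, rep(1, 5))          # population sd of {1, 3}
  one <- structure(list(members = list(constant_learner(4))),
                   class = "ensemble_model")
  expect_equal(predict_ensemble(one, x)$std, rep(0, 5))
  twin <- structure(list(members = list(constant_learner(4), constant_learner(4))),
                    class = "ensemble_model")
  expect_equal(predict_ensemble(twin, x)$std, rep(0, 5))
  # member order cannot matter
  swapped <- two; swapped$members <- rev(two$members)
  expect_equal(predict_ensemble(swapped, x), pe)
  empty <- structure(list(members = list()), class = "ensemble_model")
  expect_error(predict_ensemble(empty, x), "empty ensemble")
})

test_that("first-order and exact meta-gradients agree for inner_steps = 0 and
          differ once adaptation happens", {
  net <- tiny_network(seed = 45)
  d <- meta_datasets(net, zone_split(net), arch = "mlp")
  lcfg <- learner_config("mlp", input_dim = 5, hidden_size = 3)
  m0a <- meta_train(d, lcfg, meta_config(inner_steps = 0L, epochs = 1L,
                                         ensemble_size = 1L, first_order = TRUE,
                                         seed = 6))
  m0b <- meta_train(d, lcfg, meta_config(inner_steps = 0L, epochs = 1L,
                                         ensemble_size = 1L, first_order = FALSE,
                                         seed = 6))
  expect_equal(get_params(m0a$members[[1]]), get_params(m0b$members[[1]]))
  m1a <- meta_train(d, lcfg, meta_config(inner_steps = 1L, epochs = 1L,
                                         ensemble_size = 1L, first_order = TRUE,
                                         seed = 6))
  m1b <- meta_train(d, lcfg, meta_config(inner_steps = 1L, epochs = 1L,
                                         ensemble_size = 1L, first_order = FALSE,
                                         seed = 6))
  expect_false(identical(get_params(m1a$members[[1]]),
                         get_params(m1b$members[[1]])))
})

test_that("k-fold selection partitions stations and prefers adequate capacity", {
  net <- tiny_network(n_temperate = 6, n_tropics = 0, years = 1, seed = 46)
  mcfg <- meta_config(epochs = 8L, ensemble_size = 1L, outer_lr = 1e-2, seed = 2)
  candidates <- list(
    list(lcfg = learner_config("mlp", 5, hidden_size = 16), mcfg = mcfg),
    list(lcfg = learner_config("mlp", 5, hidden_size = 1), mcfg = mcfg))
  sel <- kfold_select(candidates, net, k = 3, seed = 4)
  expect_equal(sel$best_index, 1)          # truth-capacity net wins
  expect_equal(nrow(sel$scores), 2)
  expect_true(all(is.finite(sel$fold_scores)))
  one <- kfold_select(candidates[1], net, k = 3, seed = 4)
  expect_equal(one$best_index, 1)
  expect_error(kfold_select(candidates, net, k = 10, seed = 1),
               "configuration error")
})

test_that("ensemble checkpoints round trip and the log is well formed", {
  net <- tiny_network(seed = 47)
  d <- meta_datasets(net, zone_split(net), arch = "mlp")
  lcfg <- learner_config("mlp", input_dim = 5, hidden_size = 3)
  mcfg <- meta_config(epochs = 2L, ensemble_size = 2L, seed = 9)
  fit <- baseline_train(d$pool_train, d$pool_test, lcfg, mcfg)
  path <- tempfile(fileext = ".json")
  save_ensemble(fit, path)
  back <- load_ensemble(path)
  expect_equal(predict_ensemble(back, d$pool_test$x),
               predict_ensemble(fit, d$pool_test$x))
  logp <- tempfile(fileext = ".csv")
  write_train_log(fit, logp)
  log <- read.csv(logp)
  expect_equal(nrow(log), 2 * 2)
  expect_named(log, c("epoch", "member", "mode", "rmse"))
  unlink(c(path, logp))
})
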