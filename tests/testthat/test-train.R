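# Training protocol: loss, early stopping, ensembles, evaluation.

test_that("residual_loss closed-form checks", {
  expect_equal(residual_loss(c(-5, -3), c(-4, -2), c(-1, -1)), 0)
  y <- c(-5, -3); yp <- c(-4, -2.5)
  expect_equal(residual_loss(y, yp, c(0, 0)), mean((y - yp)^2))
  expect_equal(residual_loss(c(0, 0), c(3, 4), c(0, 0)), 12.5)
  expect_error(residual_loss(numeric(0), numeric(0), numeric(0)), "empty")
  expect_error(residual_loss(1:3, 1:2, 1:3), "length")
})

test_that("early stopping halts after exactly `patience` epochs past the best", {
  # immediate plateau: best at epoch 1, stop at 1 + patience
  tr <- solvcorr:::early_stopping_trace(rep(1.0, 50L), patience = 7L,
                                        min_delta = 0.01)
  expect_identical(tr$best_epoch, 1L)
  expect_identical(tr$stop_epoch, 8L)
  # improvements below min_delta do not reset the patience counter, but the
  # revert target still tracks the running minimum
  vals <- c(1.0, 0.996, 0.994, 0.993, 0.9925, 0.992)
  tr2 <- solvcorr:::early_stopping_trace(c(vals, rep(0.992, 20L)),
                                         patience = 5L, min_delta = 0.01)
  expect_identical(tr2$best_epoch, 6L)
  expect_identical(tr2$stop_epoch, 6L)
  # a real improvement resets it
  tr3 <- solvcorr:::early_stopping_trace(c(1, 0.5, rep(0.5, 10L)),
                                         patience = 4L, min_delta = 0.01)
  expect_identical(tr3$best_epoch, 2L)
  expect_identical(tr3$stop_epoch, 6L)
})

test_that("training is deterministic given the seed and learns a learnable residual", {
  # residual is an exact linear function of atom counts, so the network can
  # reduce validation RMSE below its starting point
  ds <- generate_synthetic_dataset(synthetic_spec(
    n_molecules = 90L, seed = 21L, noise_sigma = 0.05,
    high_uncertainty_fraction = 0))
  rec <- ds$records
  sp <- stratified_split(rec, seed = 1L)
  fz <- featurize_records(rec, feature_config("chem"))
  y <- stats::setNames(rec$expt_hfe, rec$id)
  yp <- physics_predictions(rec, "synthetic")
  tc <- train_config(batch_size = 50L, ensemble_size = 1L, base_seed = 5L,
                     max_epochs = 25L, patience = 25L)
  fit <- function() {
    train_member("graphconv", graphconv_config(), tc,
                 fz$graphs[sp$train_ids], fz$graphs[sp$val_ids],
                 y[sp$train_ids], y[sp$val_ids],
                 yp[sp$train_ids], yp[sp$val_ids], seed = 5L)
  }
  m1 <- fit()
  expect_lt(min(m1$history$val_rmse), m1$history$val_rmse[1L])
  expect_identical(m1$best_epoch, which.min(m1$history$val_rmse))
  m2 <- fit()
  expect_identical(m1$history, m2$history)
  expect_equal(m1$weights$W4, m2$weights$W4)
  # returned weights achieve the minimum recorded validation RMSE
  batchv <- solvcorr:::batch_graphs(fz$graphs[sp$val_ids])
  pv <- model_forward(m1$weights, batchv, graphconv_config())
  expect_equal(sqrt(mean((y[sp$val_ids] - (yp[sp$val_ids] + pv))^2)),
               min(m1$history$val_rmse), tolerance = 1e-10)
})

test_that("ensembles have distinct member seeds and average their outputs", {
  set <- tiny_graph_set(n = 12L, seed = 31L)
  rec <- set$records
  y <- stats::setNames(rec$expt_hfe, rec$id)
  yp <- stats::setNames(rec$calc_hfe, rec$id)
  train_ids <- rec$id[1:8]; val_ids <- rec$id[9:12]
  tc <- train_config(batch_size = 8L, ensemble_size = 3L, base_seed = 40L,
                     max_epochs = 3L, patience = 3L)
  ens <- train_ensemble("graphconv", graphconv_config(), tc,
                        set$graphs[train_ids], set$graphs[val_ids],
                        y[train_ids], y[val_ids], yp[train_ids], yp[val_ids])
  expect_length(ens$members, 3L)
  seeds <- vapply(ens$members, function(m) m$seed, 1L)
  expect_identical(seeds, c(40L, 41L, 42L))
  expect_false(any(duplicated(seeds)))
  # prediction equals the brute-force average of member outputs
  pr <- predict(ens, set$graphs[val_ids], yp[val_ids])
  member_preds <- sapply(ens$members, function(m) {
    model_forward(m$weights, set$graphs[val_ids], graphconv_config())
  })
  expect_equal(pr$correction, rowMeans(member_preds), tolerance = 1e-12)
  expect_equal(pr$final, unname(yp[val_ids]) + pr$correction)
  # single-member ensemble: prediction is that member's output
  tc1 <- train_config(batch_size = 8L, ensemble_size = 1L, base_seed = 40L,
                      max_epochs = 2L, patience = 2L)
  ens1 <- train_ensemble("graphconv", graphconv_config(), tc1,
                         set$graphs[train_ids], set$graphs[val_ids],
                         y[train_ids], y[val_ids], yp[train_ids], yp[val_ids])
  pr1 <- predict(ens1, set$graphs[val_ids], yp[val_ids])
  expect_equal(pr1$correction,
               model_forward(ens1$members[[1L]]$weights,
                             set$graphs[val_ids], graphconv_config()))
})

test_that("ensemble-mean RMSE never exceeds the mean of member RMSEs", {
  set <- tiny_graph_set(n = 10L, seed = 33L)
  rec <- set$records
  y <- rec$expt_hfe; yp <- rec$calc_hfe
  cfg <- graphconv_config()
  members <- lapply(1:4, function(s) {
    init_weights("graphconv", cfg, 24L, seed = s)
  })
  preds <- sapply(members, function(w) model_forward(w, set$graphs, cfg))
  mean_pred <- rowMeans(preds)
  rmse <- function(corr) sqrt(mean((y - (yp + corr))^2))
  member_rmses <- apply(preds, 2L, rmse)
  expect_lte(rmse(mean_pred), mean(member_rmses) + 1e-9)
})

test_that("evaluate_predictions computes RMSE and relative improvement", {
  ev <- evaluate_predictions(c("a", "b"), y_expt = c(0, 0),
                             final = c(3, 4), y_phys = c(4, 5))
  expect_equal(ev$rmse, sqrt(12.5))
  expect_equal(ev$rmse_physics_alone, sqrt(mean(c(16, 25))))
  perfect <- evaluate_predictions(c("a", "b"), c(-5, -3), c(-5, -3), c(-4, -2))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$relative_improvement, 1)
  nochange <- evaluate_predictions(c("a", "b"), c(-5, -3), c(-4, -2), c(-4, -2))
  expect_equal(nochange$relative_improvement, 0)
  expect_lte(ev$relative_improvement, 1)
  expect_error(evaluate_predictions(character(0), numeric(0), numeric(0),
                                    numeric(0)), "empty")
  # residual_loss equals evaluate rmse squared on any aligned set
  y <- c(-3, 1, -7); yp <- c(-2, 0.5, -8); corr <- c(-0.4, 0.2, 0.6)
  expect_equal(residual_loss(y, yp, corr),
               evaluate_predictions(letters[1:3], y, yp + corr, yp)$rmse^2)
})

test_that("evaluation reports are written as JSON and CSV", {
  ev <- evaluate_predictions(c("a", "b"), c(0, 0), c(3, 4), c(4, 5))
  dir <- withr::local_tempdir()
  write_eval_report(ev, json = file.path(dir, "e.json"),
                    csv = file.path(dir, "e.csv"))
  j <- jsonlite::read_json(file.path(dir, "e.json"), simplifyVector = TRUE)
  expect_equal(j$rmse, ev$rmse)
  csv <- utils::read.csv(file.path(dir, "e.csv"))
  expect_identical(names(csv),
                   c("id", "y_expt", "y_phys", "correction", "final", "error"))
})
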