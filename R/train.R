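# Residual training protocol: minibatch Adam on the combined-prediction MSE
#
#   L = (1/N) sum_i ( y_expt,i - (y_phys,i + y_corr,i) )^2  =  RMSE^2
#
# with early stopping on validation RMSE (minimum improvement 0.01 kcal/mol,
# patience 20 epochs for the MPNN and 100 for GraphConv), and ensembles of
# independently seeded members whose mean correction is added to the physics
# prediction. mode = "dnn_alone" drops the physics term and regresses the
# experimental HFE directly.

#' Residual-training configuration
#'
#' @param batch_size Minibatch size (default 100).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param patience Early-stopping patience in epochs; defaults per
#'   architecture (20 MPNN, 100 GraphConv) via [default_patience()].
#' @param min_delta Minimum validation-RMSE improvement that counts,
#'   kcal/mol (default 0.01).
#' @param max_epochs Safety cap on epochs.
#' @param ensemble_size Number of ensemble members (default 20).
#' @param base_seed Seed of member 0; member k trains with `base_seed + k`.
#' @param mode `"residual"` (correct a physics model) or `"dnn_alone"`
#'   (predict the HFE directly).
#' @returns A `train_config` list.
#' @export
train_config <- function(batch_size = 100L, learning_rate = 1e-3,
                         patience = NULL, min_delta = 0.01,
                         max_epochs = NULL, ensemble_size = 20L,
                         base_seed = 0L, mode = c("residual", "dnn_alone")) {
  mode <- match.arg(mode)
  if (!is.null(patience) && patience < 1L) stop("patience must be >= 1")
  if (min_delta < 0) stop("min_delta must be >= 0")
  if (ensemble_size < 1L) stop("ensemble_size must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = patience,
                 min_delta = min_delta, max_epochs = max_epochs,
                 ensemble_size = as.integer(ensemble_size),
                 base_seed = as.integer(base_seed), mode = mode),
            class = "train_config")
}

#' Default early-stopping patience and epoch cap per architecture
#'
#' @param kind `"mpnn"` or `"graphconv"`.
#' @returns List with `patience` (20 / 100 epochs) and `max_epochs`.
#' @export
default_patience <- function(kind = c("mpnn", "graphconv")) {
  kind <- match.arg(kind)
  if (kind == "mpnn") list(patience = 20L, max_epochs = 500L)
  else list(patience = 100L, max_epochs = 2000L)
}

#' Combined-prediction mean squared error (the training loss)
#'
#' @param y_expt Experimental HFEs (kcal/mol).
#' @param y_phys Physics-model predictions (kcal/mol); zeros in DNN-alone
#'   mode.
#' @param y_corr Model corrections (kcal/mol).
#' @returns Scalar loss in kcal^2/mol^2; its square root is the RMSE of the
#'   final predictions.
#' @export
residual_loss <- function(y_expt, y_phys, y_corr) {
  n <- length(y_expt)
  if (n == 0L) stop("empty batch")
  if (length(y_phys) != n || length(y_corr) != n) {
    stop("y_expt, y_phys, y_corr must share one length")
  }
  mean((y_expt - (y_phys + y_corr))^2)
}

#' Initialize model weights
#'
#' Deterministic given the seed; different seeds give different weights.
#'
#' @param kind `"graphconv"` or `"mpnn"`.
#' @param config The matching architecture configuration.
#' @param node_dim,edge_dim Feature dimensions of the graphs to be consumed.
#' @param seed Integer seed.
#' @returns A named list of parameter arrays with attributes `kind` and
#'   `seed`.
#' @export
init_weights <- function(kind = c("graphconv", "mpnn"), config, node_dim,
                         edge_dim = 0L, seed = 1L) {
  kind <- match.arg(kind)
  w <- .with_seed(seed, {
    if (kind == "graphconv") .graphconv_init(config, node_dim)
    else .mpnn_init(config, node_dim, edge_dim)
  })
  attr(w, "kind") <- kind
  attr(w, "seed") <- seed
  attr(w, "node_dim") <- node_dim
  attr(w, "edge_dim") <- edge_dim
  w
}

#' Forward pass of either architecture
#'
#' @param weights Output of [init_weights()] (or a trained member).
#' @param graphs A list of `sc_graph` objects or a prebuilt batch.
#' @param config The architecture configuration.
#' @param training Apply dropout (GraphConv) / training-mode behaviour.
#' @returns Numeric vector of per-graph scalar outputs (kcal/mol).
#' @export
model_forward <- function(weights, graphs, config, training = FALSE) {
  kind <- attr(weights, "kind")
  batch <- if (is.list(graphs) && !is.null(graphs$gather_idx)) graphs
           else batch_graphs(graphs)
  if (ncol(batch$X) != attr(weights, "node_dim")) {
    stop("node feature dimension (", ncol(batch$X),
         ") does not match weights (", attr(weights, "node_dim"), ")")
  }
  out <- if (kind == "graphconv") {
    .graphconv_forward(weights, batch, config, training)
  } else {
    .mpnn_forward(weights, batch, config, training)
  }
  out$pred
}

# internal: forward keeping the cache, plus backward dispatch
.forward_cached <- function(weights, batch, config, training) {
  if (attr(weights, "kind") == "graphconv") {
    .graphconv_forward(weights, batch, config, training)
  } else {
    .mpnn_forward(weights, batch, config, training)
  }
}
.backward <- function(weights, batch, cache, dpred, config) {
  if (attr(weights, "kind") == "graphconv") {
    .graphconv_backward(weights, batch, cache, dpred, config)
  } else {
    .mpnn_backward(weights, batch, cache, dpred, config)
  }
}

# early-stopping bookkeeping, exposed for testing. The revert target
# (best_epoch) is the last epoch where validation RMSE improved at all, i.e.
# the running minimum; the patience counter, however, only resets when the
# improvement over the thresholded best reaches min_delta.
early_stopping_trace <- function(val_rmse, patience, min_delta) {
  best_any <- Inf; best_epoch <- 0L
  best_delta <- Inf; delta_epoch <- 0L
  stop_epoch <- length(val_rmse)
  for (e in seq_along(val_rmse)) {
    if (val_rmse[e] < best_any) {
      best_any <- val_rmse[e]
      best_epoch <- e
    }
    if (val_rmse[e] <= best_delta - min_delta) {
      best_delta <- val_rmse[e]
      delta_epoch <- e
    }
    if (e - delta_epoch >= patience) { stop_epoch <- e; break }
  }
  list(best_epoch = best_epoch, stop_epoch = stop_epoch)
}

#' Train one ensemble member
#'
#' Minibatch Adam on the residual loss; after each epoch the validation RMSE
#' of the combined prediction is recorded, and training stops when it has not
#' improved by at least `min_delta` for `patience` epochs. The returned
#' weights are those of the best-validation epoch.
#'
#' @param kind `"graphconv"` or `"mpnn"`.
#' @param model_config Architecture configuration.
#' @param config A [train_config()].
#' @param train_graphs,val_graphs Named lists of `sc_graph`.
#' @param y_expt_train,y_expt_val Experimental HFEs aligned with the graphs.
#' @param y_phys_train,y_phys_val Physics predictions (ignored in
#'   `dnn_alone` mode).
#' @param seed Member seed (weights, shuffling, dropout).
#' @param verbose Emit one log line per epoch.
#' @returns List: `weights` (best epoch), `history` (data frame epoch /
#'   train_loss / val_rmse), `best_epoch`, `seed`.
#' @export
train_member <- function(kind, model_config, config, train_graphs, val_graphs,
                         y_expt_train, y_expt_val,
                         y_phys_train = NULL, y_phys_val = NULL,
                         seed = 1L, verbose = FALSE) {
  if (length(train_graphs) == 0L || length(val_graphs) == 0L) {
    stop("empty train or validation partition")
  }
  dnn_alone <- config$mode == "dnn_alone"
  if (dnn_alone) {
    y_phys_train <- rep(0, length(train_graphs))
    y_phys_val <- rep(0, length(val_graphs))
  }
  if (is.null(y_phys_train) || is.null(y_phys_val)) {
    stop("physics predictions required in residual mode")
  }
  pat <- config$patience
  maxe <- config$max_epochs
  defaults <- default_patience(kind)
  if (is.null(pat)) pat <- defaults$patience
  if (is.null(maxe)) maxe <- defaults$max_epochs

  node_dim <- ncol(train_graphs[[1L]]$node_features)
  edge_dim <- if (is.null(train_graphs[[1L]]$edge_features)) 0L
              else ncol(train_graphs[[1L]]$edge_features)
  n_train <- length(train_graphs)
  val_batch <- batch_graphs(val_graphs)

  .with_seed(seed, {
    weights <- if (kind == "graphconv") .graphconv_init(model_config, node_dim)
               else .mpnn_init(model_config, node_dim, edge_dim)
    attr(weights, "kind") <- kind
    attr(weights, "seed") <- seed
    attr(weights, "node_dim") <- node_dim
    attr(weights, "edge_dim") <- edge_dim
    state <- .adam_init(weights)

    best_rmse <- Inf; best_epoch <- 0L; best_weights <- weights
    best_delta_rmse <- Inf; delta_epoch <- 0L
    hist_epoch <- integer(0L); hist_loss <- numeric(0L); hist_val <- numeric(0L)

    for (epoch in seq_len(maxe)) {
      ord <- sample.int(n_train)
      nb <- ceiling(n_train / config$batch_size)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        take <- ord[(((b - 1L) * config$batch_size + 1L)):min(b * config$batch_size, n_train)]
        batch <- batch_graphs(train_graphs[take])
        fw <- .forward_cached(weights, batch, model_config, training = TRUE)
        resid <- y_expt_train[take] - y_phys_train[take]
        err <- fw$pred - resid
        loss <- mean(err^2)
        ep_loss <- ep_loss + loss * length(take)
        dpred <- 2 * err / length(take)
        grads <- .backward(weights, batch, fw$cache, dpred, model_config)
        upd <- .adam_step(weights, grads, state, lr = config$learning_rate)
        a <- attributes(weights)
        weights <- upd$params
        attributes(weights) <- a
        state <- upd$state
      }
      val_pred <- .forward_cached(weights, val_batch, model_config,
                                  training = FALSE)$pred
      val_rmse <- sqrt(mean((y_expt_val - (y_phys_val + val_pred))^2))
      hist_epoch <- c(hist_epoch, epoch)
      hist_loss <- c(hist_loss, ep_loss / n_train)
      hist_val <- c(hist_val, val_rmse)
      if (val_rmse < best_rmse) {
        best_rmse <- val_rmse
        best_epoch <- epoch
        best_weights <- weights
      }
      if (val_rmse <= best_delta_rmse - config$min_delta) {
        best_delta_rmse <- val_rmse
        delta_epoch <- epoch
      }
      if (verbose) {
        message(sprintf("epoch %3d  train_loss %.4f  val_rmse %.4f  best %d",
                        epoch, ep_loss / n_train, val_rmse, best_epoch))
      }
      if (epoch - delta_epoch >= pat) break
    }
    list(weights = best_weights,
         history = data.frame(epoch = hist_epoch, train_loss = hist_loss,
                              val_rmse = hist_val),
         best_epoch = best_epoch, seed = seed)
  })
}

#' Train a seeded ensemble
#'
#' All members see identical data; member k uses seed `base_seed + k - 1` for
#' initialization, batch shuffling and dropout.
#'
#' @inheritParams train_member
#' @param verbose Emit a line per member.
#' @returns An `sc_ensemble`: `members` (list from [train_member()]),
#'   `kind`, `model_config`, `config`.
#' @export
train_ensemble <- function(kind, model_config, config, train_graphs,
                           val_graphs, y_expt_train, y_expt_val,
                           y_phys_train = NULL, y_phys_val = NULL,
                           verbose = FALSE) {
  members <- vector("list", config$ensemble_size)
  for (k in seq_len(config$ensemble_size)) {
    members[[k]] <- train_member(kind, model_config, config, train_graphs,
                                 val_graphs, y_expt_train, y_expt_val,
                                 y_phys_train, y_phys_val,
                                 seed = config$base_seed + k - 1L)
    if (verbose) {
      message(sprintf("member %2d/%d  best epoch %d  val RMSE %.4f", k,
                      config$ensemble_size, members[[k]]$best_epoch,
                      min(members[[k]]$history$val_rmse)))
    }
  }
  structure(list(members = members, kind = kind, model_config = model_config,
                 config = config),
            class = "sc_ensemble")
}

#' @export
print.sc_ensemble <- function(x, ...) {
  cat("<ensemble>", length(x$members), x$kind, "members, mode",
      x$config$mode, "\n")
  invisible(x)
}

#' Ensemble prediction
#'
#' The correction is the arithmetic mean of the member outputs; the final
#' prediction adds the physics baseline in residual mode, or is the mean
#' output itself in DNN-alone mode.
#'
#' @param object An `sc_ensemble`.
#' @param graphs Named list of `sc_graph`.
#' @param y_phys Physics predictions aligned with `graphs` (residual mode).
#' @param ... Unused.
#' @returns A data frame: id, correction, final.
#' @export
predict.sc_ensemble <- function(object, graphs, y_phys = NULL, ...) {
  batch <- batch_graphs(graphs)
  for (m in object$members) {
    if (ncol(batch$X) != attr(m$weights, "node_dim")) {
      stop("feature configuration does not match the trained ensemble")
    }
  }
  preds <- vapply(object$members, function(m) {
    .forward_cached(m$weights, batch, object$model_config, FALSE)$pred
  }, numeric(batch$G))
  preds <- matrix(preds, nrow = batch$G)
  corr <- rowMeans(preds)
  if (object$config$mode == "dnn_alone") {
    final <- corr
  } else {
    if (is.null(y_phys)) stop("y_phys required in residual mode")
    final <- y_phys + corr
  }
  data.frame(id = names(graphs), correction = corr, final = final,
             stringsAsFactors = FALSE)
}

#' Evaluate final predictions against experiment
#'
#' @param ids Molecule ids.
#' @param y_expt Experimental HFEs (kcal/mol).
#' @param final Final model predictions (kcal/mol).
#' @param y_phys Physics-alone predictions (kcal/mol).
#' @returns An `sc_eval`: `rmse`, `rmse_physics_alone`,
#'   `relative_improvement` = (RMSE_phys - RMSE) / RMSE_phys, and a
#'   per-molecule table (id, y_expt, y_phys, correction, final, error).
#' @export
evaluate_predictions <- function(ids, y_expt, final, y_phys) {
  n <- length(ids)
  if (n == 0L) stop("empty evaluation set")
  stopifnot(length(y_expt) == n, length(final) == n, length(y_phys) == n)
  rmse <- sqrt(mean((y_expt - final)^2))
  rmse_phys <- sqrt(mean((y_expt - y_phys)^2))
  structure(list(
    rmse = rmse, rmse_physics_alone = rmse_phys,
    relative_improvement = (rmse_phys - rmse) / rmse_phys,
    table = data.frame(id = ids, y_expt = y_expt, y_phys = y_phys,
                       correction = final - y_phys, final = final,
                       error = final - y_expt, stringsAsFactors = FALSE)
  ), class = "sc_eval")
}

#' @export
print.sc_eval <- function(x, ...) {
  cat(sprintf("<evaluation> RMSE %.3f kcal/mol (physics alone %.3f, relative improvement %.1f%%)\n",
              x$rmse, x$rmse_physics_alone, 100 * x$relative_improvement))
  invisible(x)
}

#' Write an evaluation report
#'
#' @param eval An `sc_eval`.
#' @param json Optional JSON path (metrics + table).
#' @param csv Optional CSV path (per-molecule table).
#' @returns `eval`, invisibly.
#' @export
write_eval_report <- function(eval, json = NULL, csv = NULL) {
  if (!is.null(json)) {
    jsonlite::write_json(list(
      rmse = eval$rmse, rmse_physics_alone = eval$rmse_physics_alone,
      relative_improvement = eval$relative_improvement,
      per_molecule = eval$table
    ), json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv)) utils::write.csv(eval$table, csv, row.names = FALSE)
  invisible(eval)
}

#' Save / load model weights
#'
#' Single-file serialization embedding the architecture kind, configuration
#' and seed; a round trip reproduces forward outputs exactly.
#'
#' @param weights Weights (e.g. a trained member's).
#' @param config The architecture configuration.
#' @param file Path.
#' @returns `file` invisibly / the list `(weights, config)`.
#' @export
save_model <- function(weights, config, file) {
  saveRDS(list(weights = weights, config = config,
               kind = attr(weights, "kind"), seed = attr(weights, "seed"),
               node_dim = attr(weights, "node_dim"),
               edge_dim = attr(weights, "edge_dim")), file)
  invisible(file)
}

#' @rdname save_model
#' @export
load_model <- function(file) {
  obj <- readRDS(file)
  w <- obj$weights
  attr(w, "kind") <- obj$kind
  attr(w, "seed") <- obj$seed
  attr(w, "node_dim") <- obj$node_dim
  attr(w, "edge_dim") <- obj$edge_dim
  list(weights = w, config = obj$config)
}
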