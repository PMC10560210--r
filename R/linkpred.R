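#' Area under the ROC curve from score groups
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counted one half (the midrank / Mann-Whitney formulation).
#'
#' @param scores_for_positives,scores_for_negatives numeric score vectors.
#' @return AUC in \[0, 1\]; `NA` with a warning when a group is empty.
#' @examples
#' auc(c(0.9, 0.4), c(0.6, 0.1)) # 0.75
#' @export
auc <- function(scores_for_positives, scores_for_negatives) {
  np <- length(scores_for_positives)
  nn <- length(scores_for_negatives)
  if (np == 0 || nn == 0) {
    warning("AUC undefined: a score group is empty", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(c(scores_for_positives, scores_for_negatives))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# fold assignment over the cells of one layer: each cell gets a fold 1..n_folds
assign_folds <- function(n_cells, n_folds) {
  sample(rep(seq_len(n_folds), length.out = n_cells))
}

# one hold-out evaluation: fit on visible cells of the target layer (plus an
# optional fully-visible auxiliary layer), score the masked target cells.
holdout_auc <- function(mats, target_layer, visible, K, n_restarts, max_iter,
                        tolerance, seed) {
  target <- mats[[target_layer]]
  Zt <- matrix(0, nrow(target), ncol(target))
  Zt[visible] <- 1
  layers <- mats
  mask <- lapply(mats, function(m) matrix(1, nrow(m), ncol(m)))
  mask[[target_layer]] <- Zt
  net <- as_cci_network(layers)
  fit <- suppressWarnings(fit_multitensor(
    net,
    K = K, n_restarts = n_restarts, max_iter = max_iter,
    tolerance = tolerance, seed = seed, mask = mask
  ))
  M <- expected_edges(fit)[[target_layer]]
  masked <- which(Zt == 0)
  labels <- target[masked]
  if (!any(labels == 1) || !any(labels == 0)) {
    warning("fold without both masked positives and negatives skipped", call. = FALSE)
    return(NA_real_)
  }
  auc(M[masked][labels == 1], M[masked][labels == 0])
}

#' Within-layer link prediction by cell hold-out
#'
#' Repeated inverted 5-fold cross-validation on one layer: per repetition the
#' layer's adjacency cells are partitioned into `n_folds` folds; each fold in
#' turn is the visible 20% from which the SBM is fitted (masked cells are
#' excluded from the likelihood), and the fitted expected-edge values score
#' the held-out 80% of cells against their true 0/1 labels (AUC). The
#' hold-out unit is the adjacency cell — both present and absent links — so
#' negatives exist for the ROC.
#'
#' @param net a [cci_network()] or anything [as_cci_network()] accepts.
#' @param target_layer layer to predict.
#' @param K group count used for prediction (default 2).
#' @param n_reps repetitions (full-scale default 20).
#' @param n_folds folds per repetition (default 5; one fold visible at a
#'   time, realizing the 80% hold-out).
#' @param seed master seed; each (rep, fold) uses its own substream.
#' @param n_restarts,max_iter,tolerance EM settings per fit (lighter defaults
#'   than [fit_multitensor()], since each grid cell needs
#'   `n_reps * n_folds` fits).
#' @return mean AUC over folds and repetitions (skipped folds excluded).
#' @export
predict_within <- function(net, target_layer, K = 2, n_reps = 20, n_folds = 5,
                           seed = 1L, n_restarts = 2, max_iter = 200,
                           tolerance = 1e-4) {
  mats <- layer_matrices(as_cci_network(net))
  stopifnot(target_layer %in% names(mats))
  target <- mats[[target_layer]]
  vals <- c()
  for (rep in seq_len(n_reps)) {
    set.seed(seed + 7919L * rep)
    folds <- assign_folds(length(target), n_folds)
    for (f in seq_len(n_folds)) {
      vals <- c(vals, holdout_auc(
        mats[target_layer], target_layer,
        visible = which(folds == f), K = K,
        n_restarts = n_restarts, max_iter = max_iter, tolerance = tolerance,
        seed = seed + 7919L * rep + f
      ))
    }
  }
  mean(vals, na.rm = TRUE)
}

#' Cross-layer link prediction
#'
#' As [predict_within()], but each fit sees the visible 20% of the target
#' layer plus the full auxiliary layer (a two-layer model); the target
#' layer's expected-edge values score its masked cells.
#'
#' @inheritParams predict_within
#' @param auxiliary_layer helper layer (must differ from `target_layer`).
#' @return mean AUC over folds and repetitions.
#' @export
predict_cross <- function(net, target_layer, auxiliary_layer, K = 2,
                          n_reps = 20, n_folds = 5, seed = 1L,
                          n_restarts = 2, max_iter = 200, tolerance = 1e-4) {
  stopifnot(target_layer != auxiliary_layer)
  mats <- layer_matrices(as_cci_network(net))
  stopifnot(all(c(target_layer, auxiliary_layer) %in% names(mats)))
  target <- mats[[target_layer]]
  vals <- c()
  for (rep in seq_len(n_reps)) {
    set.seed(seed + 7919L * rep)
    folds <- assign_folds(length(target), n_folds)
    for (f in seq_len(n_folds)) {
      vals <- c(vals, holdout_auc(
        mats[c(target_layer, auxiliary_layer)], target_layer,
        visible = which(folds == f), K = K,
        n_restarts = n_restarts, max_iter = max_iter, tolerance = tolerance,
        seed = seed + 7919L * rep + f
      ))
    }
  }
  mean(vals, na.rm = TRUE)
}

#' Full layer x layer link-prediction grid
#'
#' Diagonal entries come from [predict_within()], off-diagonal entries from
#' [predict_cross()] (row = predicted layer, column = auxiliary layer). The
#' grid is generally asymmetric.
#'
#' @inheritParams predict_within
#' @return object of class `cci_prediction`: list with `auc` (tidy tibble:
#'   `target_layer`, `auxiliary_layer`, `auc`), `n_reps`, `n_folds`, `K`.
#' @export
prediction_grid <- function(net, K = 2, n_reps = 20, n_folds = 5, seed = 1L,
                            n_restarts = 2, max_iter = 200, tolerance = 1e-4) {
  net <- as_cci_network(net)
  if (length(net$layers) < 2) stop("need at least 2 layers", call. = FALSE)
  grid <- expand.grid(
    target_layer = net$layers, auxiliary_layer = net$layers,
    stringsAsFactors = FALSE
  )
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    tl <- grid$target_layer[i]
    al <- grid$auxiliary_layer[i]
    cell_seed <- seed + 104729L * i
    if (tl == al) {
      predict_within(net, tl,
        K = K, n_reps = n_reps, n_folds = n_folds, seed = cell_seed,
        n_restarts = n_restarts, max_iter = max_iter, tolerance = tolerance
      )
    } else {
      predict_cross(net, tl, al,
        K = K, n_reps = n_reps, n_folds = n_folds, seed = cell_seed,
        n_restarts = n_restarts, max_iter = max_iter, tolerance = tolerance
      )
    }
  }, numeric(1))
  structure(
    list(
      auc = tibble::as_tibble(grid), n_reps = n_reps, n_folds = n_folds, K = K
    ),
    class = "cci_prediction"
  )
}

#' @export
print.cci_prediction <- function(x, ...) {
  within <- x$auc$auc[x$auc$target_layer == x$auc$auxiliary_layer]
  cross <- x$auc$auc[x$auc$target_layer != x$auc$auxiliary_layer]
  cat(
    "<cci_prediction> K = ", x$K, ", ", x$n_reps, " reps x ", x$n_folds,
    " folds; within-layer AUC ", sprintf("%.3f-%.3f", min(within), max(within)),
    if (length(cross)) sprintf(", cross-layer AUC %.3f-%.3f", min(cross), max(cross)) else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @method autoplot cci_prediction
#' @export
autoplot.cci_prediction <- function(object, ...) {
  ggplot2::ggplot(
    object$auc,
    ggplot2::aes(x = .data$auxiliary_layer, y = .data$target_layer, fill = .data$auc)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$auc)), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "auxiliary layer", y = "predicted layer", fill = "AUC")
}
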