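#' Curveball fixed-margin randomization of a binary matrix
#'
#' Randomizes a binary matrix while preserving every row and column sum
#' exactly. Each trade picks two distinct rows, pools the columns held by
#' exactly one of them, and re-deals that pool at random between the two rows
#' (each row keeping its original count). Margins are conserved by
#' construction after every trade.
#'
#' @param mat binary matrix.
#' @param n_trades number of trades; default `5 * nrow(mat)`, a standard
#'   mixing heuristic (configurable; see [curveball_trace()] for diagnostics).
#' @param seed optional integer seed.
#' @return shuffled binary matrix with identical dimnames and margins.
#' @examples
#' m <- diag(2)
#' curveball(m, 10, seed = 1)
#' @export
curveball <- function(mat, n_trades = 5 * nrow(mat), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(mat %in% c(0, 1)), n_trades >= 1)
  if (nrow(mat) < 2) {
    warning("matrix has fewer than 2 rows; returned unchanged", call. = FALSE)
    return(mat)
  }
  # row support sets; trades touch only the symmetric difference
  supports <- apply(mat != 0, 1, which, simplify = FALSE)
  n <- nrow(mat)
  for (t in seq_len(n_trades)) {
    rows <- sample.int(n, 2L)
    s1 <- supports[[rows[1]]]
    s2 <- supports[[rows[2]]]
    only1 <- setdiff(s1, s2)
    only2 <- setdiff(s2, s1)
    n1 <- length(only1)
    if (n1 == 0L || length(only2) == 0L) next
    pool <- c(only1, only2)
    take1 <- pool[sample.int(length(pool), n1)]
    supports[[rows[1]]] <- c(setdiff(s1, only1), take1)
    supports[[rows[2]]] <- c(setdiff(s2, only2), setdiff(pool, take1))
  }
  out <- matrix(0L, n, ncol(mat), dimnames = dimnames(mat))
  for (i in seq_len(n)) out[i, supports[[i]]] <- 1L
  out
}

#' Curveball mixing diagnostic
#'
#' Records a scalar statistic of the shuffled matrix after every trade, so
#' users can judge how many trades are needed for the chain to mix.
#'
#' @inheritParams curveball
#' @param statistic function taking a binary matrix and returning a scalar
#'   (default: spectral radius).
#' @return tibble with columns `trade`, `value`.
#' @export
curveball_trace <- function(mat, n_trades = 20 * nrow(mat), statistic = spectral_radius,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  values <- numeric(n_trades)
  m <- mat
  for (t in seq_len(n_trades)) {
    m <- curveball(m, n_trades = 1)
    values[t] <- statistic(m)
  }
  tibble::tibble(trade = seq_len(n_trades), value = values)
}

#' Empirical one-tailed p-value against a null sample
#'
#' The fraction of null samples strictly greater than the observed value;
#' ties count toward non-significance.
#'
#' @param observed scalar.
#' @param null_samples numeric vector of the statistic under the null.
#' @return p in \[0, 1\].
#' @export
empirical_pvalue <- function(observed, null_samples) {
  if (length(null_samples) < 1) stop("empty null sample", call. = FALSE)
  sum(null_samples > observed) / length(null_samples)
}

#' Z-score of an observed value against a null sample
#'
#' `z = (observed - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation; significance at the 0.05 level is `|z| > 1.96`.
#'
#' @inheritParams empirical_pvalue
#' @return one-row tibble with `z`, `null_mean`, `null_sd`, `significant`.
#'   A null with zero spread gives `z = NA` (flagged, not significant).
#' @export
zscore <- function(observed, null_samples) {
  if (length(null_samples) < 2) stop("need at least 2 null samples", call. = FALSE)
  mu <- mean(null_samples)
  sdev <- stats::sd(null_samples)
  z <- if (sdev > 0) (observed - mu) / sdev else NA_real_
  if (is.na(z)) warning("null sample has zero standard deviation; z undefined", call. = FALSE)
  tibble::tibble(
    z = z, null_mean = mu, null_sd = sdev,
    significant = !is.na(z) & abs(z) > 1.96
  )
}

#' Ensemble of curveball-shuffled multilayer networks
#'
#' Every replicate shuffles each layer independently with [curveball()],
#' preserving all per-layer row and column sums. Optionally evaluates a
#' statistic on each replicate.
#'
#' @param net a [cci_network()] or anything [as_cci_network()] accepts.
#' @param n_replicates number of shuffled networks (full-scale default 1000).
#' @param n_trades trades per layer per replicate; default 5 x #chaperones.
#' @param seed master seed; replicate r uses substream `seed + r`.
#' @param statistic optional function mapping a list of layer matrices to a
#'   scalar, evaluated on every replicate.
#' @param keep_replicates keep the shuffled matrices (memory-heavy for large
#'   ensembles); default TRUE when `statistic` is NULL.
#' @return object of class `null_ensemble`: list with `replicates` (list of
#'   layer-matrix lists, possibly NULL), `statistic_samples` (numeric or
#'   NULL), `seed`, `n_trades`.
#' @export
shuffle_ensemble <- function(net, n_replicates = 1000, n_trades = NULL, seed = 1L,
                             statistic = NULL, keep_replicates = is.null(statistic)) {
  mats <- layer_matrices(net)
  n_trades <- n_trades %||% (5L * nrow(mats[[1]]))
  replicates <- if (keep_replicates) vector("list", n_replicates) else NULL
  samples <- if (!is.null(statistic)) numeric(n_replicates) else NULL
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    shuffled <- lapply(mats, curveball, n_trades = n_trades)
    if (keep_replicates) replicates[[r]] <- shuffled
    if (!is.null(statistic)) samples[r] <- statistic(shuffled)
  }
  structure(
    list(
      replicates = replicates, statistic_samples = samples,
      seed = seed, n_trades = n_trades, n_replicates = n_replicates
    ),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(
    "<null_ensemble> ", x$n_replicates, " curveball replicates (",
    x$n_trades, " trades/layer, seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}
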