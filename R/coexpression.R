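#' Spearman coexpression of chaperones against clients in one layer
#'
#' Computes the Spearman rank correlation (midranks for ties) and a two-sided
#' p-value (t approximation on n - 2 degrees of freedom) for every chaperone x
#' client pair, then applies a Bonferroni correction whose family is all pairs
#' tested within the layer (m = #chaperones x #clients). A pair is marked
#' significant-positive when its corrected p-value is below `alpha` and its
#' correlation is positive. Constant-expression genes yield undefined
#' correlations; their pairs are flagged non-significant with a warning.
#'
#' @param expr an [expression_matrix()] (genes x samples).
#' @param chaperone_ids,client_ids gene identifiers to correlate; all must be
#'   present in `expr`.
#' @param alpha family-wise significance level (default 0.05).
#' @return object of class `cci_correlation`: list with matrices `rho`,
#'   `p_value`, `p_bonferroni`, `significant_positive` (0/1), scalar
#'   `n_tests`, `alpha`, `layer_id`, `n_samples`.
#' @export
correlate_layer <- function(expr, chaperone_ids, client_ids, alpha = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  missing <- setdiff(c(chaperone_ids, client_ids), rownames(expr))
  if (length(missing)) {
    stop("genes absent from expression matrix: ", paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (ncol(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  res <- spearman_grid(unclass(expr), chaperone_ids, client_ids)
  n_tests <- length(chaperone_ids) * length(client_ids)
  p_bon <- pmin(1, res$p * n_tests)
  sig <- (res$rho > 0 & p_bon < alpha)
  undef <- is.na(res$rho)
  if (any(undef)) {
    warning(
      sum(undef), " pair(s) with undefined correlation (constant expression) treated as non-significant",
      call. = FALSE
    )
    sig[undef] <- FALSE
  }
  structure(
    list(
      rho = res$rho, p_value = res$p, p_bonferroni = p_bon,
      significant_positive = sig + 0L, n_tests = n_tests, alpha = alpha,
      layer_id = attr(expr, "layer_id"), n_samples = ncol(expr)
    ),
    class = "cci_correlation"
  )
}

# vectorised Spearman (midranks) with two-sided t-approximation p-values
spearman_grid <- function(values, row_ids, col_ids) {
  n <- ncol(values)
  rank_rows <- function(ids) t(apply(values[ids, , drop = FALSE], 1, rank))
  rx <- rank_rows(row_ids)
  ry <- rank_rows(col_ids)
  suppressWarnings(rho <- stats::cor(t(rx), t(ry))) # Pearson of midranks = Spearman
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  dimnames(rho) <- dimnames(p) <- list(row_ids, col_ids)
  list(rho = rho, p = p)
}

#' @export
print.cci_correlation <- function(x, ...) {
  cat(
    "<cci_correlation> layer '", x$layer_id, "': ", nrow(x$rho), " x ", ncol(x$rho),
    " pairs, ", sum(x$significant_positive), " significant-positive (alpha = ",
    x$alpha, ", Bonferroni m = ", x$n_tests, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy cci_correlation
#' @export
tidy.cci_correlation <- function(x, ...) {
  tibble::tibble(
    chaperone = rep(rownames(x$rho), times = ncol(x$rho)),
    client = rep(colnames(x$rho), each = nrow(x$rho)),
    rho = as.vector(x$rho),
    p_value = as.vector(x$p_value),
    p_bonferroni = as.vector(x$p_bonferroni),
    significant_positive = as.vector(x$significant_positive) == 1
  )
}

#' Bootstrap-consensus interaction layer
#'
#' Builds a binary chaperone-client interaction layer whose statistical power
#' is matched across environments: `n_boot` times, draw `n_subsample` samples
#' without replacement, run [correlate_layer()] on the subsample, and mark
#' the significant-positive pairs. A pair is an interaction when it was marked
#' in at least `consensus_threshold` of the attempts (a fraction of exactly
#' 0.95 qualifies at the default threshold).
#'
#' @inheritParams correlate_layer
#' @param n_subsample samples drawn per attempt, without replacement (match
#'   this to the smallest cohort across environments; 288 at full scale).
#' @param n_boot number of bootstrap attempts (default 1000).
#' @param consensus_threshold minimal fraction of attempts in which a pair
#'   must be significant-positive (default 0.95).
#' @param seed master seed; attempt b uses substream `seed + b`.
#' @return object of class `cci_consensus`: list with `incidence` (0/1
#'   matrix), `support` (fraction of attempts per pair), `n_boot`,
#'   `consensus_threshold`, `n_subsample`, `alpha`, `layer_id`.
#' @export
bootstrap_consensus <- function(expr, chaperone_ids, client_ids,
                                n_subsample, n_boot = 1000,
                                consensus_threshold = 0.95, alpha = 0.05,
                                seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"))
  n_total <- ncol(expr)
  if (n_subsample > n_total) stop("n_subsample exceeds available samples", call. = FALSE)
  if (n_subsample == n_total) {
    warning("n_subsample equals the full sample count; attempts are identical", call. = FALSE)
  }
  counts <- matrix(
    0L, length(chaperone_ids), length(client_ids),
    dimnames = list(chaperone_ids, client_ids)
  )
  for (b in seq_len(n_boot)) {
    set.seed(seed + b)
    keep <- sample.int(n_total, n_subsample)
    sub <- expression_matrix(unclass(expr)[, keep, drop = FALSE], attr(expr, "layer_id"))
    res <- suppressWarnings(correlate_layer(sub, chaperone_ids, client_ids, alpha = alpha))
    counts <- counts + res$significant_positive
  }
  support <- counts / n_boot
  structure(
    list(
      incidence = consensus_from_support(support, consensus_threshold),
      support = support,
      n_boot = n_boot, consensus_threshold = consensus_threshold,
      n_subsample = n_subsample, alpha = alpha,
      layer_id = attr(expr, "layer_id")
    ),
    class = "cci_consensus"
  )
}

#' Apply the consensus rule to per-pair support fractions
#'
#' @param support matrix of fractions of attempts in which each pair was
#'   significant-positive.
#' @param consensus_threshold minimal qualifying fraction ("at least": equality
#'   qualifies).
#' @return 0/1 incidence matrix.
#' @export
consensus_from_support <- function(support, consensus_threshold = 0.95) {
  (support >= consensus_threshold) + 0L
}

#' @export
print.cci_consensus <- function(x, ...) {
  cat(
    "<cci_consensus> layer '", x$layer_id, "': ", sum(x$incidence), " edges from ",
    x$n_boot, " attempts of n = ", x$n_subsample,
    " (threshold ", x$consensus_threshold, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Assemble a multilayer network from per-layer expression matrices
#'
#' Runs [bootstrap_consensus()] on every layer with a shared subsample size
#' (defaulting to the smallest cohort, the device that equalizes statistical
#' power across environments) and binds the consensus layers into one
#' [cci_network()].
#'
#' @param expr_list named list of [expression_matrix()] objects.
#' @inheritParams bootstrap_consensus
#' @param n_subsample defaults to the smallest sample count across layers.
#' @return a [cci_network()].
#' @export
build_consensus_network <- function(expr_list, chaperone_ids, client_ids,
                                    n_subsample = NULL, n_boot = 1000,
                                    consensus_threshold = 0.95, alpha = 0.05,
                                    seed = 1L) {
  n_subsample <- n_subsample %||% min(vapply(expr_list, ncol, integer(1)))
  mats <- purrr::imap(expr_list, function(e, id) {
    bootstrap_consensus(
      e, chaperone_ids, client_ids,
      n_subsample = n_subsample, n_boot = n_boot,
      consensus_threshold = consensus_threshold, alpha = alpha,
      seed = seed + 1000L * match(id, names(expr_list))
    )$incidence
  })
  as_cci_network(mats)
}
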