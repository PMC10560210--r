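#' Multilayer mixed-membership stochastic block model
#'
#' Fits the bipartite multilayer mixed-membership SBM by multiplicative
#' expectation-maximization. Each chaperone i carries an outgoing-membership
#' vector u_i over K groups, each client j an incoming vector v_j, and each
#' layer a a K x K affinity matrix w; the expected number of edges from i to
#' j in layer a is the bilinear form `M_ij = sum_kl u_ik v_jl w_kl`. The
#' binary adjacencies are treated as Poisson counts, giving the
#' log-likelihood `sum_a sum_ij [A_ij log M_ij - M_ij]` (over observed cells
#' only when a mask is supplied). The multiplicative updates never decrease
#' the log-likelihood; the best of `n_restarts` random initializations is
#' returned.
#'
#' @param net a [cci_network()] or anything [as_cci_network()] accepts.
#' @param K number of groups (>= 1).
#' @param n_restarts random restarts (default 10).
#' @param tolerance absolute log-likelihood improvement below which the run
#'   stops, checked every `check_every` iterations (default 1e-6).
#' @param max_iter iteration cap per restart (default 500); hitting it sets
#'   `converged = FALSE` with a warning.
#' @param seed integer seed; restart r uses substream `seed + r`.
#' @param mask optional named list of 0/1 matrices aligned with the layers;
#'   1 = cell observed. Masked (0) cells contribute nothing to the likelihood
#'   or the updates, which is what hold-out link prediction needs.
#' @param check_every convergence check stride (default 10).
#' @return object of class `multitensor_fit`: list with `u`, `v` (nodes x K),
#'   `w` (list of K x K matrices per layer), `K`, `log_likelihood`, `trace`
#'   (per-iteration log-likelihood of the winning restart), `BIC`,
#'   `converged`, `n_restarts`, `chaperones`, `clients`, `layers`.
#' @export
fit_multitensor <- function(net, K, n_restarts = 10, tolerance = 1e-6,
                            max_iter = 500, seed = 1L, mask = NULL,
                            check_every = 10) {
  stopifnot(K >= 1, n_restarts >= 1, max_iter >= 1)
  net <- as_cci_network(net)
  A <- layer_matrices(net)
  if (sum(vapply(A, sum, numeric(1))) == 0) stop("network has no edges", call. = FALSE)
  n <- length(net$chaperones)
  m <- length(net$clients)
  L <- length(net$layers)
  Z <- mask %||% rep(list(matrix(1, n, m)), L)
  if (is.null(names(Z))) names(Z) <- net$layers
  Z <- Z[net$layers]
  ZA <- purrr::map2(Z, A, `*`)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    fit <- em_run(ZA, Z, n, m, L, K, tolerance, max_iter, check_every)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  if (!best$converged) {
    warning("EM did not converge within max_iter = ", max_iter, call. = FALSE)
  }

  rownames(best$u) <- net$chaperones
  rownames(best$v) <- net$clients
  names(best$w) <- net$layers
  p <- K * (n + m) + K^2 * L
  n_obs <- sum(vapply(Z, sum, numeric(1)))
  structure(
    c(best, list(
      K = K, BIC = -2 * best$log_likelihood + p * log(n_obs),
      n_parameters = p, n_observed_cells = n_obs, n_restarts = n_restarts,
      chaperones = net$chaperones, clients = net$clients, layers = net$layers
    )),
    class = "multitensor_fit"
  )
}

# one EM run from a random start; ZA = masked adjacency, Z = mask
em_run <- function(ZA, Z, n, m, L, K, tolerance, max_iter, check_every) {
  eps <- 1e-12
  U <- matrix(stats::runif(n * K), n, K)
  V <- matrix(stats::runif(m * K), m, K)
  W <- lapply(seq_len(L), function(a) matrix(stats::runif(K * K), K, K))

  M <- function() lapply(seq_len(L), function(a) U %*% W[[a]] %*% t(V))
  loglik <- function(Ms) {
    sum(vapply(seq_len(L), function(a) {
      Mz <- pmax(Ms[[a]], eps)
      sum(ZA[[a]] * log(Mz)) - sum(Z[[a]] * Ms[[a]])
    }, numeric(1)))
  }

  Ms <- M()
  trace <- numeric(0)
  ll_prev <- loglik(Ms)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ratio <- lapply(seq_len(L), function(a) ZA[[a]] / pmax(Ms[[a]], eps))

    # U update
    num <- Reduce(`+`, lapply(seq_len(L), function(a) ratio[[a]] %*% (V %*% t(W[[a]]))))
    den <- Reduce(`+`, lapply(seq_len(L), function(a) Z[[a]] %*% (V %*% t(W[[a]]))))
    U <- U * num / pmax(den, eps)
    U[den <= eps] <- 0
    Ms <- M()

    ratio <- lapply(seq_len(L), function(a) ZA[[a]] / pmax(Ms[[a]], eps))
    # V update
    num <- Reduce(`+`, lapply(seq_len(L), function(a) t(ratio[[a]]) %*% (U %*% W[[a]])))
    den <- Reduce(`+`, lapply(seq_len(L), function(a) t(Z[[a]]) %*% (U %*% W[[a]])))
    V <- V * num / pmax(den, eps)
    V[den <= eps] <- 0
    Ms <- M()

    ratio <- lapply(seq_len(L), function(a) ZA[[a]] / pmax(Ms[[a]], eps))
    # W update (per layer)
    for (a in seq_len(L)) {
      num <- t(U) %*% ratio[[a]] %*% V
      den <- t(U) %*% Z[[a]] %*% V
      W[[a]] <- W[[a]] * num / pmax(den, eps)
      W[[a]][den <= eps] <- 0
    }
    Ms <- M()

    ll <- loglik(Ms)
    trace <- c(trace, ll)
    if (it %% check_every == 0) {
      if (abs(ll - ll_prev) < tolerance) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
  }
  list(
    u = U, v = V, w = W,
    log_likelihood = trace[length(trace)], trace = trace, converged = converged
  )
}

#' Expected-edge tensor of a fitted model
#'
#' Evaluates the bilinear form `M_ij = sum_kl u_ik v_jl w_kl` per layer.
#'
#' @param model a `multitensor_fit`.
#' @return named list of chaperone x client matrices, one per layer.
#' @export
expected_edges <- function(model) {
  stopifnot(inherits(model, "multitensor_fit"))
  out <- lapply(model$w, function(wa) {
    M <- model$u %*% wa %*% t(model$v)
    dimnames(M) <- list(model$chaperones, model$clients)
    M
  })
  names(out) <- model$layers
  out
}

#' BIC model selection over a range of group counts
#'
#' Fits every K in `K_min:K_max` and returns the model with the lowest BIC,
#' `BIC = -2 logL + p log(n)` with `p = K (#chaperones + #clients) + K^2 L`
#' free parameters and `n` the number of observed adjacency cells.
#'
#' @inheritParams fit_multitensor
#' @param K_min,K_max inclusive range of group counts (full-scale default
#'   2..15).
#' @param ... further arguments to [fit_multitensor()].
#' @return list with `best_model` (a `multitensor_fit`) and `bic_trace`
#'   (tibble: `K`, `log_likelihood`, `BIC`, `converged`).
#' @export
select_K <- function(net, K_min = 2, K_max = 15, ...) {
  stopifnot(K_min <= K_max, K_min >= 1)
  fits <- lapply(K_min:K_max, function(k) fit_multitensor(net, K = k, ...))
  bic <- vapply(fits, `[[`, numeric(1), "BIC")
  list(
    best_model = fits[[which.min(bic)]],
    bic_trace = tibble::tibble(
      K = K_min:K_max,
      log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
      BIC = bic,
      converged = vapply(fits, `[[`, logical(1), "converged")
    )
  )
}

#' Hard group assignments from mixed memberships
#'
#' Assigns every node to the group with the highest normalized membership;
#' ties break to the lowest group index. All-zero membership rows are
#' unassigned (`NA`) with a warning.
#'
#' @param model a `multitensor_fit`.
#' @return tibble with columns `node`, `type` ("chaperone"/"client"),
#'   `group`.
#' @export
hard_assignments <- function(model) {
  stopifnot(inherits(model, "multitensor_fit"))
  pick <- function(mat) {
    tot <- rowSums(mat)
    g <- max.col(mat, ties.method = "first")
    g[tot == 0] <- NA_integer_
    g
  }
  gu <- pick(model$u)
  gv <- pick(model$v)
  if (anyNA(c(gu, gv))) {
    warning(sum(is.na(c(gu, gv))), " node(s) with all-zero membership left unassigned", call. = FALSE)
  }
  tibble::tibble(
    node = c(model$chaperones, model$clients),
    type = rep(c("chaperone", "client"), c(length(model$chaperones), length(model$clients))),
    group = c(gu, gv)
  )
}

#' Pairwise co-assignment agreement between two partitions
#'
#' Label-permutation-invariant recovery score: the fraction of node pairs on
#' which two partitions agree about being co-grouped or not (the Rand index).
#'
#' @param labels_a,labels_b equal-length label vectors (any label alphabet).
#' @return agreement in \[0, 1\].
#' @export
coassignment_agreement <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) >= 2)
  pairs <- utils::combn(length(labels_a), 2)
  same_a <- labels_a[pairs[1, ]] == labels_a[pairs[2, ]]
  same_b <- labels_b[pairs[1, ]] == labels_b[pairs[2, ]]
  mean(same_a == same_b)
}

#' @export
print.multitensor_fit <- function(x, ...) {
  cat(
    "<multitensor_fit> K = ", x$K, ", ", length(x$chaperones), " x ",
    length(x$clients), " x ", length(x$layers),
    ", logL = ", format(x$log_likelihood, digits = 8),
    ", BIC = ", format(x$BIC, digits = 8),
    if (!x$converged) " (not converged)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy multitensor_fit
#' @export
tidy.multitensor_fit <- function(x, ...) {
  norm_rows <- function(mat) {
    tot <- rowSums(mat)
    sweep(mat, 1, ifelse(tot > 0, tot, 1), "/")
  }
  long <- function(mat, type) {
    tibble::tibble(
      node = rep(rownames(mat), times = ncol(mat)),
      type = type,
      group = rep(seq_len(ncol(mat)), each = nrow(mat)),
      membership = as.vector(norm_rows(mat))
    )
  }
  dplyr::bind_rows(long(x$u, "chaperone"), long(x$v, "client"))
}

#' @method glance multitensor_fit
#' @export
glance.multitensor_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    log_likelihood = x$log_likelihood,
    BIC = x$BIC,
    n_parameters = x$n_parameters,
    n_observed_cells = x$n_observed_cells,
    converged = x$converged,
    n_restarts = x$n_restarts,
    n_iterations = length(x$trace)
  )
}
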