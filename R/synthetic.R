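#' Generate a multilayer bipartite network with planted block structure
#'
#' Draws a multilayer binary bipartite network from the mixed-membership
#' block model the analysis assumes: each chaperone i has a membership vector
#' u_i over K groups, each client j a vector v_j, and each layer a a K x K
#' non-negative affinity matrix w. The expected number of edges from i to j in
#' layer a is the bilinear form `M_ij = sum_kl u_ik v_jl w_kl`, and each edge
#' is drawn Bernoulli(min(1, M_ij)) independently (rates above 1 are clipped
#' and counted).
#'
#' Memberships are drawn from a symmetric Dirichlet with the given
#' concentration; `membership_concentration = 0` is the hard-membership
#' limit (each node assigned one group uniformly at random). Affinities put
#' `within_rate` on the diagonal and `within_rate / affinity_contrast` off it
#' (`affinity_contrast = Inf` gives zero between-group rate). With
#' `share_affinities = TRUE` all layers share one affinity matrix (high
#' cross-layer fidelity); otherwise each layer rescales groups independently,
#' eroding fidelity.
#'
#' @param n_chaperones,n_clients,n_layers network dimensions (>= 1).
#' @param K number of planted groups (>= 1).
#' @param affinity_contrast ratio of within- to between-group rate (>= 1).
#' @param membership_concentration Dirichlet concentration (>= 0; 0 = hard).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param within_rate expected within-group edge rate (default 0.3, giving
#'   realistic layer densities once memberships mix).
#' @param share_affinities share one affinity matrix across layers (default
#'   TRUE).
#' @return list with `network` (a [cci_network()]) and `truth` (class
#'   `planted_truth`: `u`, `v`, `w` (list of K x K matrices per layer),
#'   `group_chaperone`, `group_client` (argmax labels), `n_clipped`).
#' @export
generate_sbm_multilayer <- function(n_chaperones, n_clients, n_layers, K,
                                    affinity_contrast = 10,
                                    membership_concentration = 0.1,
                                    seed = 1L,
                                    within_rate = 0.3,
                                    share_affinities = TRUE) {
  stopifnot(
    n_chaperones >= 1, n_clients >= 1, n_layers >= 1, K >= 1,
    affinity_contrast >= 1, membership_concentration >= 0, within_rate > 0
  )
  set.seed(seed)
  chap_ids <- sprintf("chap%02d", seq_len(n_chaperones))
  client_ids <- sprintf("client%04d", seq_len(n_clients))
  layer_ids <- sprintf("env%02d", seq_len(n_layers))

  u <- rdirichlet_rows(n_chaperones, K, membership_concentration)
  v <- rdirichlet_rows(n_clients, K, membership_concentration)
  rownames(u) <- chap_ids
  rownames(v) <- client_ids

  between <- if (is.infinite(affinity_contrast)) 0 else within_rate / affinity_contrast
  w_base <- matrix(between, K, K)
  diag(w_base) <- within_rate
  w <- lapply(seq_len(n_layers), function(a) {
    if (share_affinities) w_base else w_base * stats::runif(1, 0.5, 1.5)
  })
  names(w) <- layer_ids

  n_clipped <- 0L
  mats <- lapply(seq_len(n_layers), function(a) {
    M <- u %*% w[[a]] %*% t(v)
    n_clipped <<- n_clipped + sum(M > 1)
    Mc <- pmin(M, 1)
    A <- matrix(
      stats::rbinom(length(Mc), 1L, as.vector(Mc)),
      n_chaperones, n_clients,
      dimnames = list(chap_ids, client_ids)
    )
    A
  })
  names(mats) <- layer_ids
  if (n_clipped > 0) {
    message("generate_sbm_multilayer: clipped ", n_clipped, " expected rates above 1")
  }

  truth <- structure(
    list(
      u = u, v = v, w = w,
      group_chaperone = stats::setNames(max.col(u, ties.method = "first"), chap_ids),
      group_client = stats::setNames(max.col(v, ties.method = "first"), client_ids),
      n_clipped = n_clipped
    ),
    class = "planted_truth"
  )
  list(network = as_cci_network(mats), truth = truth)
}

# rows of a symmetric Dirichlet(alpha) sample; alpha = 0 -> one-hot rows
rdirichlet_rows <- function(n, K, alpha) {
  if (K == 1) return(matrix(1, n, 1))
  if (alpha == 0) {
    g <- sample.int(K, n, replace = TRUE)
    m <- matrix(0, n, K)
    m[cbind(seq_len(n), g)] <- 1
    return(m)
  }
  g <- matrix(stats::rgamma(n * K, shape = alpha), n, K)
  # guard against all-zero rows at tiny alpha
  zero <- rowSums(g) == 0
  if (any(zero)) g[cbind(which(zero), sample.int(K, sum(zero), replace = TRUE))] <- 1
  g / rowSums(g)
}

#' Generate expression matrices encoding a planted network
#'
#' Emulates the statistical structure the coexpression stage assumes: in each
#' layer, every chaperone carries a latent standard-normal signal across
#' samples; a client linked to it in the planted network is that signal plus
#' Gaussian noise calibrated so that the expected Spearman correlation of
#' linked pairs is approximately `signal_rho` (via the bivariate-normal
#' rank-correlation relation `r = 2 sin(pi * rho_s / 6)`); unlinked pairs are
#' independent. A client linked to several chaperones uses the sum of their
#' latent signals (scaled to unit variance) — documented behaviour, not an
#' error. All values are shifted to be >= 0 (a monotone transform, so rank
#' correlations are untouched).
#'
#' @param planted_network a [cci_network()] whose edges the expression should
#'   encode.
#' @param n_samples_per_layer samples per layer (>= 10).
#' @param signal_rho target Spearman correlation of linked pairs, in (0, 1).
#' @param noise_sd additional independent measurement noise added to every
#'   gene (default 0; the link noise is set by `signal_rho`).
#' @param seed integer seed.
#' @return named list of [expression_matrix()] objects, one per layer, rows =
#'   chaperones then clients.
#' @export
generate_expression <- function(planted_network, n_samples_per_layer = 300,
                                signal_rho = 0.8, noise_sd = 0, seed = 1L) {
  stopifnot(signal_rho > 0, signal_rho < 1, n_samples_per_layer >= 10)
  net <- as_cci_network(planted_network)
  mats <- layer_matrices(net)
  set.seed(seed)

  r <- 2 * sin(pi * signal_rho / 6) # Pearson corr of the latent Gaussians
  sigma <- sqrt(1 / r^2 - 1)
  n <- n_samples_per_layer

  out <- lapply(names(mats), function(a) {
    A <- mats[[a]]
    z <- matrix(stats::rnorm(nrow(A) * n), nrow(A), n) # latent chaperone signals
    chap_expr <- z
    client_expr <- matrix(stats::rnorm(ncol(A) * n), ncol(A), n)
    linked <- which(rowSums(t(A)) > 0) # clients with >= 1 chaperone
    for (j in linked) {
      members <- which(A[, j] != 0)
      s <- colSums(z[members, , drop = FALSE]) / sqrt(length(members))
      client_expr[j, ] <- s + sigma * stats::rnorm(n)
    }
    values <- rbind(chap_expr, client_expr)
    if (noise_sd > 0) values <- values + noise_sd * stats::rnorm(length(values))
    values <- values - min(values) # shift to >= 0, rank-preserving
    rownames(values) <- c(net$chaperones, net$clients)
    colnames(values) <- sprintf("%s_s%03d", a, seq_len(n))
    expression_matrix(values, a)
  })
  names(out) <- names(mats)
  out
}

#' Perfectly nested weighted matrix
#'
#' Builds a staircase pattern in which the column support of every row is a
#' superset of the next row's support (and analogously across columns): row i
#' occupies columns 1..k_i with k_i = max(1, round(fill * n_cols * i /
#' n_rows)). With `fill = 1` and a square matrix this is the lower-triangular
#' ones pattern. Such a matrix is maximally nested: its column sums are the
#' conjugate of its row sums, so it is the unique member of its fixed-margin
#' class.
#'
#' @param n_rows,n_cols dimensions.
#' @param fill fraction of each row's maximal staircase width, in (0, 1].
#' @return binary (0/1-weight) matrix.
#' @export
generate_nested_matrix <- function(n_rows, n_cols, fill = 1) {
  stopifnot(fill > 0, fill <= 1, n_rows >= 1, n_cols >= 1)
  k <- pmax(1, round(fill * n_cols * seq_len(n_rows) / n_rows))
  m <- matrix(0, n_rows, n_cols)
  for (i in seq_len(n_rows)) m[i, seq_len(k[i])] <- 1
  m
}

#' Multilayer network with a planted nested realized-niche pattern
#'
#' Constructs a network whose chaperone x layer realized-niche matrix R is
#' (approximately) a nested staircase. Each chaperone gets a private random
#' preference order over clients; in layer a it links to the first L_ca
#' clients of that order, where the targets L_ca decrease across both
#' chaperones and layers following [generate_nested_matrix()]'s staircase.
#' Because each layer's client sets are nested prefixes of the same order,
#' P_c = max_a L_ca and R follows the planted gradient, while the individual
#' layers remain randomizable by curveball (supports differ across
#' chaperones).
#'
#' @param n_chaperones,n_clients,n_layers dimensions.
#' @param fill scales the largest per-layer link count as a fraction of
#'   `n_clients` (default 0.5).
#' @param seed integer seed (controls the preference orders).
#' @return a [cci_network()].
#' @export
generate_nested_network <- function(n_chaperones, n_clients, n_layers,
                                    fill = 0.5, seed = 1L) {
  stopifnot(fill > 0, fill <= 1)
  set.seed(seed)
  chap_ids <- sprintf("chap%02d", seq_len(n_chaperones))
  client_ids <- sprintf("client%04d", seq_len(n_clients))
  layer_ids <- sprintf("env%02d", seq_len(n_layers))

  # staircase of per-layer link counts: decreasing in chaperone and layer rank
  base <- pmax(2, round(fill * n_clients * rev(seq_len(n_chaperones)) / n_chaperones))
  layer_scale <- rev(seq_len(n_layers)) / n_layers # 1 .. 1/L
  prefs <- lapply(chap_ids, function(i) sample.int(n_clients))

  mats <- lapply(seq_len(n_layers), function(a) {
    A <- matrix(0L, n_chaperones, n_clients, dimnames = list(chap_ids, client_ids))
    for (c in seq_len(n_chaperones)) {
      L_ca <- max(1, round(base[c] * layer_scale[a]))
      A[c, prefs[[c]][seq_len(L_ca)]] <- 1L
    }
    A
  })
  names(mats) <- layer_ids
  as_cci_network(mats)
}
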