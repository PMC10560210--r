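#' Per-chaperone niche table
#'
#' For every chaperone c and layer a: the link count `n_links` (L_ca), the
#' layer-specific specialization `layer_specialization` (S_ca = L_ca divided
#' by the total number of clients), the pooled client count `n_clients_total`
#' (P_c, the size of the union of c's client sets across layers), the overall
#' specialization `specialization` (S_c = P_c / total clients), and the
#' realized niche `realized_niche` (R_ca = L_ca / P_c). The total-client
#' denominator is the network's client-set size, not a constant. Chaperones
#' with P_c = 0 get `realized_niche = NA` and are flagged.
#'
#' @param net a [cci_network()] or anything [as_cci_network()] accepts.
#' @return tibble, one row per chaperone x layer, with an additional logical
#'   column `no_clients` flagging chaperones with no links anywhere.
#' @export
niche_table <- function(net) {
  net <- as_cci_network(net)
  mats <- layer_matrices(net)
  n_client_total <- length(net$clients)
  L <- vapply(mats, rowSums, numeric(length(net$chaperones)))
  union_support <- Reduce(`|`, lapply(mats, function(m) m != 0))
  P <- rowSums(union_support)

  tibble::tibble(
    chaperone = rep(net$chaperones, times = length(net$layers)),
    layer = rep(net$layers, each = length(net$chaperones)),
    n_links = as.vector(L),
    layer_specialization = as.vector(L) / n_client_total,
    n_clients_total = rep(unname(P), times = length(net$layers)),
    specialization = rep(unname(P) / n_client_total, times = length(net$layers)),
    realized_niche = ifelse(rep(unname(P), times = length(net$layers)) > 0,
      as.vector(L) / rep(unname(pmax(P, 1)), times = length(net$layers)), NA_real_
    ),
    no_clients = rep(unname(P) == 0, times = length(net$layers))
  )
}

# client sets of each chaperone per layer, as a list of lists of integer indices
client_sets <- function(mats) {
  lapply(mats, function(m) apply(m != 0, 1, which, simplify = FALSE))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_) # two empty sets: undefined, excluded downstream
  length(intersect(a, b)) / u
}

#' Partner fidelity: cross-layer similarity of a chaperone's clients
#'
#' For every chaperone c and unordered layer pair (a, b), the Jaccard
#' similarity of c's client sets in the two layers. Pairs where both sets are
#' empty are undefined (`NA`) and excluded from the fidelity median.
#'
#' @param net a [cci_network()] or anything [as_cci_network()] accepts.
#' @return tibble with columns `chaperone`, `layer_a`, `layer_b`, `jaccard`
#'   (one row per chaperone x unordered layer pair).
#' @seealso [partner_fidelity_scores()] for the per-chaperone median J_c.
#' @export
partner_fidelity <- function(net) {
  net <- as_cci_network(net)
  if (length(net$layers) < 2) stop("need at least 2 layers", call. = FALSE)
  sets <- client_sets(layer_matrices(net))
  pairs <- utils::combn(net$layers, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]
    b <- pairs[2, p]
    tibble::tibble(
      chaperone = net$chaperones,
      layer_a = a, layer_b = b,
      jaccard = vapply(
        net$chaperones,
        function(c) jaccard(sets[[a]][[c]], sets[[b]][[c]]), numeric(1),
        USE.NAMES = FALSE
      )
    )
  })
}

#' @rdname partner_fidelity
#' @return `partner_fidelity_scores()`: tibble with `chaperone`, `fidelity`
#'   (the median of defined pairwise Jaccard values), `n_pairs`.
#' @export
partner_fidelity_scores <- function(net) {
  partner_fidelity(net) |>
    dplyr::group_by(.data$chaperone) |>
    dplyr::summarise(
      fidelity = stats::median(.data$jaccard, na.rm = TRUE),
      n_pairs = sum(!is.na(.data$jaccard)),
      .groups = "drop"
    )
}

#' Within-layer niche overlap between chaperone pairs
#'
#' Jaccard similarity of the client sets of every unordered pair of distinct
#' chaperones, within each layer. Low values indicate niche separation, high
#' values redundancy.
#'
#' @inheritParams partner_fidelity
#' @return tibble with columns `layer`, `chaperone_x`, `chaperone_y`,
#'   `jaccard`.
#' @export
within_layer_overlap <- function(net) {
  net <- as_cci_network(net)
  if (length(net$chaperones) < 2) stop("need at least 2 chaperones", call. = FALSE)
  sets <- client_sets(layer_matrices(net))
  pairs <- utils::combn(net$chaperones, 2)
  purrr::map_dfr(net$layers, function(a) {
    tibble::tibble(
      layer = a,
      chaperone_x = pairs[1, ],
      chaperone_y = pairs[2, ],
      jaccard = vapply(
        seq_len(ncol(pairs)),
        function(p) jaccard(sets[[a]][[pairs[1, p]]], sets[[a]][[pairs[2, p]]]),
        numeric(1)
      )
    )
  })
}

#' Jaccard similarity of edge sets between layers
#'
#' Layers are compared as sets of (chaperone, client) pairs; the diagonal is
#' 1 by definition.
#'
#' @inheritParams partner_fidelity
#' @return tibble with columns `layer_a`, `layer_b`, `jaccard`, covering all
#'   ordered pairs including the diagonal (symmetric).
#' @export
layer_similarity <- function(net) {
  net <- as_cci_network(net)
  if (length(net$layers) < 2) stop("need at least 2 layers", call. = FALSE)
  edge_keys <- lapply(net$layers, function(a) {
    e <- net$edges[net$edges$layer == a, , drop = FALSE]
    paste(e$chaperone, e$client, sep = "\r")
  })
  names(edge_keys) <- net$layers
  grid <- expand.grid(
    layer_a = net$layers, layer_b = net$layers,
    stringsAsFactors = FALSE
  )
  grid$jaccard <- vapply(seq_len(nrow(grid)), function(i) {
    if (grid$layer_a[i] == grid$layer_b[i]) return(1)
    jaccard(edge_keys[[grid$layer_a[i]]], edge_keys[[grid$layer_b[i]]])
  }, numeric(1))
  tibble::as_tibble(grid)
}

#' Spearman correlation with Bonferroni correction
#'
#' Two-sided Spearman rank correlation (t approximation) between two equal
#' length vectors, with the corrected p-value `min(1, p * n_tests)`.
#'
#' @param x_values,y_values finite numeric vectors of equal length >= 3.
#' @param n_tests Bonferroni family size (default 1 = no correction).
#' @return one-row tibble with `rho`, `p_value`, `p_bonferroni`, `n`. A
#'   constant input vector gives `rho = NA` with a warning.
#' @export
spearman_with_bonferroni <- function(x_values, y_values, n_tests = 1) {
  stopifnot(length(x_values) == length(y_values), length(x_values) >= 3, n_tests >= 1)
  if (any(!is.finite(x_values)) || any(!is.finite(y_values))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(x_values) == 0 || stats::sd(y_values) == 0) {
    warning("constant input vector: correlation undefined", call. = FALSE)
    return(tibble::tibble(
      rho = NA_real_, p_value = NA_real_, p_bonferroni = NA_real_,
      n = length(x_values)
    ))
  }
  ct <- suppressWarnings(
    stats::cor.test(x_values, y_values, method = "spearman", exact = FALSE)
  )
  tibble::tibble(
    rho = unname(ct$estimate),
    p_value = ct$p.value,
    p_bonferroni = min(1, ct$p.value * n_tests),
    n = length(x_values)
  )
}

#' Fidelity-niche correlation across chaperones
#'
#' Correlates each chaperone's partner fidelity (median cross-layer Jaccard)
#' with its median realized niche across layers — the relationship linking
#' how faithfully a chaperone keeps its clients across environments to how
#' much of its potential niche it realizes.
#'
#' @inheritParams partner_fidelity
#' @param n_tests Bonferroni family size for the single correlation
#'   (default 1).
#' @return one-row tibble as [spearman_with_bonferroni()], plus `n_chaperones`.
#' @export
fidelity_niche_correlation <- function(net, n_tests = 1) {
  net <- as_cci_network(net)
  fid <- partner_fidelity_scores(net)
  med_r <- niche_table(net) |>
    dplyr::group_by(.data$chaperone) |>
    dplyr::summarise(median_realized_niche = stats::median(.data$realized_niche), .groups = "drop")
  joined <- dplyr::inner_join(fid, med_r, by = "chaperone") |>
    dplyr::filter(is.finite(.data$fidelity), is.finite(.data$median_realized_niche))
  out <- spearman_with_bonferroni(joined$fidelity, joined$median_realized_niche, n_tests)
  out$n_chaperones <- nrow(joined)
  out
}

#' Realized-niche heatmap
#'
#' @param net a [cci_network()].
#' @return a ggplot: chaperone x layer tiles coloured by realized niche, rows
#'   and columns arranged by marginal sums.
#' @export
plot_realized_niche <- function(net) {
  R <- realized_niche_matrix(as_cci_network(net))
  df <- tibble::as_tibble(as.data.frame.table(R, stringsAsFactors = FALSE))
  names(df) <- c("chaperone", "layer", "realized_niche")
  df$chaperone <- factor(df$chaperone, levels = rownames(R)[order(rowSums(R))])
  df$layer <- factor(df$layer, levels = colnames(R)[order(colSums(R))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$chaperone, fill = .data$realized_niche)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "environment", y = "chaperone", fill = "realized\nniche")
}
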