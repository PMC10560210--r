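#' Chaperone removal order for a robustness scenario
#'
#' Four orderings over one layer's chaperones: `"degree"` removes from the
#' most to the least connected (static initial degrees, ties broken by
#' identifier); `"module_first_A"` removes most-to-least connected within
#' module 1, then within module 2 (and so on for further modules);
#' `"module_first_B"` does the same with the module order reversed;
#' `"random"` is a uniform permutation.
#'
#' @param layer binary incidence matrix (chaperones x clients) with row
#'   names, e.g. one element of [layer_matrices()].
#' @param scenario one of `"degree"`, `"module_first_A"`, `"module_first_B"`,
#'   `"random"`.
#' @param group_labels named integer vector mapping each chaperone to its
#'   module number (required for the modular scenarios); see
#'   [module_numbers()].
#' @param seed seed for the random scenario.
#' @param dynamic recompute degrees after each removal instead of using the
#'   initial degrees (default FALSE, the reproducible static rule).
#' @return character vector: the chaperone removal sequence.
#' @export
removal_order <- function(layer, scenario = c("degree", "module_first_A", "module_first_B", "random"),
                          group_labels = NULL, seed = NULL, dynamic = FALSE) {
  scenario <- match.arg(scenario)
  chaps <- rownames(layer)
  stopifnot(!is.null(chaps))
  degrees <- rowSums(layer)

  by_degree <- function(ids, m) {
    if (!dynamic) {
      ids[order(-degrees[ids], ids, method = "radix")]
    } else {
      out <- character(0)
      remaining <- ids
      mm <- m
      while (length(remaining)) {
        d <- rowSums(mm[remaining, , drop = FALSE])
        nxt <- remaining[order(-d, remaining, method = "radix")][1]
        out <- c(out, nxt)
        # a removed chaperone's clients may co-extinct; drop their columns
        mm[nxt, ] <- 0
        mm[, colSums(mm) == 0] <- 0
        remaining <- setdiff(remaining, nxt)
      }
      out
    }
  }

  switch(scenario,
    degree = by_degree(chaps, layer),
    random = {
      if (!is.null(seed)) set.seed(seed)
      sample(chaps)
    },
    module_first_A = ,
    module_first_B = {
      if (is.null(group_labels)) {
        stop("modular scenarios require group_labels", call. = FALSE)
      }
      g <- group_labels[chaps]
      if (anyNA(g)) stop("group_labels missing for some chaperones", call. = FALSE)
      mods <- sort(unique(g))
      if (scenario == "module_first_B") mods <- rev(mods)
      unlist(lapply(mods, function(mod) by_degree(chaps[g == mod], layer)), use.names = FALSE)
    }
  )
}

#' Module numbering from SBM hard assignments
#'
#' Maps hard group labels to module numbers 1, 2, ... ordered by descending
#' group size (ties by lowest member identifier), the convention used by the
#' modular removal scenarios.
#'
#' @param assignments tibble from [hard_assignments()] (chaperone rows are
#'   used), or a named vector of group labels.
#' @return named integer vector: chaperone -> module number.
#' @export
module_numbers <- function(assignments) {
  if (is.data.frame(assignments)) {
    a <- assignments[assignments$type == "chaperone", , drop = FALSE]
    labels <- stats::setNames(a$group, a$node)
  } else {
    labels <- assignments
  }
  groups <- split(names(labels), labels)
  ord <- order(-lengths(groups), vapply(groups, function(g) sort_ids(g)[1], character(1)),
    method = "radix"
  )
  renum <- stats::setNames(seq_along(groups), names(groups)[ord])
  stats::setNames(as.integer(renum[as.character(labels)]), names(labels))
}

#' Simulate sequential chaperone removal with client co-extinction
#'
#' Chaperones are removed in the given order; a client is co-extinct once it
#' has no remaining connected chaperone. The curve records the fraction of
#' initially-connected clients still connected after k of N removals, sampled
#' at x = k/N for k = 0..N.
#'
#' @param layer binary incidence matrix with dimnames.
#' @param order permutation of the layer's chaperones (from
#'   [removal_order()]).
#' @param scenario optional label stored with the curve.
#' @return object of class `extinction_curve`: tibble with columns `step`,
#'   `x` (fraction removed), `y` (surviving client fraction), and attributes
#'   `scenario`, `removal_order`.
#' @export
simulate_extinctions <- function(layer, order, scenario = NA_character_) {
  stopifnot(setequal(order, rownames(layer)), !anyDuplicated(order))
  if (sum(layer) == 0) stop("layer has no links: nothing to collapse", call. = FALSE)
  initial <- colSums(layer) > 0
  n0 <- sum(initial)
  N <- nrow(layer)
  y <- numeric(N + 1)
  y[1] <- 1
  support <- colSums(layer) # remaining chaperone count per client
  for (k in seq_len(N)) {
    support <- support - layer[order[k], ]
    y[k + 1] <- sum(support > 0 & initial) / n0
  }
  structure(
    tibble::tibble(step = 0:N, x = (0:N) / N, y = y),
    scenario = scenario, removal_order = order,
    class = c("extinction_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Robustness score T: area under the extinction curve
#'
#' Trapezoidal integration of the surviving-client fraction over the k/N
#' removal grid, both endpoints included. T is 1 for a network that keeps
#' every client until the final removal and approaches 0 for one that
#' collapses immediately.
#'
#' @param curve an [simulate_extinctions()] result (or any data frame with
#'   `x`, `y`).
#' @return T in \[0, 1\].
#' @export
robustness_T <- function(curve) {
  x <- curve$x
  y <- curve$y
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Robustness scores for every layer and removal scenario
#'
#' Runs the deterministic scenarios once per layer and the random scenario
#' `n_random_reps` times (mean and SD reported).
#'
#' @param net a [cci_network()] or anything [as_cci_network()] accepts.
#' @param group_labels named chaperone -> module vector (see
#'   [module_numbers()]); when NULL the modular scenarios are skipped.
#' @param n_random_reps random-removal replicates (default 100).
#' @param seed master seed for the random scenario.
#' @return tibble with columns `layer`, `scenario`, `T`, `T_sd` (NA for the
#'   deterministic scenarios), `n_reps`.
#' @export
robustness_suite <- function(net, group_labels = NULL, n_random_reps = 100, seed = 1L) {
  stopifnot(n_random_reps >= 1)
  mats <- layer_matrices(as_cci_network(net))
  scenarios <- c(
    "degree",
    if (!is.null(group_labels)) c("module_first_A", "module_first_B"),
    "random"
  )
  purrr::map_dfr(names(mats), function(a) {
    m <- mats[[a]]
    purrr::map_dfr(scenarios, function(sc) {
      if (sc == "random") {
        Ts <- vapply(seq_len(n_random_reps), function(r) {
          ord <- removal_order(m, "random", seed = seed + 1009L * match(a, names(mats)) + r)
          robustness_T(simulate_extinctions(m, ord, sc))
        }, numeric(1))
        tibble::tibble(
          layer = a, scenario = sc, T = mean(Ts),
          T_sd = stats::sd(Ts), n_reps = n_random_reps
        )
      } else {
        ord <- removal_order(m, sc, group_labels = group_labels)
        tibble::tibble(
          layer = a, scenario = sc,
          T = robustness_T(simulate_extinctions(m, ord, sc)),
          T_sd = NA_real_, n_reps = 1L
        )
      }
    })
  })
}

#' Correlate robustness with mean realized niche across layers
#'
#' For each removal scenario, the two-tailed Spearman correlation across
#' layers between the robustness score T and the layer's mean realized niche.
#'
#' @param T_table output of [robustness_suite()].
#' @param niche output of [niche_table()] for the same network.
#' @return tibble with one row per scenario: `scenario`, `rho`, `p_value`,
#'   `n_layers`. Constant inputs give `NA` with a warning.
#' @export
correlate_T_with_niche <- function(T_table, niche) {
  mean_r <- niche |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(mean_realized_niche = mean(.data$realized_niche, na.rm = TRUE), .groups = "drop")
  if (nrow(mean_r) < 3) stop("need at least 3 layers", call. = FALSE)
  T_table |>
    dplyr::inner_join(mean_r, by = "layer") |>
    dplyr::group_by(.data$scenario) |>
    dplyr::group_modify(function(df, key) {
      if (stats::sd(df$T) == 0 || stats::sd(df$mean_realized_niche) == 0) {
        warning("constant values for scenario '", key$scenario, "': correlation undefined",
          call. = FALSE
        )
        return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n_layers = nrow(df)))
      }
      res <- spearman_with_bonferroni(df$mean_realized_niche, df$T)
      tibble::tibble(rho = res$rho, p_value = res$p_value, n_layers = nrow(df))
    }) |>
    dplyr::ungroup()
}

#' Extinction-curve plot
#'
#' @param curves one `extinction_curve` or a named list of them (names used
#'   as scenario labels when the curves carry none).
#' @return a ggplot of surviving-client fraction against fraction removed.
#' @export
plot_extinction_curves <- function(curves) {
  if (inherits(curves, "extinction_curve")) curves <- list(curves)
  df <- purrr::imap_dfr(curves, function(cv, nm) {
    lab <- attr(cv, "scenario")
    if (is.null(lab) || is.na(lab)) lab <- as.character(nm)
    tibble::tibble(x = cv$x, y = cv$y, scenario = lab)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$scenario)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::labs(
      x = "fraction of chaperones removed",
      y = "fraction of clients surviving", colour = "scenario"
    )
}
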