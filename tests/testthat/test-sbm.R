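test_that("expected edges evaluate the bilinear form exactly", {
  res <- planted_net(n_chap = 3, n_client = 4, n_layers = 2, seed = 1)
  fit <- suppressWarnings(fit_multitensor(res$network, K = 2, n_restarts = 1, max_iter = 5))

  # scalar reduction: K = 1, u = v = 1, w = 0.3
  fit1 <- fit
  fit1$u <- matrix(1, 3, 1, dimnames = list(fit$chaperones, NULL))
  fit1$v <- matrix(1, 4, 1, dimnames = list(fit$clients, NULL))
  fit1$w <- stats::setNames(list(matrix(0.3), matrix(0.3)), fit$layers)
  M <- expected_edges(fit1)
  expect_true(all(vapply(M, function(m) all(m == 0.3), logical(1))))

  # a zero membership row silences that chaperone in every layer
  fit0 <- fit
  fit0$u[1, ] <- 0
  M0 <- expected_edges(fit0)
  expect_true(all(vapply(M0, function(m) all(m[1, ] == 0), logical(1))))

  # hand expansion: u = (1,0), v = (0,1) picks w[1,2]
  fit2 <- fit
  fit2$u <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2, dimnames = list(fit$chaperones, NULL))
  fit2$v <- matrix(c(0, 1, 0, 0, 1, 0, 1, 1), 4, 2, dimnames = list(fit$clients, NULL))
  w <- matrix(c(0.1, 0.3, 0.7, 0.2), 2, 2) # w[1,2] = 0.7
  fit2$w <- stats::setNames(list(w, w), fit$layers)
  M2 <- expected_edges(fit2)
  expect_equal(M2[[1]][1, 1], 0.7)
})

test_that("EM log-likelihood is non-decreasing on random instances", {
  for (s in 1:20) {
    res <- generate_sbm_multilayer(
      6, 30, 2,
      K = 2, affinity_contrast = 3,
      membership_concentration = 0.5, seed = s, within_rate = 0.4
    )
    fit <- suppressWarnings(fit_multitensor(
      res$network,
      K = 2, n_restarts = 1, max_iter = 60, seed = s
    ))
    expect_true(all(diff(fit$trace) >= -1e-8))
  }
})

test_that("with K = 1 the fitted expected edges approximate the layer densities", {
  res <- generate_sbm_multilayer(
    10, 200, 3,
    K = 1, affinity_contrast = 1,
    membership_concentration = 1, seed = 3, within_rate = 0.25
  )
  fit <- fit_multitensor(res$network, K = 1, n_restarts = 2, seed = 3)
  M <- expected_edges(fit)
  mats <- layer_matrices(res$network)
  for (a in names(mats)) {
    expect_equal(mean(M[[a]]), mean(mats[[a]]), tolerance = 0.05)
  }
})

test_that("a planted two-group network is recovered with high co-assignment agreement", {
  res <- planted_net(n_chap = 15, n_client = 200, n_layers = 4, K = 2, contrast = 10, seed = 19)
  fit <- fit_multitensor(res$network, K = 2, n_restarts = 5, seed = 19)
  hard <- hard_assignments(fit)
  est <- hard$group[match(res$network$chaperones, hard$node)]
  truth <- res$truth$group_chaperone[res$network$chaperones]
  expect_gte(coassignment_agreement(est, truth), 0.9)
})

test_that("duplicating a layer leaves hard assignments unchanged", {
  res <- planted_net(n_chap = 10, n_client = 100, n_layers = 2, seed = 23)
  mats <- layer_matrices(res$network)
  dup <- as_cci_network(c(mats, stats::setNames(mats[1], "env01_copy")))
  f1 <- fit_multitensor(res$network, K = 2, n_restarts = 4, seed = 23)
  f2 <- fit_multitensor(dup, K = 2, n_restarts = 4, seed = 23)
  g1 <- suppressWarnings(hard_assignments(f1))
  g2 <- suppressWarnings(hard_assignments(f2))
  both <- intersect(g1$node[g1$type == "chaperone"], g2$node)
  expect_gte(
    coassignment_agreement(
      g1$group[match(both, g1$node)],
      g2$group[match(both, g2$node)]
    ),
    0.9
  )
})

test_that("BIC follows its formula and select_K returns the full trace", {
  # BIC arithmetic on a stub fit: logL = -100, p = 10, n = e
  expect_equal(-2 * (-100) + 10 * log(exp(1)), 210)
  res <- planted_net(n_chap = 10, n_client = 120, n_layers = 3, K = 2, seed = 29)
  sel <- suppressWarnings(
    select_K(res$network, K_min = 1, K_max = 3, n_restarts = 2, seed = 29, max_iter = 200)
  )
  expect_equal(nrow(sel$bic_trace), 3)
  expect_equal(sel$bic_trace$K, 1:3)
  with(sel$bic_trace, {
    n_cells <- 10 * 120 * 3
    p <- K * (10 + 120) + K^2 * 3
    expect_equal(BIC, -2 * log_likelihood + p * log(n_cells))
  })
  expect_equal(sel$best_model$BIC, min(sel$bic_trace$BIC))
})

test_that("model selection recovers the planted group count", {
  res <- planted_net(n_chap = 15, n_client = 250, n_layers = 4, K = 2, contrast = 10, seed = 37)
  sel <- suppressWarnings(select_K(res$network, K_min = 2, K_max = 4, n_restarts = 3, seed = 37))
  expect_equal(sel$best_model$K, 2)
})

test_that("hard assignments take the argmax with lowest-index tie-break", {
  res <- planted_net(n_chap = 3, n_client = 4, n_layers = 2, seed = 1)
  fit <- suppressWarnings(fit_multitensor(res$network, K = 2, n_restarts = 1, max_iter = 5))
  fit$u <- matrix(c(0.9, 0.5, 0, 0.1, 0.5, 0), 3, 2, dimnames = list(fit$chaperones, NULL))
  expect_warning(hard <- hard_assignments(fit), "all-zero")
  chap <- hard[hard$type == "chaperone", ]
  expect_equal(chap$group, c(1L, 1L, NA_integer_))
})

test_that("tidy and glance expose memberships and fit summary", {
  res <- planted_net(n_chap = 6, n_client = 40, n_layers = 2, seed = 41)
  fit <- fit_multitensor(res$network, K = 2, n_restarts = 2, seed = 41)
  td <- tidy(fit)
  expect_setequal(unique(td$type), c("chaperone", "client"))
  sums <- tapply(td$membership, td$node, sum)
  # rows sum to 1 except nodes with no links anywhere, whose membership is zero
  expect_true(all(abs(sums - 1) < 1e-8 | sums == 0))
  expect_gt(mean(abs(sums - 1) < 1e-8), 0.5)
  gl <- glance(fit)
  expect_equal(gl$K, 2)
  expect_true(gl$converged)
})
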