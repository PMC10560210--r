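test_that("fixed seed gives bit-identical generated networks", {
  a <- planted_net(seed = 11)
  b <- planted_net(seed = 11)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$truth$u, b$truth$u)
})

test_that("generated networks satisfy multilayer invariants", {
  res <- planted_net(n_chap = 10, n_client = 80, n_layers = 5, seed = 2)
  expect_equal(nrow(validate_multilayer(res$network)), 0)
  expect_equal(nrow(validate_multilayer(layer_matrices(res$network))), 0)
  expect_true(all(abs(rowSums(res$truth$u) - 1) < 1e-12))
  expect_true(all(abs(rowSums(res$truth$v) - 1) < 1e-12))
  expect_true(all(unlist(res$truth$w) >= 0))
})

test_that("single-group model reduces to homogeneous Bernoulli edges", {
  rate <- 0.3
  res <- generate_sbm_multilayer(
    20, 300, 5,
    K = 1, affinity_contrast = 1,
    membership_concentration = 1, seed = 5, within_rate = rate
  )
  n_trials <- 20 * 300 * 5
  density <- nrow(res$network$edges) / n_trials
  sigma <- sqrt(rate * (1 - rate) / n_trials)
  expect_lt(abs(density - rate), 3 * sigma)
})

test_that("infinite contrast with hard memberships yields no between-group edges", {
  res <- generate_sbm_multilayer(
    10, 100, 3,
    K = 2, affinity_contrast = Inf,
    membership_concentration = 0, seed = 9
  )
  gu <- res$truth$group_chaperone
  gv <- res$truth$group_client
  cross <- vapply(layer_matrices(res$network), function(m) {
    sum(m[gu == 1, gv == 2]) + sum(m[gu == 2, gv == 1])
  }, numeric(1))
  expect_true(all(cross == 0))
})

test_that("empirical edge density matches the mean of the clipped rate tensor", {
  res <- generate_sbm_multilayer(
    15, 400, 6,
    K = 3, affinity_contrast = 5,
    membership_concentration = 0.2, seed = 13
  )
  expected <- mean(vapply(names(res$truth$w), function(a) {
    mean(pmin(res$truth$u %*% res$truth$w[[a]] %*% t(res$truth$v), 1))
  }, numeric(1)))
  n_trials <- 15 * 400 * 6
  density <- nrow(res$network$edges) / n_trials
  expect_lt(abs(density - expected), 4 * sqrt(expected * (1 - expected) / n_trials))
})

test_that("nested matrix construction is a staircase of prefix supports", {
  m <- generate_nested_matrix(3, 3)
  expect_equal(m, matrix(c(1, 1, 1, 0, 1, 1, 0, 0, 1), 3, 3), ignore_attr = TRUE)
  supports <- apply(m != 0, 1, which, simplify = FALSE)
  for (i in 2:3) expect_true(all(supports[[i - 1]] %in% supports[[i]]))

  sq <- generate_nested_matrix(4, 4, fill = 1)
  expect_equal(sq, (lower.tri(diag(4), diag = TRUE)) + 0, ignore_attr = TRUE)
})

test_that("a perfectly nested binary matrix is frozen by fixed-margin shuffling", {
  m <- generate_nested_matrix(5, 8, fill = 0.7)
  rho <- spectral_radius(m)
  nulls <- vapply(1:100, function(s) spectral_radius(curveball(m, 50, seed = s)), numeric(1))
  # the staircase's column sums are the conjugate of its row sums: the class is
  # a singleton, so every shuffle reproduces the matrix and p = 0 under the
  # strict-inequality rule
  expect_true(all(abs(nulls - rho) < 1e-12))
  expect_equal(empirical_pvalue(rho, nulls), 0)
})

test_that("planted nested networks carry a nested realized-niche gradient", {
  net <- generate_nested_network(8, 150, 5, fill = 0.5, seed = 4)
  R <- realized_niche_matrix(net)
  # within every chaperone the realized niche decreases across the layer gradient
  expect_true(all(apply(R, 1, function(r) all(diff(r) <= 1e-12))))
  expect_gt(spectral_radius(R), 0)
})

test_that("expression generator encodes the planted network at the target rank correlation", {
  res <- planted_net(n_chap = 5, n_client = 30, n_layers = 1, seed = 21)
  expr <- generate_expression(res$network, n_samples_per_layer = 400, signal_rho = 0.7, seed = 21)
  e <- expr[[1]]
  expect_true(all(e >= 0))
  A <- layer_matrices(res$network)[[1]]
  linked <- which(A == 1, arr.ind = TRUE)
  # only pairs with a single linked chaperone hit the calibration target exactly
  single <- linked[colSums(A)[linked[, 2]] == 1, , drop = FALSE]
  rhos <- vapply(seq_len(nrow(single)), function(i) {
    stats::cor(
      e[rownames(A)[single[i, 1]], ], e[colnames(A)[single[i, 2]], ],
      method = "spearman"
    )
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.7), 0.05)
  # unlinked pairs are uncorrelated
  free <- which(A == 0, arr.ind = TRUE)[1:20, ]
  rho0 <- vapply(seq_len(20), function(i) {
    stats::cor(
      e[rownames(A)[free[i, 1]], ], e[colnames(A)[free[i, 2]], ],
      method = "spearman"
    )
  }, numeric(1))
  expect_lt(max(abs(rho0)), 0.2)
})

test_that("identical planted layers give partner fidelity 1 downstream", {
  m <- mat_layer(c("h1", "h2"), c("p1", "p2", "p3"), rbind(
    c("h1", "p1"), c("h1", "p2"), c("h2", "p3")
  ))
  net <- net_from_layers(A = m, B = m)
  fid <- partner_fidelity_scores(net)
  expect_true(all(fid$fidelity == 1))
})
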