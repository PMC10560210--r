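two_chap_layer <- function() {
  mat_layer(
    c("chap1", "chap2"), c("c1", "c2", "c3"),
    rbind(c("chap1", "c1"), c("chap1", "c2"), c("chap1", "c3"), c("chap2", "c1"))
  )
}

test_that("removal orders follow degree, module, and random rules", {
  m <- mat_layer(
    c("a", "b", "c", "d"), sprintf("p%d", 1:6),
    rbind(
      c("a", "p1"), c("a", "p2"), c("a", "p3"), c("a", "p4"), c("a", "p5"),
      c("b", "p1"), c("b", "p2"), c("b", "p3"),
      c("c", "p4"), c("c", "p5"), c("c", "p6"),
      c("d", "p6")
    )
  ) # degrees a=5, b=3, c=3, d=1
  expect_equal(removal_order(m, "degree"), c("a", "b", "c", "d"))
  groups <- c(a = 1L, c = 1L, b = 2L, d = 2L)
  expect_equal(removal_order(m, "module_first_A", groups), c("a", "c", "b", "d"))
  expect_equal(removal_order(m, "module_first_B", groups), c("b", "d", "a", "c"))
  r1 <- removal_order(m, "random", seed = 9)
  r2 <- removal_order(m, "random", seed = 9)
  expect_identical(r1, r2)
  expect_setequal(r1, rownames(m))
  expect_error(removal_order(m, "module_first_A"), "group_labels")
})

test_that("module numbering orders groups by size with identifier tie-break", {
  labels <- c(h1 = 5L, h2 = 5L, h3 = 9L, h4 = 9L, h5 = 9L)
  mods <- module_numbers(labels)
  expect_equal(unname(mods[c("h3", "h4", "h5")]), c(1L, 1L, 1L))
  expect_equal(unname(mods[c("h1", "h2")]), c(2L, 2L))
  tie <- module_numbers(c(h2 = 1L, h1 = 2L)) # equal sizes: lowest member id first
  expect_equal(unname(tie[c("h1", "h2")]), c(1L, 2L))
})

test_that("co-extinction simulation matches the hand-worked example", {
  curve <- simulate_extinctions(two_chap_layer(), c("chap1", "chap2"))
  expect_equal(curve$x, c(0, 0.5, 1))
  expect_equal(curve$y, c(1, 1 / 3, 0))
  expect_equal(robustness_T(curve), 5 / 12)
})

test_that("complete bipartite layers give the closed-form robustness score", {
  for (N in c(2, 5, 15)) {
    m <- matrix(1L, N, 20, dimnames = list(sprintf("h%02d", 1:N), sprintf("p%02d", 1:20)))
    curve <- simulate_extinctions(m, rownames(m))
    expect_equal(curve$y, c(rep(1, N), 0))
    expect_equal(robustness_T(curve), (2 * N - 1) / (2 * N))
  }
})

test_that("a network that collapses on the first removal scores the floor trapezoid", {
  m <- mat_layer(c("h1", "h2"), c("p1", "p2"), rbind(c("h1", "p1"), c("h1", "p2")))
  curve <- simulate_extinctions(m, c("h1", "h2"))
  expect_equal(curve$y, c(1, 0, 0))
  expect_equal(robustness_T(curve), 0.25)
})

test_that("clients never revive and partitioned clients fall by their chaperone's share", {
  res <- planted_net(n_chap = 10, n_client = 60, n_layers = 2, seed = 91)
  m <- layer_matrices(res$network)[[1]]
  curve <- simulate_extinctions(m, removal_order(m, "degree"))
  expect_true(all(diff(curve$y) <= 1e-12))
  expect_equal(curve$y[length(curve$y)], 0)

  # disjoint client sets: each removal drops exactly that chaperone's share
  part <- mat_layer(
    c("h1", "h2"), sprintf("p%d", 1:5),
    rbind(c("h1", "p1"), c("h1", "p2"), c("h1", "p3"), c("h2", "p4"), c("h2", "p5"))
  )
  curve2 <- simulate_extinctions(part, c("h1", "h2"))
  expect_equal(curve2$y, c(1, 2 / 5, 0))
})

test_that("an empty layer cannot be collapsed", {
  m <- mat_layer(c("h1", "h2"), c("p1",  "p2"), NULL)
  expect_error(simulate_extinctions(m, c("h1", "h2")), "no links")
})

test_that("targeted removal is never more robust than tolerance-order removal", {
  for (s in 1:5) {
    res <- planted_net(n_chap = 10, n_client = 80, n_layers = 1, seed = 100 + s)
    m <- layer_matrices(res$network)[[1]]
    attack <- removal_order(m, "degree")
    tolerate <- rev(attack)
    expect_lte(
      robustness_T(simulate_extinctions(m, attack)),
      robustness_T(simulate_extinctions(m, tolerate))
    )
  }
})

test_that("robustness suite reports all scenarios per layer with random dispersion", {
  res <- planted_net(n_chap = 8, n_client = 50, n_layers = 3, seed = 111)
  fit <- fit_multitensor(res$network, K = 2, n_restarts = 2, seed = 3)
  mods <- module_numbers(suppressWarnings(hard_assignments(fit)))
  tab <- robustness_suite(res$network, mods, n_random_reps = 20, seed = 5)
  expect_equal(nrow(tab), 12) # 4 scenarios x 3 layers
  expect_true(all(tab$T >= 0 & tab$T <= 1))
  expect_true(all(is.na(tab$T_sd[tab$scenario != "random"])))
  expect_true(all(!is.na(tab$T_sd[tab$scenario == "random"])))
  # degree-targeted removal collapses heterogeneous layers faster than random
  wide <- tidyr::pivot_wider(tab[, 1:3], names_from = "scenario", values_from = "T")
  expect_true(all(wide$degree <= wide$random + 1e-9))
  # identical layers give identical deterministic rows
  m <- layer_matrices(res$network)[[1]]
  dup <- robustness_suite(net_from_layers(A = m, B = m), mods, n_random_reps = 5, seed = 5)
  expect_equal(
    dup$T[dup$scenario == "degree" & dup$layer == "A"],
    dup$T[dup$scenario == "degree" & dup$layer == "B"]
  )
})

test_that("duplicating a chaperone row never decreases random-removal robustness", {
  set.seed(12)
  m <- mat_layer(
    sprintf("h%d", 1:4), sprintf("p%d", 1:20),
    cbind(sprintf("h%d", sample(1:4, 30, TRUE)), sprintf("p%d", sample(1:20, 30, TRUE)))
  )
  redundant <- rbind(m, h5 = m["h1", ])
  t_base <- mean(vapply(1:50, function(s) {
    robustness_T(simulate_extinctions(m, removal_order(m, "random", seed = s)))
  }, numeric(1)))
  t_red <- mean(vapply(1:50, function(s) {
    robustness_T(simulate_extinctions(redundant, removal_order(redundant, "random", seed = s)))
  }, numeric(1)))
  expect_gte(t_red + 0.02, t_base) # small Monte-Carlo slack
})

test_that("robustness correlates with realized niche across a density gradient", {
  set.seed(21)
  chaps <- sprintf("h%02d", 1:8)
  clients <- sprintf("p%03d", 1:80)
  mats <- lapply(1:5, function(a) {
    density <- 0.08 * a
    matrix(rbinom(8 * 80, 1, density), 8, 80, dimnames = list(chaps, clients))
  })
  names(mats) <- sprintf("env%d", 1:5)
  net <- as_cci_network(mats)
  tab <- robustness_suite(net, group_labels = NULL, n_random_reps = 20, seed = 31)
  corr <- correlate_T_with_niche(tab, niche_table(net))
  expect_gt(corr$rho[corr$scenario == "random"], 0)
  # identical layers: constant values are flagged undefined
  m <- layer_matrices(net)[[5]]
  same <- net_from_layers(A = m, B = m, C = m)
  tab2 <- robustness_suite(same, group_labels = NULL, n_random_reps = 5, seed = 31)
  corr2 <- suppressWarnings(correlate_T_with_niche(tab2, niche_table(same)))
  expect_true(any(is.na(corr2$rho)))
})
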