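make_demo_net <- function() {
  # h1: {p1,p2,p3} in A, {p2,p3,p4} in B; h2: {p1} in A, {} in B
  a <- mat_layer(
    c("h1", "h2"), paste0("p", 1:4),
    rbind(c("h1", "p1"), c("h1", "p2"), c("h1", "p3"), c("h2", "p1"))
  )
  b <- mat_layer(
    c("h1", "h2"), paste0("p", 1:4),
    rbind(c("h1", "p2"), c("h1", "p3"), c("h1", "p4"))
  )
  net_from_layers(A = a, B = b)
}

test_that("niche table computes links, specialization and realized niche", {
  nt <- niche_table(make_demo_net())
  h1 <- nt[nt$chaperone == "h1", ]
  expect_equal(h1$n_links, c(3, 3))
  expect_equal(unique(h1$n_clients_total), 4) # union {p1..p4}
  expect_equal(unique(h1$specialization), 1)
  expect_equal(h1$realized_niche, c(0.75, 0.75))
  h2 <- nt[nt$chaperone == "h2", ]
  expect_equal(h2$n_links, c(1, 0))
  expect_equal(h2$realized_niche, c(1, 0))
  # invariant: max layer links <= pooled client count
  expect_true(all(tapply(nt$n_links, nt$chaperone, max) <= tapply(nt$n_clients_total, nt$chaperone, unique)))
})

test_that("single-layer networks realize their full niche", {
  net <- as_cci_network(layer_matrices(make_demo_net())["A"])
  nt <- niche_table(net)
  expect_true(all(nt$realized_niche[nt$n_clients_total > 0] == 1))
})

test_that("chaperones with no clients anywhere are flagged, not divided by zero", {
  m <- mat_layer(c("h1", "h2"), c("p1", "p2"), cbind("h1", "p1"))
  nt <- niche_table(net_from_layers(A = m))
  expect_true(all(nt$no_clients[nt$chaperone == "h2"]))
  expect_true(all(is.na(nt$realized_niche[nt$chaperone == "h2"])))
})

test_that("partner fidelity follows the Jaccard formula and the empty-pair rule", {
  pf <- partner_fidelity(make_demo_net())
  # h1: {p1,p2,p3} vs {p2,p3,p4} -> 2/4
  expect_equal(pf$jaccard[pf$chaperone == "h1"], 0.5)
  # h2: {p1} vs {} -> 0 (defined: union non-empty)
  expect_equal(pf$jaccard[pf$chaperone == "h2"], 0)
  # both-empty pairs are undefined and excluded from the median
  z <- mat_layer(c("h1", "h2"), c("p1", "p2"), cbind("h1", "p1"))
  pf2 <- partner_fidelity(net_from_layers(A = z, B = z))
  expect_true(is.na(pf2$jaccard[pf2$chaperone == "h2"]))
  expect_equal(partner_fidelity_scores(net_from_layers(A = z, B = z))$n_pairs, c(1, 0))
})

test_that("15 chaperones x 12 layers yield 66 layer pairs and 990 fidelity values", {
  res <- planted_net(n_chap = 15, n_client = 80, n_layers = 12, seed = 6)
  pf <- partner_fidelity(res$network)
  expect_equal(nrow(dplyr::distinct(pf, layer_a, layer_b)), 66)
  expect_equal(nrow(pf), 990)
})

test_that("within-layer overlap covers each unordered chaperone pair once per layer", {
  res <- planted_net(n_chap = 15, n_client = 80, n_layers = 12, seed = 6)
  ov <- within_layer_overlap(res$network)
  expect_equal(sum(ov$layer == ov$layer[1]), 105)
  expect_equal(nrow(ov), 1260)
  expect_false(any(ov$chaperone_x == ov$chaperone_y))
  # symmetry of the underlying measure: disjoint sets give 0
  a <- mat_layer(c("h1", "h2"), c("p1", "p2"), rbind(c("h1", "p1"), c("h2", "p2")))
  expect_equal(within_layer_overlap(net_from_layers(A = a, B = a))$jaccard, c(0, 0))
})

test_that("layer similarity treats layers as edge sets", {
  m1 <- mat_layer(c("h1", "h2"), c("p1", "p2"), rbind(c("h1", "p1"), c("h1", "p2")))
  m2 <- mat_layer(c("h1", "h2"), c("p1", "p2"), rbind(c("h1", "p2"), c("h2", "p1")))
  ls <- layer_similarity(net_from_layers(A = m1, B = m2))
  expect_equal(ls$jaccard[ls$layer_a == "A" & ls$layer_b == "A"], 1)
  expect_equal(ls$jaccard[ls$layer_a == "A" & ls$layer_b == "B"], 1 / 3)
  expect_equal(ls$jaccard[ls$layer_a == "B" & ls$layer_b == "A"], 1 / 3)
  dup <- layer_similarity(net_from_layers(A = m1, B = m1))
  expect_true(all(dup$jaccard == 1))
})

test_that("spearman_with_bonferroni applies the correction and the cap", {
  x <- 1:10
  y <- x^2 # monotone
  res <- spearman_with_bonferroni(x, y)
  expect_equal(res$rho, 1)
  # corrected p is raw p times the family size, capped at 1
  raw <- spearman_with_bonferroni(x, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9), n_tests = 15)
  expect_equal(raw$p_bonferroni, min(1, raw$p_value * 15))
  weak <- spearman_with_bonferroni(c(1, 2, 3, 4, 5), c(2, 1, 3, 5, 4), n_tests = 15)
  expect_equal(weak$p_bonferroni, 1)
  expect_warning(const <- spearman_with_bonferroni(rep(1, 5), 1:5), "constant")
  expect_true(is.na(const$rho))
})

test_that("expression summary is the log10 of per-layer medians", {
  vals <- rbind(
    g1 = rep(100, 5),
    g2 = c(1, 1, 10, 100, 100),
    g3 = rep(0, 5)
  )
  colnames(vals) <- paste0("s", 1:5)
  e <- expression_matrix(vals, "L1")
  expect_warning(out <- expression_summary(list(e)), "zero median")
  expect_equal(out$log10_median, c(2, 1, NA))
})

test_that("fidelity and realized niche correlate positively on structure-sharing networks", {
  res <- planted_net(n_chap = 15, n_client = 300, n_layers = 6, seed = 77)
  out <- fidelity_niche_correlation(res$network)
  expect_gt(out$rho, 0)
})
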