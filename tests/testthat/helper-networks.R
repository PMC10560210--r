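# shared fixture builders (everything generated in code, no files)

# tiny two-layer network: layer A = {(h1,p1)}, layer B = {(h1,p2)}
toy_two_layer <- function() {
  cci_network(data.frame(
    chaperone = c("h1", "h1"),
    client = c("p1", "p2"),
    layer = c("A", "B")
  ))
}

# deterministic hand-built network over named matrices
net_from_layers <- function(...) {
  as_cci_network(list(...))
}

mat_layer <- function(chaps, clients, edges) {
  m <- matrix(0L, length(chaps), length(clients), dimnames = list(chaps, clients))
  if (length(edges)) m[edges] <- 1L
  m
}

# small planted-structure network used by sbm / linkpred tests
planted_net <- function(n_chap = 15, n_client = 200, n_layers = 4, K = 2,
                        contrast = 10, seed = 42) {
  generate_sbm_multilayer(
    n_chap, n_client, n_layers,
    K = K,
    affinity_contrast = contrast, membership_concentration = 0, seed = seed
  )
}

# brute-force enumeration of all binary matrices with the margins of `mat`
enumerate_margin_class <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  rs <- rowSums(mat)
  cs <- colSums(mat)
  cells <- expand.grid(rep(list(0:1), n * m))
  keep <- apply(cells, 1, function(v) {
    cand <- matrix(v, n, m)
    all(rowSums(cand) == rs) && all(colSums(cand) == cs)
  })
  lapply(which(keep), function(i) matrix(as.numeric(cells[i, ]), n, m))
}

matrix_key <- function(m) paste(as.vector(m), collapse = "")
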