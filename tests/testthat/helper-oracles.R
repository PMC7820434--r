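# Independent oracles used to cross-check the implementation. Each is
# written the dumbest way that is obviously correct, never sharing code
# with the functions it checks.

# Brute-force candidate-formula enumerator: a full grid over the bounds,
# no pruning, no closed forms.
brute_force_fit <- function(observed_mz, adduct_name, bounds, tolerance_ppm) {
  tab <- supported_adducts()
  delta <- tab$mass_delta[tab$adduct == adduct_name]
  grid <- do.call(expand.grid, lapply(bounds, function(b) b[1]:b[2]))
  masses <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.99491461956,
              Na = 22.9897692809, Cl = 34.96885268, S = 31.97207100,
              P = 30.97376163)
  total <- as.matrix(grid) %*% masses[names(bounds)]
  theo <- total + delta
  ppm <- (observed_mz - theo) / theo * 1e6
  keep <- abs(ppm) <= tolerance_ppm & rowSums(grid) >= 1
  out <- grid[keep, , drop = FALSE]
  out$ppm <- ppm[keep]
  out
}

# Betweenness via walk counts: (A^L)[s, t] counts walks of length L, and at
# the shortest length walks are exactly the shortest paths. A shortest s-t
# path passes v iff d(s,v) + d(v,t) = d(s,t), and the number doing so is
# the product of the two segment counts.
betweenness_oracle <- function(edges_from, edges_to, ids) {
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_along(edges_from)) {
    A[edges_from[i], edges_to[i]] <- 1
    A[edges_to[i], edges_from[i]] <- 1
  }
  # path counts by length
  powers <- vector("list", n)
  powers[[1]] <- A
  for (L in seq_len(n - 1)) powers[[L + 1]] <- powers[[L]] %*% A
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  npaths <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    for (L in seq_len(n)) {
      if (powers[[L]][s, t] > 0) {
        dist[s, t] <- L
        npaths[s, t] <- powers[[L]][s, t]
        break
      }
    }
  }
  bc <- stats::setNames(numeric(n), ids)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
        bc[v] <- bc[v] + npaths[s, v] * npaths[v, t] / npaths[s, t]
      }
    }
  }
  if (n < 3) return(bc * 0)
  bc * 2 / ((n - 1) * (n - 2))
}

# Upper-tail hypergeometric p by full enumeration of all C(N, n) draws.
hyper_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K) # term genes are labelled 1..K
  mean(overlaps >= k)
}

random_typed_graph <- function(n, p_edge = 0.4, role = "target") {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  typed_graph(
    nodes = tibble::tibble(id = ids, role = role),
    edges = tibble::tibble(from = pairs[1, keep], to = pairs[2, keep])
  )
}

random_composition <- function(bounds) {
  repeat {
    counts <- vapply(bounds, function(b) sample(b[1]:b[2], 1), integer(1))
    if (sum(counts) >= 1) return(counts)
  }
}
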