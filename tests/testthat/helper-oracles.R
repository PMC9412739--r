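# Independent brute-force / closed-form oracles used across the suite.
# These deliberately share no code with the package implementation.

# --- one-component PLS-DA by the textbook NIPALS recipe -------------------
pls1_oracle <- function(X, y) {
  Xc <- scale(X, center = TRUE, scale = TRUE)
  yc <- y - mean(y)
  w <- drop(crossprod(Xc, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(Xc %*% w)
  q <- sum(yc * t) / sum(t^2)
  r2y <- 1 - sum((yc - t * q)^2) / sum(yc^2)
  list(w = w, t = t, q = q, r2y = r2y)
}

# --- Welch's t statistic and Satterthwaite df, closed form ----------------
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}

# --- graph oracles on small adjacency matrices ----------------------------
bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- which(A[u, ] == 1)
      new <- nb[d[nb] > d[u] + 1]
      d[new] <- d[u] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

# shortest-path counts from s by layered dynamic programming
path_counts <- function(A, s, d) {
  n <- nrow(A)
  sig <- numeric(n); sig[s] <- 1
  for (dist in sort(unique(d[is.finite(d) & d > 0]))) {
    for (u in which(d == dist)) {
      pred <- which(A[u, ] == 1 & d == dist - 1)
      sig[u] <- sum(sig[pred])
    }
  }
  sig
}

betweenness_oracle <- function(A) {
  n <- nrow(A)
  D <- t(vapply(seq_len(n), function(s) bfs_dist(A, s), numeric(n)))
  SIG <- t(vapply(seq_len(n), function(s) path_counts(A, s, D[s, ]),
                  numeric(n)))
  bw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == t || s == v || t == v) next
        if (!is.finite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          bw[v] <- bw[v] + SIG[s, v] * SIG[v, t] / SIG[s, t]
        }
      }
    }
  }
  bw / 2   # undirected: each unordered pair counted twice
}

harmonic_oracle <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(s) {
    d <- bfs_dist(A, s)
    sum(1 / d[-s][is.finite(d[-s]) & d[-s] > 0])
  }, numeric(1))
}

mcc_oracle <- function(A) {
  n <- nrow(A)
  scores <- numeric(n)
  subsets <- lapply(2:n, function(k) combn(n, k, simplify = FALSE))
  for (cl in unlist(subsets, recursive = FALSE)) {
    pairs <- combn(cl, 2)
    is_clique <- all(A[t(pairs)] == 1)
    if (!is_clique) next
    outside <- setdiff(seq_len(n), cl)
    maximal <- !any(vapply(outside, function(v) all(A[v, cl] == 1),
                           logical(1)))
    if (maximal) scores[cl] <- scores[cl] + factorial(length(cl) - 1)
  }
  scores
}

# --- Benjamini-Hochberg step-up, direct textbook form ---------------------
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m / i * p[o[i]])
    adj[o[i]] <- prev
  }
  adj
}

# --- hypergeometric upper tail by explicit combinatorial sum --------------
hyper_tail_oracle <- function(overlap, term_size, bg_size, query_size) {
  ks <- overlap:min(term_size, query_size)
  sum(choose(term_size, ks) * choose(bg_size - term_size, query_size - ks)) /
    choose(bg_size, query_size)
}

# --- random small graph helper --------------------------------------------
random_adjacency <- function(n, p_edge = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p_edge)
  A + t(A)
}

adjacency_to_igraph <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(nrow(A)))
  g
}
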