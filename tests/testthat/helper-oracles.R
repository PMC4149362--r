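# Independent brute-force oracles, deliberately implemented with
# different algorithms than the package paths they check.

# all-pairs shortest-path betweenness by path counting from both ends:
# btw(v) = sum over pairs s < t (s,t != v) of sigma(s,v)*sigma(v,t)/sigma(s,t)
# whenever d(s,v) + d(v,t) = d(s,t).
oracleBetweenness <- function(net) {
  nodes <- networkNodes(net)
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  e <- networkEdges(net)
  for (i in seq_len(nrow(e))) {
    adj[e$node1[i], e$node2[i]] <- TRUE
    adj[e$node2[i], e$node1[i]] <- TRUE
  }
  dist <- matrix(Inf, n, n); sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (u in frontier) for (v in which(adj[u, ])) {
        if (is.infinite(dist[s, v])) { dist[s, v] <- d; nxt <- c(nxt, v) }
        if (dist[s, v] == d) sigma[s, v] <- sigma[s, v] + sigma[s, u]
      }
      frontier <- unique(nxt)
    }
  }
  btw <- setNames(numeric(n), nodes)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || is.infinite(dist[s, t])) next
      if (dist[s, v] + dist[v, t] == dist[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- tot
  }
  btw
}

# exhaustive k-clique enumeration over all node combinations
oracleCliques <- function(net, k) {
  nodes <- sort(networkNodes(net))
  if (length(nodes) < k) return(list())
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  e <- networkEdges(net)
  for (i in seq_len(nrow(e))) {
    adj[e$node1[i], e$node2[i]] <- TRUE
    adj[e$node2[i], e$node1[i]] <- TRUE
  }
  out <- list()
  idx <- combn(n, k)
  full <- k * (k - 1)
  for (j in seq_len(ncol(idx))) {
    members <- idx[, j]
    if (sum(adj[members, members]) == full)
      out[[length(out) + 1L]] <- nodes[members]
  }
  out
}

# exhaustive upper hypergeometric tail
oracleHyperTail <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# two-pass mean/sd
oracleMeanSd <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# canonical string form of a clique list for set comparison
cliqueKeys <- function(cliques)
  sort(vapply(cliques, function(cl) paste(sort(cl), collapse = "|"), ""))

# random Erdos-Renyi QQPPINetwork over letter-ish node names
randomNet <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- combn(nodes, 2)
  keep <- runif(ncol(pairs)) < p
  inter <- Interactome(pairs[1, keep], pairs[2, keep])
  buildQQPPI(nodes, inter, keepIsolated = TRUE)
}

# small literal network from an edge string like "A-B, B-C"
literalNet <- function(edgeString, extraNodes = character()) {
  pairs <- strsplit(trimws(strsplit(edgeString, ",")[[1]]), "-")
  n1 <- vapply(pairs, `[`, "", 1)
  n2 <- vapply(pairs, `[`, "", 2)
  buildQQPPI(unique(c(n1, n2, extraNodes)), Interactome(n1, n2),
             keepIsolated = length(extraNodes) > 0)
}
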