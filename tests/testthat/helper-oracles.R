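# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (plain loops, direct enumeration) so the two
# routes stay independent.

# pairwise-concordance AUC by enumeration over all (positive, negative) pairs
auc_by_enumeration <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# exhaustive threshold scan over the same candidate grid, scored by brute
# force confusion counting
threshold_by_exhaustive_scan <- function(scores, labels) {
  u <- sort(unique(scores))
  pad <- if (length(u) > 1) min(diff(u)) / 2 else 0.5
  cand <- c(u[1] - pad,
            if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + pad)
  best_th <- NA
  best_diff <- Inf; best_tss <- -Inf
  for (th in cand) {
    tp <- sum(scores >= th & labels == 1)
    fn <- sum(scores < th & labels == 1)
    tn <- sum(scores < th & labels == 0)
    fp <- sum(scores >= th & labels == 0)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    d <- abs(sens - spec); tss <- sens + spec - 1
    if (d < best_diff ||
        (d == best_diff && (tss > best_tss ||
                            (tss == best_tss && th > best_th)))) {
      best_th <- th; best_diff <- d; best_tss <- tss
    }
  }
  best_th
}

# BFS reachability from a seed set over an undirected edge list
bfs_reachable <- function(ids, edges, from_set) {
  adj <- setNames(vector("list", length(ids)), ids)
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(ids)), ids)
  queue <- unique(from_set)
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[[w]]) {
      seen[[w]] <- TRUE
      queue <- c(queue, w)
    }
  }
  names(seen)[seen]
}

# small fully-connected toy world shared by several tests
toy_world <- function(seed = 42, n = 60, regions = 2) {
  network <- generate_network(n, regions, seed = seed)
  env <- generate_environment(network, climate_config(), seed = seed + 1)
  list(network = network, env = env)
}

# tiny linearly separable classification problem
separable_data <- function(n = 120, seed = 9) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- data.frame(a = y * 4 + rnorm(n, 0, 0.4),
                  b = -y * 3 + rnorm(n, 0, 0.4))
  list(x = x, y = y)
}
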