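# Independent brute-force oracles used to cross-check the vectorized
# implementations. Each oracle re-derives its quantity with explicit loops,
# never calling the function under test.

# KS tag-set enrichment: explicit loop over j computing the two CDF gaps.
oracle_ks <- function(tags, ranked) {
  v <- sort(match(tags, ranked))
  v <- v[!is.na(v)]
  t <- length(v)
  n <- length(ranked)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  if (a >= b) a else -b
}

# the two one-sided maxima, separately
oracle_ks_ab <- function(tags, ranked) {
  v <- sort(match(tags, ranked))
  v <- v[!is.na(v)]
  t <- length(v)
  n <- length(ranked)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  c(a = a, b = b)
}

# Pearson r computed from first principles (sum formulas) plus the Fisher-z
# two-sided p-value, looped over every gene pair.
oracle_network_edges <- function(z, genes, alpha) {
  n <- ncol(z)
  out <- NULL
  for (a in seq_along(genes)) {
    for (b in seq_along(genes)) {
      if (b <= a) next
      xi <- z[genes[a], ]
      xj <- z[genes[b], ]
      num <- sum((xi - mean(xi)) * (xj - mean(xj)))
      den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
      if (den == 0) next
      r <- num / den
      if (r == 0) next
      p <- 2 * pnorm(-abs(atanh(max(min(r, 1), -1))) * sqrt(n - 3))
      if (is.finite(r) && p < alpha) {
        out <- rbind(out, data.frame(gene_i = genes[a], gene_j = genes[b],
                                     r = r, p = p,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# Activity formula evaluated term by term over the component genes.
oracle_activity <- function(z, component, degrees, signs) {
  norm <- 0
  for (g in component) norm <- norm + degrees[[g]]^2
  norm <- sqrt(norm)
  scores <- numeric(ncol(z))
  for (s in seq_len(ncol(z))) {
    acc <- 0
    for (g in component) {
      acc <- acc + signs[[g]] * degrees[[g]] * z[g, s]
    }
    scores[s] <- acc / norm
  }
  stats::setNames(scores, colnames(z))
}

# Per-sample max over each gene's probes, looped over every gene-sample pair.
oracle_collapse <- function(probe_matrix, probe_map) {
  tab <- table(probe_map$probe)
  single <- names(tab)[tab == 1]
  keep <- probe_map[probe_map$probe %in% single &
                      probe_map$probe %in% rownames(probe_matrix), ]
  genes <- sort(unique(keep$gene))
  out <- matrix(NA_real_, length(genes), ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  for (g in genes) {
    probes <- keep$probe[keep$gene == g]
    for (s in seq_len(ncol(probe_matrix))) {
      best <- -Inf
      for (p in probes) best <- max(best, probe_matrix[p, s])
      out[g, s] <- best
    }
  }
  out
}

# orient each undirected edge with gene_i < gene_j and sort, so edge sets
# from different construction orders can be compared row by row
canonical_edges <- function(edges) {
  swap <- edges$gene_i > edges$gene_j
  tmp <- edges$gene_i[swap]
  edges$gene_i[swap] <- edges$gene_j[swap]
  edges$gene_j[swap] <- tmp
  edges <- edges[order(edges$gene_i, edges$gene_j), ]
  row.names(edges) <- NULL
  edges
}

toy_signature <- function(n_up = 3, n_down = 3, name = "toy") {
  gene_signature(name,
                 up = sprintf("UP%02d", seq_len(n_up)),
                 down = sprintf("DN%02d", seq_len(n_down)))
}
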