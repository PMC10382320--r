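#' Standardize expression rows to z-scores
#'
#' Each gene row is centred to mean 0 and scaled to sample standard deviation
#' 1 (n - 1 denominator). Zero-variance rows are set to all-zero and flagged
#' rather than dropped, so matrix shapes stay stable; a flagged gene can never
#' gain a network edge.
#'
#' @param m Numeric gene-by-sample matrix with at least 2 columns.
#' @return Standardized matrix; attribute `zero_variance` names the flagged
#'   rows.
#' @export
standardize_rows <- function(m) {
  check_expression_matrix(m)
  if (ncol(m) < 2L) stop("standardization needs at least 2 samples")
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  flat <- !is.finite(s) | s == 0
  s[flat] <- 1
  z <- (m - mu) / s
  z[flat, ] <- 0
  structure(z, zero_variance = rownames(m)[flat])
}

#' Build the relevance network of a signature
#'
#' Nodes are the signature genes present in the matrix; every gene pair gets a
#' Pearson correlation across samples, with a two-sided p-value from the
#' Fisher z-transform normal approximation (z = atanh(r), se = 1/sqrt(n - 3)).
#' An edge is kept iff p < `alpha`. The default cutoff 1e-6 is a deliberately
#' stringent fixed threshold, conservative in the Bonferroni sense for the
#' ~10^4 pairwise correlations a signature of ~100 genes generates. Exactly
#' zero correlations carry no sign and are never significant; they are
#' excluded outright.
#'
#' @param z Standardized gene-by-sample matrix (see [standardize_rows()]).
#' @param sig A [gene_signature()].
#' @param alpha Significance threshold on the Fisher-z p-value.
#' @return An object of class `"relevance_network"`: list with `nodes`
#'   (genes used), `edges` (data frame `gene_i`, `gene_j`, `r`, `p`,
#'   `consistent`), `n_samples`, and `alpha`.
#' @export
build_relevance_network <- function(z, sig, alpha = 1e-6) {
  check_expression_matrix(z)
  stopifnot(inherits(sig, "gene_signature"))
  n <- ncol(z)
  if (n <= 3L) stop("need more than 3 samples for Fisher-z edge p-values")
  nodes <- intersect(signature_genes(sig), rownames(z))
  if (length(nodes) < 2L) {
    stop("fewer than 2 signature genes present in the matrix")
  }
  cz <- z[nodes, , drop = FALSE]
  flat <- apply(cz, 1L, stats::sd) == 0
  R <- suppressWarnings(stats::cor(t(cz)))
  idx <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[idx]
  gi <- nodes[idx[, 1L]]
  gj <- nodes[idx[, 2L]]
  ok <- is.finite(r) & r != 0 & !flat[idx[, 1L]] & !flat[idx[, 2L]]
  p <- rep(NA_real_, length(r))
  p[ok] <- 2 * stats::pnorm(-abs(atanh(pmin(pmax(r[ok], -1), 1))) * sqrt(n - 3))
  keep <- ok & p < alpha
  edges <- data.frame(gene_i = gi[keep], gene_j = gj[keep],
                      r = r[keep], p = p[keep],
                      consistent = rep(NA, sum(keep)),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, n_samples = n, alpha = alpha),
            class = "relevance_network")
}

#' @export
print.relevance_network <- function(x, ...) {
  cat("Relevance network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (alpha =", format(x$alpha), ",",
      x$n_samples, "samples)\n")
  if (!all(is.na(x$edges$consistent))) {
    cat(sprintf("  prior-consistent edges: %d/%d\n",
                sum(x$edges$consistent), nrow(x$edges)))
  }
  invisible(x)
}

#' Prune edges inconsistent with the signature's prior signs
#'
#' An edge (i, j) is consistent with the prior when the sign of its
#' correlation equals the product of the two genes' signature signs
#' \eqn{\sigma_i \sigma_j}; inconsistent edges are removed. The consistency
#' fraction f = retained/total is recorded on the result.
#'
#' @param net A [build_relevance_network()] result.
#' @param sig The [gene_signature()] providing the prior signs.
#' @return The pruned `"relevance_network"`, with elements
#'   `consistency_fraction` and `n_edges_total` added. An empty network is
#'   allowed through.
#' @export
prune_inconsistent_edges <- function(net, sig) {
  stopifnot(inherits(net, "relevance_network"),
            inherits(sig, "gene_signature"))
  sgn <- signature_signs(sig)
  if (!all(net$nodes %in% names(sgn))) {
    stop("every network node must carry a sign in the signature")
  }
  e <- net$edges
  total <- nrow(e)
  if (total) {
    e$consistent <- sign(e$r) == sgn[e$gene_i] * sgn[e$gene_j]
    net$edges <- e[e$consistent, , drop = FALSE]
    net$consistency_fraction <- sum(e$consistent) / total
  } else {
    net$consistency_fraction <- NA_real_
  }
  net$n_edges_total <- total
  net
}

#' Permutation significance of the network's prior consistency
#'
#' Tests whether the observed fraction of prior-consistent edges f could arise
#' with randomly assigned gene signs: the signs are permuted over the nodes
#' `n_perm` times and p = (1 + #\{f_perm >= f_obs\}) / (n_perm + 1).
#'
#' @param net An unpruned [build_relevance_network()] result with >= 1 edge.
#' @param sig The [gene_signature()] providing signs.
#' @param n_perm Number of sign permutations (>= 1).
#' @param seed Optional integer seed for the permutations (local to this
#'   call; the global RNG state is restored).
#' @return List with `f_obs`, `p_value`, and `n_perm`.
#' @export
consistency_significance <- function(net, sig, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(net, "relevance_network"),
            inherits(sig, "gene_signature"))
  if (nrow(net$edges) == 0L) stop("network has no edges")
  if (n_perm < 1L) stop("n_perm must be at least 1")
  sgn <- signature_signs(sig)[net$nodes]
  if (anyNA(sgn)) stop("every network node must carry a sign in the signature")
  i <- match(net$edges$gene_i, net$nodes)
  j <- match(net$edges$gene_j, net$nodes)
  rs <- sign(net$edges$r)
  f_obs <- mean(rs == sgn[i] * sgn[j])
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    ps <- sample(sgn)
    mean(rs == ps[i] * ps[j])
  }, numeric(1)))
  list(f_obs = f_obs,
       p_value = (1 + sum(f_perm >= f_obs)) / (n_perm + 1),
       n_perm = n_perm)
}

largest_component <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("gene_i", "gene_j")], directed = FALSE,
    vertices = net$nodes)
  comp <- igraph::components(g)
  sizes <- comp$csize
  if (max(sizes) < 2L) return(character())
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # deterministic tie-break: component containing the alphabetically
    # first gene among the tied components
    first_gene <- vapply(best, function(k) {
      min(names(comp$membership)[comp$membership == k])
    }, character(1))
    best <- best[order(first_gene)][1L]
  }
  names(comp$membership)[comp$membership == best]
}

#' Pathway activity scores from a pruned relevance network
#'
#' The activity score of sample s is the degree-weighted, sign-directed
#' average of standardized expression over the maximally connected component
#' of the pruned network:
#' \deqn{A_s = \sum_i \sigma_i k_i z_{is} / \sqrt{\sum_i k_i^2}}
#' where \eqn{k_i} is the node degree. Genes outside the component (including
#' all isolated nodes) contribute nothing. A high positive score indicates
#' stimulation of the pathway in that sample, a high negative score
#' repression.
#'
#' @param z Standardized gene-by-sample matrix.
#' @param net_pruned A pruned relevance network
#'   (see [prune_inconsistent_edges()]).
#' @param sig The [gene_signature()].
#' @return Named numeric vector of activity scores, one per sample.
#' @export
dart_activity_scores <- function(z, net_pruned, sig) {
  check_expression_matrix(z)
  stopifnot(inherits(net_pruned, "relevance_network"),
            inherits(sig, "gene_signature"))
  comp <- largest_component(net_pruned)
  if (!length(comp)) {
    stop("pruned network has no connected component; ",
         "consider relaxing the edge significance threshold alpha")
  }
  k <- dart_degrees(net_pruned)[comp]
  sgn <- signature_signs(sig)[comp]
  w <- sgn * k / sqrt(sum(k^2))
  colSums(w * z[comp, , drop = FALSE])
}

dart_degrees <- function(net) {
  tab <- table(factor(c(net$edges$gene_i, net$edges$gene_j),
                      levels = net$nodes))
  stats::setNames(as.numeric(tab), net$nodes)
}

#' Fit a relevance-network pathway activity model
#'
#' `dart()` is the one-stop fitting function tying the estimator together:
#' it standardizes the expression rows, builds the signature's relevance
#' network, prunes prior-inconsistent edges, assesses the pruning's
#' permutation significance, and scores every sample on the maximally
#' connected component. The returned object supports `print()`, `summary()`,
#' `coef()` (per-gene score weights), `fitted()` (the per-sample activity
#' scores), `predict()` (scores for new samples, standardized with the
#' training means/sds), and `plot()`.
#'
#' @param x Numeric gene-by-sample expression matrix (normalized,
#'   gene-level).
#' @param signature A [gene_signature()].
#' @param alpha Edge significance threshold on the Fisher-z p-value.
#' @param n_perm Permutations for the consistency test; 0 skips the test.
#' @param seed Optional seed for the permutation test.
#' @return An object of class `"dart"`.
#' @examples
#' sig <- gene_signature("toy", up = c("g1", "g2"), down = c("g3", "g4"))
#' sim <- simulate_cohort(sig, deltas = c(tumour = 1.5, normal = 0),
#'                        n_per_group = 20, n_background_genes = 5, seed = 1)
#' fit <- dart(sim$expression, sig, n_perm = 100, seed = 1)
#' fit
#' head(fitted(fit))
#' @export
dart <- function(x, signature, alpha = 1e-6, n_perm = 1000, seed = NULL) {
  check_expression_matrix(x)
  stopifnot(inherits(signature, "gene_signature"))
  z <- standardize_rows(x)
  net <- build_relevance_network(z, signature, alpha = alpha)
  pruned <- prune_inconsistent_edges(net, signature)
  consistency <- if (n_perm > 0L && nrow(net$edges) > 0L) {
    consistency_significance(net, signature, n_perm = n_perm, seed = seed)
  }
  scores <- dart_activity_scores(z, pruned, signature)
  comp <- largest_component(pruned)
  k <- dart_degrees(pruned)[comp]
  sgn <- signature_signs(signature)[comp]
  structure(list(
    signature = signature,
    alpha = alpha,
    nodes = net$nodes,
    network = net,
    pruned = pruned,
    component = comp,
    degrees = k,
    weights = stats::setNames(as.numeric(sgn * k / sqrt(sum(k^2))), comp),
    consistency = consistency,
    center = rowMeans(x)[comp],
    scale = apply(x[comp, , drop = FALSE], 1L, stats::sd),
    scores = scores,
    zero_variance = attr(z, "zero_variance"),
    n_samples = ncol(x)
  ), class = "dart")
}

#' @export
print.dart <- function(x, ...) {
  cat("Relevance-network pathway activity model\n")
  cat("  signature:", x$signature$name,
      sprintf("(%d up / %d down tags)\n",
              length(x$signature$up), length(x$signature$down)))
  cat(sprintf("  %d genes in matrix, %d edges kept of %d (alpha = %s)\n",
              length(x$nodes), nrow(x$pruned$edges),
              x$pruned$n_edges_total, format(x$alpha)))
  cat(sprintf("  scoring component: %d genes\n", length(x$component)))
  if (!is.null(x$consistency)) {
    cat(sprintf("  prior consistency f = %.3f (permutation p = %.4g)\n",
                x$consistency$f_obs, x$consistency$p_value))
  }
  cat(sprintf("  activity scores for %d samples; range [%.2f, %.2f]\n",
              x$n_samples, min(x$scores), max(x$scores)))
  invisible(x)
}

#' @export
summary.dart <- function(object, ...) {
  structure(list(
    fit = object,
    score_summary = summary(object$scores),
    degree_summary = summary(object$degrees)
  ), class = "summary.dart")
}

#' @export
print.summary.dart <- function(x, ...) {
  print(x$fit)
  cat("\nActivity scores:\n")
  print(x$score_summary)
  cat("\nComponent degrees:\n")
  print(x$degree_summary)
  invisible(x)
}

#' @export
coef.dart <- function(object, ...) object$weights

#' @export
fitted.dart <- function(object, ...) object$scores

#' Score new samples with a fitted activity model
#'
#' New expression columns are standardized gene-wise with the training means
#' and standard deviations, then scored with the fitted component weights.
#'
#' @param object A fitted [dart()] model.
#' @param newdata Gene-by-sample matrix covering all component genes.
#' @param ... Unused.
#' @return Named numeric vector of activity scores.
#' @export
predict.dart <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$scores)
  check_expression_matrix(newdata)
  miss <- setdiff(object$component, rownames(newdata))
  if (length(miss)) {
    stop("newdata lacks component gene(s): ", paste(miss, collapse = ", "))
  }
  z <- (newdata[object$component, , drop = FALSE] - object$center) /
    ifelse(object$scale == 0, 1, object$scale)
  colSums(object$weights * z)
}

#' @export
plot.dart <- function(x, ...) {
  graphics::plot(sort(x$scores), seq_along(x$scores) / length(x$scores),
                 type = "s", xlab = "activity score",
                 ylab = "empirical CDF",
                 main = paste0(x$signature$name, " pathway activity"), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Export a relevance network as a tab-delimited edge list
#'
#' @param net A `"relevance_network"` (pruned or not).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_edges <- function(net, path) {
  stopifnot(inherits(net, "relevance_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export activity scores as a two-column table
#'
#' @param scores Named numeric vector of activity scores.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_activity_scores <- function(scores, path) {
  utils::write.table(
    data.frame(sample = names(scores), activity_score = as.numeric(scores),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Run code with a temporarily seeded RNG, restoring global state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
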