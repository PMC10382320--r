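#' Rank an instance's identifiers by treatment-minus-control change
#'
#' Produces the ranked list a connectivity query consumes: position 1 is the
#' identifier most up-regulated by the treatment relative to its (aggregated)
#' control. Ties are broken by lexicographic identifier order so the ranking
#' is fully deterministic.
#'
#' @param treatment_values Named numeric vector for the treatment sample.
#' @param control_values Named numeric vector for a single control, or a
#'   matrix (identifiers x controls) aggregated by row means.
#' @return Character vector of identifiers, most up-regulated first.
#' @export
rank_instance <- function(treatment_values, control_values) {
  if (is.matrix(control_values)) {
    control_values <- rowMeans(control_values)
  }
  ids <- names(treatment_values)
  if (is.null(ids) || is.null(names(control_values))) {
    stop("treatment and control vectors must be named")
  }
  if (!setequal(ids, names(control_values)) ||
      length(ids) != length(control_values)) {
    stop("treatment and control must cover the same identifier set")
  }
  d <- treatment_values - control_values[ids]
  ids[order(-d, ids, method = "radix")]
}

#' KS enrichment of a tag set in a ranked list
#'
#' The weighted Kolmogorov-Smirnov-style statistic of the connectivity map:
#' with V(1) < ... < V(t) the sorted positions of the t tags present in the
#' n-long ranked list,
#' \deqn{a = \max_j (j/t - V(j)/n), \quad b = \max_j (V(j)/n - (j-1)/t)}
#' and the score is `a` if `a > b`, else `-b`. On the tie a = b the
#' non-negative branch `a` is returned. The score lies in \[-1, 1\]: +1 for
#' tags packed at the top of the list, -1 for tags packed at the bottom.
#'
#' @param tags Character vector of tag identifiers.
#' @param ranked Character vector, the ranked list (no duplicates).
#' @return A single score in \[-1, 1\].
#' @examples
#' ks_enrichment("g1", paste0("g", 1:10))   #  0.9: tag at the very top
#' ks_enrichment("g10", paste0("g", 1:10))  # -1:   tag at the very bottom
#' @export
ks_enrichment <- function(tags, ranked) {
  if (anyDuplicated(ranked)) stop("ranked list contains duplicates")
  v <- sort(match(unique(tags), ranked))
  v <- v[!is.na(v)]
  t <- length(v)
  if (t == 0L) stop("no tag present in the ranked list")
  n <- length(ranked)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a >= b) a else -b
}

#' Combine up- and down-tag KS scores into a raw connectivity score
#'
#' When the two tag sets are enriched at the same end of the list the
#' instance carries no directional signal and the raw score is 0; otherwise
#' it is `ks_up - ks_down`, in \[-2, 2\]. A strongly negative raw score means
#' the treatment moved the signature's up tags down and its down tags up,
#' i.e. reversed the signature.
#'
#' @param ks_up,ks_down KS enrichment scores of the up and down tags.
#' @return Raw score s in \[-2, 2\].
#' @export
combined_raw_score <- function(ks_up, ks_down) {
  stopifnot(is.finite(ks_up), is.finite(ks_down),
            abs(ks_up) <= 1, abs(ks_down) <= 1)
  if (ks_up * ks_down > 0) 0 else ks_up - ks_down
}

#' Scale raw connectivity scores to \[-1, 1\] within a batch
#'
#' With p the largest positive raw score and q the largest magnitude among
#' negative raw scores, c = s/p for s > 0, c = s/q for s < 0, and c = 0 for
#' s = 0. By construction some instance attains c = 1 (resp. -1) whenever any
#' raw score is positive (resp. negative). The map is idempotent and
#' preserves sign and ordering. `NA` entries pass through untouched.
#'
#' @param raw Numeric vector of raw scores.
#' @return Numeric vector of scaled connectivity scores in \[-1, 1\].
#' @export
scale_scores <- function(raw) {
  if (!length(raw)) stop("need at least one instance to scale")
  out <- raw
  pos <- !is.na(raw) & raw > 0
  neg <- !is.na(raw) & raw < 0
  if (any(pos)) out[pos] <- raw[pos] / max(raw[pos])
  if (any(neg)) out[neg] <- raw[neg] / abs(min(raw[neg]))
  out[!is.na(raw) & raw == 0] <- 0
  out
}

#' Query a signature against a batch of ranked instances
#'
#' Computes, for every ranked list, the KS enrichment of the signature's up
#' tags and down tags, the raw combined score, and the batch-scaled
#' connectivity score c in \[-1, 1\]. Instances in which neither tag set has
#' a single member present are flagged null (`NA` scores) and excluded from
#' the scaling; instances where only one tag set is present are likewise
#' flagged, since the combined statistic needs both.
#'
#' @param sig A [gene_signature()] with non-empty up and down tag sets (at
#'   gene or probe level, matching the ranked identifiers).
#' @param ranked_lists Named list of character vectors (one ranked list per
#'   instance).
#' @param sort_by_connectivity Sort the result by ascending connectivity
#'   score (most signature-reversing first)?
#' @return Data frame with one row per instance: `instance`, `ks_up`,
#'   `ks_down`, `raw_score`, `connectivity`, `null` (flag).
#' @export
query_signature <- function(sig, ranked_lists, sort_by_connectivity = FALSE) {
  stopifnot(inherits(sig, "gene_signature"))
  if (!length(sig$up) || !length(sig$down)) {
    stop("connectivity queries need non-empty up and down tag sets")
  }
  if (is.null(names(ranked_lists)) || anyDuplicated(names(ranked_lists))) {
    stop("ranked_lists must be a uniquely named list of instances")
  }
  one <- function(ranked) {
    up_ok <- any(sig$up %in% ranked)
    dn_ok <- any(sig$down %in% ranked)
    if (!up_ok || !dn_ok) {
      return(c(ks_up = NA_real_, ks_down = NA_real_, raw = NA_real_))
    }
    ku <- ks_enrichment(sig$up, ranked)
    kd <- ks_enrichment(sig$down, ranked)
    c(ks_up = ku, ks_down = kd, raw = combined_raw_score(ku, kd))
  }
  m <- t(vapply(ranked_lists, one, numeric(3)))
  out <- data.frame(instance = names(ranked_lists),
                    ks_up = m[, "ks_up"], ks_down = m[, "ks_down"],
                    raw_score = m[, "raw"],
                    connectivity = scale_scores(m[, "raw"]),
                    null = is.na(m[, "raw"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (sort_by_connectivity) {
    out <- out[order(out$connectivity, out$instance, method = "radix"), ]
    row.names(out) <- NULL
  }
  out
}

#' Connectivity-score a batch of perturbational instances
#'
#' Convenience wrapper over [rank_instance()] and [query_signature()]: each
#' instance's ranked list is built from the treatment column minus the mean
#' of its control columns, then the whole batch is KS-scored and scaled.
#'
#' @param x Gene-by-sample expression matrix holding all treatment and
#'   control columns.
#' @param instances Instance table (see [simulate_instances()]): columns
#'   `instance_id`, `compound`, `dose`, `treatment`, `controls`
#'   (`;`-separated sample ids).
#' @param sig A [gene_signature()].
#' @return Data frame as from [query_signature()], with `compound` and
#'   `dose` columns attached.
#' @export
score_connectivity <- function(x, instances, sig) {
  check_expression_matrix(x)
  check_instances(instances, x)
  ranked <- lapply(seq_len(nrow(instances)), function(i) {
    ctrl <- split_controls(instances$controls[i])
    rank_instance(x[, instances$treatment[i]],
                  x[, ctrl, drop = FALSE])
  })
  names(ranked) <- instances$instance_id
  rec <- query_signature(sig, ranked)
  rec$compound <- instances$compound[match(rec$instance,
                                           instances$instance_id)]
  rec$dose <- instances$dose[match(rec$instance, instances$instance_id)]
  rec
}

#' Write / read ranked lists as tab-delimited tables
#'
#' Long format: columns `instance`, `rank`, `identifier`.
#'
#' @param ranked_lists Named list of character vectors.
#' @param path File path.
#' @return `read_ranked_lists` returns a named list of character vectors;
#'   `write_ranked_lists` invisibly returns `path`.
#' @export
write_ranked_lists <- function(ranked_lists, path) {
  tab <- do.call(rbind, lapply(names(ranked_lists), function(id) {
    data.frame(instance = id,
               rank = seq_along(ranked_lists[[id]]),
               identifier = ranked_lists[[id]],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_lists
#' @export
read_ranked_lists <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[order(tab$instance, tab$rank), ]
  split(tab$identifier, tab$instance)
}
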