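split_controls <- function(s) strsplit(s, ";", fixed = TRUE)[[1L]]

check_instances <- function(instances, x = NULL) {
  need <- c("instance_id", "compound", "dose", "treatment", "controls")
  miss <- setdiff(need, names(instances))
  if (length(miss)) {
    stop("instance table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(instances$instance_id)) {
    stop("duplicate instance ids")
  }
  for (i in seq_len(nrow(instances))) {
    ctrl <- split_controls(instances$controls[i])
    if (!length(ctrl)) stop("instance without controls: ",
                            instances$instance_id[i])
    if (instances$treatment[i] %in% ctrl) {
      stop("treatment sample listed among its controls: ",
           instances$instance_id[i])
    }
    if (!is.null(x)) {
      absent <- setdiff(c(instances$treatment[i], ctrl), colnames(x))
      if (length(absent)) {
        stop("sample(s) missing from the matrix: ",
             paste(absent, collapse = ", "))
      }
    }
  }
  invisible(instances)
}

#' Aggregate control activity scores for one instance
#'
#' With three or more controls, one maximum and one minimum occurrence are
#' removed as outliers and the mean of the rest is returned. With one or two
#' controls there is nothing sensible to trim, so the plain mean is used.
#'
#' @param control_scores Numeric vector of control activity scores (>= 1).
#' @return The aggregated control score AS_c.
#' @examples
#' aggregate_controls(c(1, 2, 3))  # 2: trims the 1 and the 3
#' aggregate_controls(c(1, 3))     # 2: too few to trim
#' @export
aggregate_controls <- function(control_scores) {
  n <- length(control_scores)
  if (n == 0L) stop("no control scores to aggregate")
  if (n < 3L) return(mean(control_scores))
  drop <- c(which.max(control_scores), which.min(control_scores))
  mean(control_scores[-drop])
}

#' Activity score difference of an instance
#'
#' The screen's per-instance statistic: AS_d = AS_t - AS_c, the treatment's
#' activity score minus the aggregated control score. Its magnitude is the
#' degree of pathway modulation and its sign the direction (positive:
#' stimulation, negative: repression).
#'
#' @param as_t Treatment activity score.
#' @param as_c Aggregated control activity score.
#' @return AS_d, exact subtraction (vectorized).
#' @export
activity_difference <- function(as_t, as_c) {
  stopifnot(all(is.finite(as_t)), all(is.finite(as_c)))
  as_t - as_c
}

#' Activity-score a batch of perturbational instances
#'
#' Fits the relevance-network activity model on the full perturbational
#' matrix (all treatment and control columns together), then derives each
#' instance's treatment score AS_t, aggregated control score AS_c (high/low
#' control outliers trimmed), and difference AS_d = AS_t - AS_c.
#'
#' @param x Gene-by-sample expression matrix holding all samples.
#' @param instances Instance table (columns `instance_id`, `compound`,
#'   `dose`, `treatment`, `controls` with `;`-separated sample ids).
#' @param sig A [gene_signature()], or a pre-fitted [dart()] model.
#' @param alpha Edge significance threshold (used when `sig` is a
#'   signature).
#' @return Data frame with one row per instance: `instance_id`, `compound`,
#'   `dose`, `as_t`, `as_c`, `as_d`.
#' @export
score_activity <- function(x, instances, sig, alpha = 1e-6) {
  check_expression_matrix(x)
  check_instances(instances, x)
  fit <- if (inherits(sig, "dart")) sig else {
    dart(x, sig, alpha = alpha, n_perm = 0L)
  }
  scores <- if (inherits(sig, "dart")) predict(fit, x) else fitted(fit)
  as_t <- scores[instances$treatment]
  as_c <- vapply(instances$controls, function(s) {
    aggregate_controls(scores[split_controls(s)])
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(instance_id = instances$instance_id,
             compound = instances$compound,
             dose = instances$dose,
             as_t = as.numeric(as_t),
             as_c = as_c,
             as_d = activity_difference(as.numeric(as_t), as_c),
             stringsAsFactors = FALSE)
}

#' Average replicate instances into compound-level summaries
#'
#' Replicate instances of the same compound and dose are averaged: N is the
#' group size and the group's AS_t and AS_c are averaged, with AS_d
#' recomputed as mean(AS_t) - mean(AS_c) (equal to mean(AS_d) by linearity).
#' Connectivity records (column `connectivity`) are averaged the same way;
#' `method = "best"` instead keeps the most negative connectivity in the
#' group.
#'
#' @param records Per-instance records carrying `compound` and `dose` plus
#'   score columns (`as_t`/`as_c`/`as_d` and/or `connectivity`).
#' @param method Replicate aggregation for connectivity: `"mean"` or
#'   `"best"` (most negative).
#' @return Data frame with one row per (compound, dose): `compound`, `dose`,
#'   `n`, and the averaged score columns.
#' @export
average_replicates <- function(records, method = c("mean", "best")) {
  method <- match.arg(method)
  stopifnot(all(c("compound", "dose") %in% names(records)))
  key <- interaction(records$compound, records$dose, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    out <- data.frame(compound = g$compound[1L], dose = g$dose[1L],
                      n = nrow(g), stringsAsFactors = FALSE)
    for (col in intersect(c("as_t", "as_c"), names(g))) {
      out[[col]] <- mean(g[[col]])
    }
    if (all(c("as_t", "as_c") %in% names(g))) {
      out$as_d <- out$as_t - out$as_c
    }
    if ("connectivity" %in% names(g)) {
      v <- g$connectivity[!is.na(g$connectivity)]
      out$connectivity <- if (!length(v)) NA_real_
        else if (method == "mean") mean(v) else min(v)
    }
    out
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out[order(out$compound, out$dose, method = "radix"), , drop = FALSE]
}

#' Order compound summaries by desired direction of modulation
#'
#' `direction = "suppress"` ranks by ascending mean AS_d (most negative, i.e.
#' strongest repression, first); `"stimulate"` by descending. Ties are broken
#' by compound name so the ordering is deterministic.
#'
#' @param summaries Compound summaries from [average_replicates()], or any
#'   data frame with `compound` and a score column.
#' @param direction `"suppress"` or `"stimulate"`.
#' @param score_col Column to rank on (default `"as_d"`).
#' @return The summaries reordered, with a 1-based `rank` column added.
#' @export
rank_compounds <- function(summaries, direction = c("suppress", "stimulate"),
                           score_col = "as_d") {
  direction <- match.arg(direction)
  stopifnot(score_col %in% names(summaries))
  s <- summaries[[score_col]]
  o <- if (direction == "suppress") {
    order(s, summaries$compound, method = "radix")
  } else {
    order(-s, summaries$compound, method = "radix")
  }
  out <- summaries[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  row.names(out) <- NULL
  out
}

#' Intersect the top of two ranked compound lists
#'
#' Takes the first `top_n` compounds of each ranked list (both ranked
#' desirable-first) and returns their intersection, carrying both ranks.
#' This is the screen's final selection step: a hit must both shift the
#' pathway activity score in the desired direction and reverse the
#' signature's expression pattern.
#'
#' @param activity_ranked,connectivity_ranked Data frames with `compound`
#'   and `rank` columns (see [rank_compounds()]).
#' @param top_n Number of top entries to take from each list.
#' @return Data frame `compound`, `rank_activity`, `rank_connectivity`,
#'   ordered by activity rank.
#' @export
intersect_top <- function(activity_ranked, connectivity_ranked, top_n = 50) {
  for (tab in list(activity_ranked, connectivity_ranked)) {
    stopifnot(all(c("compound", "rank") %in% names(tab)))
  }
  if (top_n > nrow(activity_ranked) || top_n > nrow(connectivity_ranked)) {
    warning("top_n exceeds a list length; using the full list(s)")
  }
  top_a <- utils::head(activity_ranked[order(activity_ranked$rank), ], top_n)
  top_c <- utils::head(
    connectivity_ranked[order(connectivity_ranked$rank), ], top_n)
  common <- intersect(top_a$compound, top_c$compound)
  out <- data.frame(
    compound = common,
    rank_activity = top_a$rank[match(common, top_a$compound)],
    rank_connectivity = top_c$rank[match(common, top_c$compound)],
    stringsAsFactors = FALSE)
  out <- out[order(out$rank_activity), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Census of score signs
#'
#' Counts how many records fall strictly below, at, and strictly above zero.
#' Zeros are counted separately and belong to neither signed bucket.
#'
#' @param values Numeric vector (e.g. per-instance AS_d or connectivity).
#' @return Named integer vector `c(negative, zero, positive)`.
#' @export
sign_census <- function(values) {
  values <- values[!is.na(values)]
  c(negative = sum(values < 0),
    zero = sum(values == 0),
    positive = sum(values > 0))
}

#' Min-max normalization to \[0, 1\]
#'
#' @param scores Numeric vector with at least two distinct values.
#' @return `(x - min) / (max - min)`, an order-preserving map onto \[0, 1\].
#' @export
minmax_normalize <- function(scores) {
  rng <- range(scores)
  if (!all(is.finite(rng))) stop("scores must be finite")
  if (rng[1L] == rng[2L]) stop("constant input cannot be min-max normalized")
  (scores - rng[1L]) / (rng[2L] - rng[1L])
}

#' Compare activity scores across sample groups
#'
#' One-way ANOVA across all groups, followed by all pairwise two-sample
#' Welch t-tests with Benjamini-Hochberg adjustment across the pairwise
#' family. Significance stars follow the conventional tiers: ns p > 0.05,
#' * p <= 0.05, ** p <= 0.01, *** p <= 0.001, **** p <= 0.0001. Groups with
#' fewer than 2 observations are excluded with a warning.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param groups Group label per sample (factor or character).
#' @return Object of class `"group_comparison"`: list with `anova`
#'   (`f_statistic`, `p_value`, `df`), `pairwise` (data frame `group1`,
#'   `group2`, `t`, `p`, `p_adj`, `stars`), and `groups_used`.
#' @export
group_comparison <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  groups <- as.character(groups)
  keep <- !is.na(scores) & !is.na(groups)
  scores <- scores[keep]; groups <- groups[keep]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    scores <- scores[keep]; groups <- groups[keep]
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("need at least 2 groups with >= 2 observations")
  fit <- stats::aov(scores ~ factor(groups, levels = lev))
  an <- summary(fit)[[1L]]
  pairs <- utils::combn(lev, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    tt <- stats::t.test(scores[groups == g1], scores[groups == g2])
    data.frame(group1 = g1, group2 = g2,
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
  pw$stars <- significance_stars(pw$p_adj)
  structure(list(
    anova = list(f_statistic = an[["F value"]][1L],
                 p_value = an[["Pr(>F)"]][1L],
                 df = an[["Df"]]),
    pairwise = pw,
    groups_used = lev
  ), class = "group_comparison")
}

significance_stars <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                   labels = c("****", "***", "**", "*", "ns"), right = TRUE))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA over %d groups: F = %.3f, p = %.4g\n",
              length(x$groups_used), x$anova$f_statistic, x$anova$p_value))
  cat("Pairwise Welch t-tests (BH-adjusted):\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Run the full compound screen on a perturbational batch
#'
#' End-to-end prioritization: activity-scores every instance with the
#' relevance-network model (AS_d = AS_t - AS_c), connectivity-scores every
#' instance with the KS tag-set statistic, averages replicates per
#' (compound, dose), ranks both branches desirable-first, and intersects
#' their top `top_n`. For a pathway to be suppressed the desirable direction
#' is negative AS_d; for stimulation, positive AS_d; in both cases the
#' desirable connectivity is negative (the treatment reverses the disease
#' signature).
#'
#' @inheritParams score_activity
#' @param direction `"suppress"` or `"stimulate"`: desired direction of the
#'   pathway activity change.
#' @param top_n Number of top compounds to intersect from each branch.
#' @param replicate_method Replicate aggregation for connectivity
#'   (see [average_replicates()]).
#' @return Object of class `"compound_screen"`: list with per-instance
#'   `activity` and `connectivity` records, compound-level `activity_ranked`
#'   and `connectivity_ranked` tables, the intersection `hits`, and the
#'   per-branch `census` of score signs.
#' @export
screen_compounds <- function(x, instances, sig,
                             direction = c("suppress", "stimulate"),
                             alpha = 1e-6, top_n = 50,
                             replicate_method = c("mean", "best")) {
  direction <- match.arg(direction)
  replicate_method <- match.arg(replicate_method)
  act <- score_activity(x, instances, sig, alpha = alpha)
  conn <- score_connectivity(x, instances, sig)
  act_sum <- average_replicates(act)
  conn_sum <- average_replicates(conn, method = replicate_method)
  act_ranked <- rank_compounds(act_sum, direction = direction)
  # desirable connectivity is always the most negative (signature reversal)
  conn_ranked <- rank_compounds(conn_sum, direction = "suppress",
                                score_col = "connectivity")
  hits <- intersect_top(act_ranked, conn_ranked, top_n = top_n)
  structure(list(
    direction = direction, top_n = top_n,
    activity = act, connectivity = conn,
    activity_ranked = act_ranked, connectivity_ranked = conn_ranked,
    hits = hits,
    census = list(activity = sign_census(act$as_d),
                  connectivity = sign_census(conn$connectivity))
  ), class = "compound_screen")
}

#' @export
print.compound_screen <- function(x, ...) {
  cat(sprintf("Compound screen (%s; top %d of each branch)\n",
              x$direction, x$top_n))
  cat(sprintf("  %d instances, %d compound x dose groups\n",
              nrow(x$activity), nrow(x$activity_ranked)))
  cen <- x$census
  cat(sprintf("  AS_d sign census: %d negative / %d zero / %d positive\n",
              cen$activity["negative"], cen$activity["zero"],
              cen$activity["positive"]))
  cat(sprintf("  connectivity sign census: %d negative / %d zero / %d positive\n",
              cen$connectivity["negative"], cen$connectivity["zero"],
              cen$connectivity["positive"]))
  cat(sprintf("  hits in both top lists: %d\n", nrow(x$hits)))
  if (nrow(x$hits)) print(utils::head(x$hits, 10L))
  invisible(x)
}
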