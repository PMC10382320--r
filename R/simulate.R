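#' Configuration for the perturbational-data simulator
#'
#' Defines the study conditions emulated by [simulate_instances()]: a batch
#' of compound-treatment instances (each a treated sample paired with 1-5
#' vehicle controls, with 1-5 replicate instances per compound at a shared
#' dose) measured on a gene panel of signature genes plus independent
#' background genes.
#'
#' Signature genes load on a shared latent pathway factor with sign-directed
#' loadings, \eqn{x_g = \sigma_g \sqrt{\rho} f + \sqrt{1-\rho}\,\epsilon},
#' so any two same-tag genes correlate at \eqn{\rho} and cross-tag pairs at
#' \eqn{-\rho} — the structure the relevance network is built to recover.
#' The factor is drawn once per instance and shared by the treated sample
#' and its vehicle controls (they come from the same culture batch), so
#' pathway-level biological noise largely cancels in the treatment-minus-
#' control contrast, as it does in a paired design. Background genes are
#' independent noise. A compound of class `"reverser"`
#' shifts its treated samples' affected up-tags down by \eqn{\delta} within-
#' gene standard deviations and affected down-tags up by the same amount
#' (class `"mimicker"`: mirrored; `"null"`: no shift). Effects are additive
#' on the log-intensity scale and planted at the compound level, so
#' replicates share them.
#'
#' @param signature A [gene_signature()].
#' @param n_compounds Number of compounds in the batch.
#' @param classes Compound classes: vector of `"reverser"`, `"mimicker"`,
#'   `"null"`, recycled/validated to `n_compounds`. The default plants 10%
#'   reversers and 10% mimickers among nulls.
#' @param replicates Replicate instances per compound (1-5).
#' @param controls Vehicle controls per treatment (1-5).
#' @param delta Effect size in units of within-gene standard deviation.
#' @param affected_fraction Fraction of each tag set a compound affects.
#' @param rho Within-signature latent-factor correlation, in \[0, 1).
#' @param noise_sd Standard deviation of the idiosyncratic noise and the
#'   background genes.
#' @param n_background_genes Number of independent background genes.
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(signature,
                              n_compounds = 100,
                              classes = NULL,
                              replicates = 2,
                              controls = 3,
                              delta = 2,
                              affected_fraction = 1,
                              rho = 0.6,
                              noise_sd = 1,
                              n_background_genes = 100,
                              seed = 1) {
  stopifnot(inherits(signature, "gene_signature"))
  if (is.null(classes)) {
    n_rev <- max(1L, round(0.1 * n_compounds))
    n_mim <- max(1L, round(0.1 * n_compounds))
    classes <- c(rep("reverser", n_rev), rep("mimicker", n_mim),
                 rep("null", n_compounds - n_rev - n_mim))
  }
  if (length(classes) != n_compounds) {
    stop("classes must name a class for every compound")
  }
  if (!all(classes %in% c("reverser", "mimicker", "null"))) {
    stop("classes must be 'reverser', 'mimicker', or 'null'")
  }
  if (delta < 0) stop("delta must be non-negative")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (replicates < 1 || replicates > 5) stop("replicates must be in 1..5")
  if (controls < 1 || controls > 5) stop("controls must be in 1..5")
  if (affected_fraction <= 0 || affected_fraction > 1) {
    stop("affected_fraction must lie in (0, 1]")
  }
  if (n_compounds < 1 || n_background_genes < 0 || noise_sd <= 0) {
    stop("invalid counts or noise sd")
  }
  structure(list(signature = signature, n_compounds = n_compounds,
                 classes = classes, replicates = replicates,
                 controls = controls, delta = delta,
                 affected_fraction = affected_fraction, rho = rho,
                 noise_sd = noise_sd,
                 n_background_genes = n_background_genes,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sim_panel <- function(cfg, n_samples, f = stats::rnorm(n_samples)) {
  sig_genes <- signature_genes(cfg$signature)
  sgn <- signature_signs(cfg$signature)
  eps <- matrix(stats::rnorm(length(sig_genes) * n_samples,
                             sd = cfg$noise_sd),
                length(sig_genes), n_samples)
  sig_block <- outer(sgn[sig_genes] * sqrt(cfg$rho), f) +
    sqrt(1 - cfg$rho) * eps
  bg <- if (cfg$n_background_genes > 0) {
    matrix(stats::rnorm(cfg$n_background_genes * n_samples,
                        sd = cfg$noise_sd),
           cfg$n_background_genes, n_samples,
           dimnames = list(sprintf("BG%04d", seq_len(cfg$n_background_genes)),
                           NULL))
  }
  m <- rbind(sig_block, bg)
  rownames(m)[seq_along(sig_genes)] <- sig_genes
  m
}

# within-gene sd of a signature gene under the factor model
sim_gene_sd <- function(cfg) {
  sqrt(cfg$rho + (1 - cfg$rho) * cfg$noise_sd^2)
}

#' Simulate a batch of perturbational instances
#'
#' Generates the expression matrix, instance table, and ground-truth class
#' table for a compound screen under the conditions in `cfg` (see
#' [simulation_config()]). Control samples sit at baseline; each treated
#' sample of a reverser/mimicker compound carries the planted signed shift on
#' its affected signature genes. Deterministic given the config's seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `expression` (gene x sample matrix), `instances`
#'   (columns `instance_id`, `compound`, `dose`, `treatment`, `controls`),
#'   and `truth` (columns `compound`, `class`).
#' @export
simulate_instances <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    sig <- cfg$signature
    sgn <- signature_signs(sig)
    gene_sd <- sim_gene_sd(cfg)
    n_inst <- cfg$n_compounds * cfg$replicates
    n_samples <- n_inst * (1L + cfg$controls)
    # one latent-factor draw per instance, shared by its treatment and
    # controls (paired design)
    f_inst <- stats::rnorm(n_inst)
    m <- sim_panel(cfg, n_samples,
                   f = rep(f_inst, each = 1L + cfg$controls))
    compounds <- sprintf("cpd%04d", seq_len(cfg$n_compounds))
    doses <- sample(c(0.1, 1, 10), cfg$n_compounds, replace = TRUE)
    affected <- lapply(seq_len(cfg$n_compounds), function(i) {
      pick <- function(tags) {
        sort(sample(tags, max(1L, ceiling(cfg$affected_fraction *
                                            length(tags)))))
      }
      list(up = if (length(sig$up)) pick(sig$up) else character(),
           down = if (length(sig$down)) pick(sig$down) else character())
    })
    inst <- vector("list", n_inst)
    col <- 0L
    sample_names <- character(n_samples)
    k <- 0L
    for (i in seq_len(cfg$n_compounds)) {
      for (r in seq_len(cfg$replicates)) {
        k <- k + 1L
        id <- sprintf("inst%05d", k)
        treat_col <- col + 1L
        ctrl_cols <- col + 1L + seq_len(cfg$controls)
        col <- col + 1L + cfg$controls
        sample_names[treat_col] <- paste0(id, "_T")
        sample_names[ctrl_cols] <- paste0(id, "_C", seq_len(cfg$controls))
        cls <- cfg$classes[i]
        if (cls != "null" && cfg$delta > 0) {
          dirn <- if (cls == "reverser") -1 else 1
          genes <- c(affected[[i]]$up, affected[[i]]$down)
          m[genes, treat_col] <- m[genes, treat_col] +
            dirn * sgn[genes] * cfg$delta * gene_sd
        }
        inst[[k]] <- data.frame(
          instance_id = id, compound = compounds[i], dose = doses[i],
          treatment = paste0(id, "_T"),
          controls = paste(paste0(id, "_C", seq_len(cfg$controls)),
                           collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    colnames(m) <- sample_names
    list(expression = m,
         instances = do.call(rbind, inst),
         truth = data.frame(compound = compounds, class = cfg$classes,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a labelled cohort expression matrix
#'
#' Emulates a cohort with predefined sample groups (e.g. tumour subtypes and
#' normal tissue): all samples share the signature's latent-factor
#' correlation structure, and each group receives a sign-directed mean shift
#' of its `delta` (in within-gene standard deviations; up-tags shifted by
#' `+delta`, down-tags by `-delta`).
#'
#' @param signature A [gene_signature()].
#' @param deltas Named numeric vector: one effect size per group.
#' @param n_per_group Samples per group (single value or per-group vector),
#'   each >= 2.
#' @param rho Within-signature latent-factor correlation.
#' @param noise_sd Noise standard deviation.
#' @param n_background_genes Number of independent background genes.
#' @param seed Integer seed.
#' @return List with `expression` (gene x sample matrix) and `groups`
#'   (group label per column).
#' @export
simulate_cohort <- function(signature, deltas, n_per_group,
                            rho = 0.6, noise_sd = 1,
                            n_background_genes = 100, seed = 1) {
  stopifnot(inherits(signature, "gene_signature"))
  if (length(deltas) < 2L || is.null(names(deltas))) {
    stop("deltas must be a named vector with at least 2 groups")
  }
  n_per_group <- rep_len(n_per_group, length(deltas))
  if (any(n_per_group < 2L)) stop("every group needs at least 2 samples")
  cfg <- simulation_config(signature, n_compounds = 1,
                           classes = "null", rho = rho,
                           noise_sd = noise_sd,
                           n_background_genes = n_background_genes,
                           seed = seed)
  with_seed(as.integer(seed), {
    n_total <- sum(n_per_group)
    m <- sim_panel(cfg, n_total)
    groups <- rep(names(deltas), n_per_group)
    colnames(m) <- sprintf("%s_%03d", groups, stats::ave(
      seq_len(n_total), groups, FUN = seq_along))
    sgn <- signature_signs(signature)
    gene_sd <- sim_gene_sd(cfg)
    genes <- signature_genes(signature)
    for (g in names(deltas)) {
      cols <- groups == g
      m[genes, cols] <- m[genes, cols] +
        sgn[genes] * deltas[[g]] * gene_sd
    }
    list(expression = m, groups = groups)
  })
}
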