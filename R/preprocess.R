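#' Read / write a gene-by-sample expression matrix
#'
#' Matrices travel as tab-delimited text: first column the gene (or probe)
#' identifier, header row of sample identifiers. Row and column identifiers
#' must be unique.
#'
#' @param path File path.
#' @return `read_expression_matrix` returns a numeric matrix with gene
#'   rownames and sample colnames; `write_expression_matrix` invisibly
#'   returns `path`.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  check_expression_matrix(m)
}

#' @rdname read_expression_matrix
#' @param m Numeric matrix, genes in rows, samples in columns.
#' @param id_name Header for the identifier column.
#' @export
write_expression_matrix <- function(m, path, id_name = "gene") {
  check_expression_matrix(m)
  tab <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[1L] <- id_name
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

check_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression data must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs row (gene) and column (sample) names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate row identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate column identifiers")
  m
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes mapping to zero or to multiple genes are discarded. For each
#' remaining gene the expression value in each sample is the maximum across
#' that gene's probes in that sample.
#'
#' @param probe_matrix Numeric matrix, probes in rows, samples in columns.
#' @param probe_map Data frame with columns `probe` and `gene`; a probe
#'   appearing on several rows maps to several genes (and is discarded).
#' @return Gene-level numeric matrix. Attribute `discarded_probes` lists the
#'   probes dropped for multi- or zero-mapping.
#' @examples
#' m <- matrix(c(1, 5, 3, 2), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' pm <- data.frame(probe = c("p1", "p2"), gene = "A")
#' collapse_probes(m, pm)  # gene A = pmax of its probes, per sample
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  check_expression_matrix(probe_matrix)
  stopifnot(is.data.frame(probe_map),
            all(c("probe", "gene") %in% names(probe_map)))
  probe <- as.character(probe_map$probe)
  gene <- as.character(probe_map$gene)
  map <- unique(data.frame(probe = probe, gene = gene,
                           stringsAsFactors = FALSE))
  n_genes <- table(map$probe)
  single <- names(n_genes)[n_genes == 1L]
  keep <- map[map$probe %in% single & map$probe %in% rownames(probe_matrix), ]
  discarded <- setdiff(rownames(probe_matrix), keep$probe)
  if (nrow(keep) == 0L) {
    stop("no probe maps to exactly one gene; nothing left after discarding")
  }
  by_gene <- split(keep$probe, keep$gene)
  out <- t(vapply(by_gene, function(p) {
    apply(probe_matrix[p, , drop = FALSE], 2L, max)
  }, numeric(ncol(probe_matrix))))
  colnames(out) <- colnames(probe_matrix)
  structure(out, discarded_probes = discarded)
}

#' Convert an FPKM matrix to log2(TPM + 1)
#'
#' Per sample, \eqn{TPM_i = FPKM_i / \sum_j FPKM_j \times 10^6}, then
#' \eqn{\log_2(TPM + 1)}. Each pre-log column sums to \eqn{10^6} exactly.
#'
#' @param m Numeric matrix of non-negative FPKM values.
#' @return Matrix of log2(TPM + 1) values, same shape.
#' @export
fpkm_to_log2_tpm <- function(m) {
  check_expression_matrix(m)
  if (any(m < 0)) stop("FPKM values must be non-negative")
  cs <- colSums(m)
  if (any(cs <= 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(m)[cs <= 0], collapse = ", "))
  }
  tpm <- sweep(m, 2L, cs, "/") * 1e6
  log2(tpm + 1)
}

#' Convert scaled abundance estimates to log2 TPM
#'
#' Per-sample scaled transcript abundance estimates (fractions summing to ~1,
#' as produced by RSEM) are multiplied by \eqn{10^6} to give TPM and
#' log2-transformed with a pseudocount of 1.
#'
#' @param m Numeric matrix of non-negative scaled estimates.
#' @param pseudocount Added before the log; default 1.
#' @return Matrix of log2(TPM + pseudocount) values.
#' @export
scaled_estimate_to_log2_tpm <- function(m, pseudocount = 1) {
  check_expression_matrix(m)
  if (any(m < 0)) stop("scaled estimates must be non-negative")
  log2(m * 1e6 + pseudocount)
}
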