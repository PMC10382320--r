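#' Directional gene signature
#'
#' A gene signature is a named pair of disjoint tag sets: genes expected to be
#' up-regulated in the condition of interest ("up" tags) and genes expected to
#' be down-regulated ("down" tags). Every gene carries a prior sign
#' \eqn{\sigma(g)}: +1 for up tags, -1 for down tags. Signatures are the query
#' object for both scoring branches of the screen (relevance-network activity
#' scoring and KS connectivity scoring).
#'
#' Gene symbols are treated as opaque, case-sensitive tokens; no alias
#' resolution is attempted. Tag-set order is preserved from the input, but all
#' scoring treats tag sets as unordered.
#'
#' @param name Signature name (single string).
#' @param up Character vector of up-tag gene symbols (may be empty).
#' @param down Character vector of down-tag gene symbols (may be empty).
#'
#' @return An object of class `"gene_signature"`: a list with elements
#'   `name`, `up`, and `down`.
#' @examples
#' sig <- gene_signature("toy", up = c("A", "B"), down = "C")
#' signature_signs(sig)
#' @export
gene_signature <- function(name, up = character(), down = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  up <- as.character(up)
  down <- as.character(down)
  if (anyDuplicated(up)) {
    stop("duplicate gene(s) in up tags: ",
         paste(unique(up[duplicated(up)]), collapse = ", "))
  }
  if (anyDuplicated(down)) {
    stop("duplicate gene(s) in down tags: ",
         paste(unique(down[duplicated(down)]), collapse = ", "))
  }
  both <- intersect(up, down)
  if (length(both)) {
    stop("gene(s) present in both up and down tags: ",
         paste(both, collapse = ", "))
  }
  if (length(up) + length(down) == 0L) {
    stop("a signature must contain at least one gene")
  }
  structure(list(name = name, up = up, down = down),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature:", x$name, "\n")
  cat(sprintf("  up   (%d): %s\n", length(x$up),
              paste(utils::head(x$up, 8L), collapse = ", ")))
  cat(sprintf("  down (%d): %s\n", length(x$down),
              paste(utils::head(x$down, 8L), collapse = ", ")))
  invisible(x)
}

#' Prior sign of every signature gene
#'
#' @param sig A [gene_signature()].
#' @return Named numeric vector: +1 for up tags, -1 for down tags.
#' @export
signature_signs <- function(sig) {
  stopifnot(inherits(sig, "gene_signature"))
  stats::setNames(c(rep(1, length(sig$up)), rep(-1, length(sig$down))),
                  c(sig$up, sig$down))
}

#' All genes of a signature
#'
#' @inheritParams signature_signs
#' @return Character vector, up tags first.
#' @export
signature_genes <- function(sig) {
  stopifnot(inherits(sig, "gene_signature"))
  c(sig$up, sig$down)
}

check_direction_table <- function(direction_table) {
  if (!is.data.frame(direction_table) || nrow(direction_table) == 0L) {
    stop("direction table must be a non-empty data frame")
  }
  need <- c("gene", "direction")
  miss <- setdiff(need, names(direction_table))
  if (length(miss)) {
    stop("direction table lacks column(s): ", paste(miss, collapse = ", "))
  }
  gene <- as.character(direction_table$gene)
  if (anyDuplicated(gene)) {
    stop("duplicate gene(s) in direction table: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  dirn <- as.character(direction_table$direction)
  if (anyNA(dirn) || !all(dirn %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down' for every gene")
  }
  invisible(direction_table)
}

#' Build a signature from a direction table
#'
#' A direction table records, per pathway gene, whether the gene was observed
#' up- or down-regulated in the condition of interest (here: tumour versus
#' normal tissue, as determined upstream by gene set enrichment analysis). An
#' optional logical `is_core` column flags the enrichment "core" (leading-edge)
#' members that contribute most to the pathway's enrichment; it is consumed by
#' [build_combined_signature()].
#'
#' @param direction_table Data frame with columns `gene`, `direction`
#'   (`"up"`/`"down"`), and optionally `is_core` (logical).
#' @param name Name for the resulting signature.
#' @return A [gene_signature()] whose up/down tag sets partition the table's
#'   genes by direction.
#' @examples
#' tab <- data.frame(gene = c("A", "B", "C"),
#'                   direction = c("up", "up", "down"))
#' build_signature(tab, "toy")
#' @export
build_signature <- function(direction_table, name) {
  check_direction_table(direction_table)
  gene <- as.character(direction_table$gene)
  dirn <- as.character(direction_table$direction)
  gene_signature(name, up = gene[dirn == "up"], down = gene[dirn == "down"])
}

#' Build a combined signature from two pathways' core members
#'
#' Collapses two directional pathway signatures into one by taking the
#' enrichment core members of the up-regulated pathway as the combined up tags
#' and the core members of the down-regulated pathway as the combined down
#' tags. A gene ending up in both tag sets signals contradictory input and is
#' an error, not a silent drop.
#'
#' @param sig_up_source Direction table (with `is_core`) of the pathway whose
#'   core up-regulated genes become the combined "up" tags.
#' @param sig_down_source Direction table (with `is_core`) of the pathway whose
#'   core down-regulated genes become the combined "down" tags.
#' @param name Name for the combined signature.
#' @return A [gene_signature()].
#' @export
build_combined_signature <- function(sig_up_source, sig_down_source, name) {
  for (tab in list(sig_up_source, sig_down_source)) {
    check_direction_table(tab)
    if (!"is_core" %in% names(tab)) {
      stop("both direction tables must carry an 'is_core' column")
    }
  }
  up <- with(sig_up_source,
             as.character(gene)[direction == "up" & as.logical(is_core)])
  down <- with(sig_down_source,
               as.character(gene)[direction == "down" & as.logical(is_core)])
  conflict <- intersect(up, down)
  if (length(conflict)) {
    stop("gene(s) with conflicting direction across the two sources: ",
         paste(conflict, collapse = ", "))
  }
  gene_signature(name, up = up, down = down)
}

#' Read / write a signature as GMT tag sets
#'
#' The two tag sets are stored as two GMT lines named `<name>_UP` and
#' `<name>_DN` (gene-set name, description, then one gene symbol per field,
#' tab-separated). `read_signature_gmt(write_signature_gmt(sig, f))` is the
#' identity on `(name, up, down)`.
#'
#' @param path Path of the GMT file.
#' @param name Optional signature name; by default inferred from the `_UP`
#'   line.
#' @return `read_signature_gmt` returns a [gene_signature()];
#'   `write_signature_gmt` invisibly returns `path`.
#' @export
read_signature_gmt <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    stop("malformed GMT line(s) (need name, description, >=1 gene): ",
         paste(which(bad), collapse = ", "))
  }
  set_names <- vapply(fields, `[[`, "", 1L)
  if (is.null(name)) {
    up_idx <- grep("_UP$", set_names)
    if (length(up_idx) != 1L) stop("GMT must contain exactly one *_UP line")
    name <- sub("_UP$", "", set_names[up_idx])
  }
  pick <- function(suffix) {
    idx <- which(set_names == paste0(name, suffix))
    if (length(idx) != 1L) {
      stop("GMT line '", name, suffix, "' missing or duplicated in ", path)
    }
    fields[[idx]][-(1:2)]
  }
  gene_signature(name, up = pick("_UP"), down = pick("_DN"))
}

#' @rdname read_signature_gmt
#' @param sig A [gene_signature()] to write.
#' @export
write_signature_gmt <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  if (!length(sig$up) || !length(sig$down)) {
    stop("GMT export needs non-empty up and down tag sets")
  }
  lines <- c(
    paste(c(paste0(sig$name, "_UP"), "up tags", sig$up), collapse = "\t"),
    paste(c(paste0(sig$name, "_DN"), "down tags", sig$down), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Translate a gene-level signature to platform probe identifiers
#'
#' Array-platform queries need probe identifiers rather than gene symbols.
#' Each signature gene expands to all of its probes, inheriting the gene's
#' sign; genes with no probe are dropped and reported. A probe that would
#' inherit conflicting signs (mapped from both an up and a down gene) is an
#' error.
#'
#' @param sig A [gene_signature()].
#' @param probe_map Data frame with columns `probe` and `gene` (one row per
#'   probe-gene pair; one gene may map to many probes).
#' @return List with elements `signature` (probe-level [gene_signature()], or
#'   `NULL` when no gene mapped) and `dropped` (character vector of signature
#'   genes with no probe).
#' @export
map_genes_to_probes <- function(sig, probe_map) {
  stopifnot(inherits(sig, "gene_signature"), is.data.frame(probe_map))
  need <- c("probe", "gene")
  if (!all(need %in% names(probe_map))) {
    stop("probe_map needs columns 'probe' and 'gene'")
  }
  probe <- as.character(probe_map$probe)
  gene <- as.character(probe_map$gene)
  expand <- function(tags) unique(probe[gene %in% tags])
  up <- expand(sig$up)
  down <- expand(sig$down)
  conflict <- intersect(up, down)
  if (length(conflict)) {
    stop("probe(s) inheriting conflicting signs: ",
         paste(conflict, collapse = ", "))
  }
  mapped <- unique(gene)
  dropped <- setdiff(signature_genes(sig), mapped)
  out <- if (length(up) + length(down) == 0L) NULL else {
    gene_signature(sig$name, up = up, down = down)
  }
  list(signature = out, dropped = dropped)
}

#' Bundled pathway signatures and direction tables
#'
#' The package ships the three worked example signatures from the breast
#' cancer screen as plain-text fixtures: a 40-gene cell-cycle/proliferation
#' pathway signature (27 up / 13 down tags; "FOXM1"), a 57-gene lipid
#' metabolism pathway signature (12 up / 45 down; "PPARA"), and the combined
#' signature built from the two pathways' enrichment core members (21 up / 26
#' down; "FOXM1_PPARA").
#'
#' @param which One of `"FOXM1"`, `"PPARA"`, `"FOXM1_PPARA"`.
#' @return `bundled_signature` returns a [gene_signature()];
#'   `bundled_direction_table` returns the direction table (with `is_core`)
#'   for `"FOXM1"` or `"PPARA"`.
#' @examples
#' bundled_signature("FOXM1")
#' @export
bundled_signature <- function(which = c("FOXM1", "PPARA", "FOXM1_PPARA")) {
  which <- match.arg(which)
  file <- c(FOXM1 = "foxm1.gmt", PPARA = "ppara.gmt",
            FOXM1_PPARA = "foxm1_ppara.gmt")[[which]]
  read_signature_gmt(system.file("extdata", file, package = "dartmap",
                                 mustWork = TRUE))
}

#' @rdname bundled_signature
#' @export
bundled_direction_table <- function(which = c("FOXM1", "PPARA")) {
  which <- match.arg(which)
  file <- c(FOXM1 = "foxm1_directions.tsv",
            PPARA = "ppara_directions.tsv")[[which]]
  tab <- utils::read.delim(system.file("extdata", file, package = "dartmap",
                                       mustWork = TRUE),
                           stringsAsFactors = FALSE)
  tab$is_core <- as.logical(tab$is_core)
  tab
}
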