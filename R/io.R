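#' Read and write the package's tabular interchange formats
#'
#' All on-disk formats are plain TSV with a header row. Methylation matrices
#' are stored CpGs-in-rows x samples-in-columns (the Illumina export
#' convention), with the first column named `cpg_id`; in memory the matrix is
#' transposed to samples x CpGs. The CpG annotation manifest has columns
#' `cpg_id`, `chr`, `pos` (1-based position, Illumina-manifest convention) and
#' `gene`, where `gene` may hold several semicolon-separated symbols.
#'
#' @param m A [meth_matrix].
#' @param path File path.
#' @param stage Processing stage to tag the matrix read from disk with.
#' @return Readers return the parsed object; writers return `path` invisibly.
#' @name meth_io
NULL

#' @rdname meth_io
#' @export
write_methylation_tsv <- function(m, path) {
  stopifnot(is_meth_matrix(m))
  out <- data.frame(cpg_id = cpg_ids(m), t(m$values), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname meth_io
#' @export
read_methylation_tsv <- function(path, stage = "beta") {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "cpg_id")
    stop("methylation TSV must have `cpg_id` as its first column")
  v <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(v) <- d$cpg_id
  meth_matrix(v, stage = stage)
}

#' @rdname meth_io
#' @param x A data frame (cohort table or manifest).
#' @export
write_cohort_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname meth_io
#' @export
read_cohort_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d)) stop("cohort TSV must have a `sample_id` column")
  d
}

#' @rdname meth_io
#' @export
write_manifest_tsv <- write_cohort_tsv

#' @rdname meth_io
#' @export
read_manifest_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = c(cpg_id = "character", chr = "character",
                                        gene = "character"))
  need <- c("cpg_id", "chr", "pos", "gene")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' Read and write gene sets in GMT format with a metadata sidecar
#'
#' GMT is the tab-separated gene-set exchange format: one set per line as
#' `id <TAB> description <TAB> gene1 <TAB> gene2 ...`. Pathway text metadata
#' (name, description, disease, reference titles) that the keyword search
#' scans lives in a sidecar TSV keyed by pathway id; reference titles are
#' pipe-joined in one column.
#'
#' @param ps A `pathway_set` (see [pathway_set()]).
#' @param path File path (`.gmt` or metadata `.tsv`).
#' @return Readers return the parsed object; writers return `path` invisibly.
#' @name gmt_io
NULL

#' Pathway set container
#'
#' @param genes Named list: pathway id -> character vector of gene symbols
#'   (non-empty).
#' @param meta Data frame with columns `id`, `name`, `description`, `disease`,
#'   `reference_titles` (pipe-joined string), one row per pathway.
#' @return An object of class `pathway_set`.
#' @export
pathway_set <- function(genes, meta) {
  if (is.null(names(genes)) || anyDuplicated(names(genes)))
    stop("pathway ids must be unique and named")
  if (any(!vapply(genes, length, 1L)))
    stop("every pathway must have at least one gene")
  need <- c("id", "name", "description", "disease", "reference_titles")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (!setequal(meta$id, names(genes)))
    stop("metadata ids must match gene-set ids")
  meta <- meta[match(names(genes), meta$id), need]
  rownames(meta) <- NULL
  structure(list(genes = genes, meta = meta), class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("<pathway_set> %d pathways, %d distinct genes\n",
              length(x$genes), length(unique(unlist(x$genes)))))
  invisible(x)
}

#' @rdname gmt_io
#' @export
write_gmt <- function(ps, path) {
  stopifnot(inherits(ps, "pathway_set"))
  lines <- vapply(names(ps$genes), function(id) {
    desc <- ps$meta$name[ps$meta$id == id]
    paste(c(id, desc, ps$genes[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gmt_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  genes <- lapply(parts, function(p) p[-(1:2)])
  names(genes) <- ids
  genes
}

#' @rdname gmt_io
#' @export
write_pathway_meta_tsv <- function(ps, path) {
  stopifnot(inherits(ps, "pathway_set"))
  utils::write.table(ps$meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gmt_io
#' @export
read_pathway_meta_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' @rdname gmt_io
#' @param gmt_path,meta_path Paths to the GMT file and its metadata sidecar.
#' @export
read_pathway_set <- function(gmt_path, meta_path) {
  genes <- read_gmt(gmt_path)
  meta <- read_pathway_meta_tsv(meta_path)
  pathway_set(genes, meta)
}

#' Write and read the generator's ground-truth ledger as JSON
#'
#' @param truth A `ground_truth` object from [generate_cohort()].
#' @param path File path.
#' @name truth_io
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname truth_io
#' @export
read_ground_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_paths <- as.data.frame(x$planted_paths, stringsAsFactors = FALSE)
  structure(x, class = "ground_truth")
}
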