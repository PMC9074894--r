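#' Keyword match against pathway text metadata
#'
#' A keyword is related to a pathway if it occurs at least once — case
#' insensitively, as a plain substring — in the pathway's name, description,
#' disease annotation, or any of its reference titles. Substring semantics
#' (rather than whole-word) are used uniformly, so e.g. "neuron" matches
#' "neuronal ceroid lipofuscinosis".
#'
#' @param meta One-row data frame (or list) with fields `name`,
#'   `description`, `disease`, `reference_titles` (reference titles may be a
#'   character vector or a single pipe-joined string).
#' @param keyword Non-empty keyword string.
#' @return `TRUE` if the keyword occurs in any of the four fields.
#' @examples
#' match_keyword(list(name = "", description = "major depression pathway",
#'                    disease = "", reference_titles = ""), "depression")
#' @export
match_keyword <- function(meta, keyword) {
  if (!nzchar(keyword)) stop("`keyword` must be non-empty")
  hay <- tolower(paste(unlist(meta[c("name", "description", "disease",
                                     "reference_titles")]), collapse = "\n"))
  grepl(tolower(keyword), hay, fixed = TRUE)
}

#' Select the CpG universe for one outcome from keyword-matched pathways
#'
#' Step 1 of the cascade: pathways related to at least one keyword of the
#' outcome's profile are selected; their member genes are pooled; genes are
#' intersected with the manifest annotation; and all manifest CpGs on those
#' genes form the outcome's CpG universe (a CpG annotated to several
#' semicolon-separated genes is selected if any of them is selected).
#'
#' @param pathways A [pathway_set()].
#' @param keywords Character vector of keywords for one outcome (a
#'   `KeywordProfile`).
#' @param manifest Manifest data frame (`cpg_id`, `chr`, `pos`, `gene`).
#' @param outcome_id Optional outcome label carried into the result.
#' @return A list of class `cpg_universe`: `outcome`, `pathway_ids`, `genes`
#'   (pathway genes), `genes_annotated` (intersection with manifest genes),
#'   `cpg_ids`, and `counts` (one-row data frame: `n_pathways`, `n_genes`,
#'   `n_genes_annotated`, `n_cpgs`). Zero matched pathways give an empty
#'   universe with a warning; the outcome is then skipped downstream.
#' @export
select_universe <- function(pathways, keywords, manifest, outcome_id = NA_character_) {
  stopifnot(inherits(pathways, "pathway_set"))
  if (!length(keywords)) stop("keyword profile must be non-empty")
  hit <- vapply(seq_len(nrow(pathways$meta)), function(i) {
    any(vapply(keywords, function(k) match_keyword(pathways$meta[i, ], k), TRUE))
  }, TRUE)
  path_ids <- pathways$meta$id[hit]
  if (!length(path_ids))
    warning(sprintf("no pathway matched any keyword for outcome '%s'; empty universe",
                    outcome_id))

  genes <- sort(unique(unlist(pathways$genes[path_ids])))
  gene_lists <- strsplit(manifest$gene, ";", fixed = TRUE)
  manifest_genes <- unique(unlist(gene_lists))
  genes_annot <- intersect(genes, manifest_genes)
  on_gene <- vapply(gene_lists, function(g) any(g %in% genes_annot), TRUE)
  cpgs <- manifest$cpg_id[on_gene]

  structure(list(
    outcome = outcome_id,
    pathway_ids = sort(path_ids),
    genes = genes,
    genes_annotated = sort(genes_annot),
    cpg_ids = sort(cpgs),
    counts = data.frame(outcome = outcome_id,
                        n_pathways = length(path_ids),
                        n_genes = length(genes),
                        n_genes_annotated = length(genes_annot),
                        n_cpgs = length(cpgs),
                        stringsAsFactors = FALSE)
  ), class = "cpg_universe")
}

#' @export
print.cpg_universe <- function(x, ...) {
  cat(sprintf("<cpg_universe> outcome %s: %d pathways, %d genes (%d annotated), %d CpGs\n",
              x$outcome, length(x$pathway_ids), length(x$genes),
              length(x$genes_annotated), length(x$cpg_ids)))
  invisible(x)
}

#' Build universes for every outcome profile
#'
#' @param pathways A [pathway_set()].
#' @param profiles Named list: outcome id -> keyword vector.
#' @param manifest Manifest data frame.
#' @return Named list of `cpg_universe` objects, plus a combined counts table
#'   as attribute `"counts"`.
#' @export
select_universes <- function(pathways, profiles, manifest) {
  out <- lapply(names(profiles), function(oid)
    select_universe(pathways, profiles[[oid]], manifest, outcome_id = oid))
  names(out) <- names(profiles)
  attr(out, "counts") <- do.call(rbind, lapply(out, `[[`, "counts"))
  out
}
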