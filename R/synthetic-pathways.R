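#' Default keyword profiles per outcome
#'
#' One lowercase keyword list per outcome, following the convention used in
#' pathway-driven screens of child neurodevelopment: a shared developmental
#' core ("children", "brain", "neuron") plus outcome-specific terms
#' (intelligence terms for IQ, autism/social terms for social problems,
#' depression terms for internalizing scales, attention/hyperactivity terms
#' for attention and ADHD scales). Outcomes measured at different ages share
#' the same profile.
#'
#' @param outcome_ids Character vector of outcome ids; keywords are chosen by
#'   matching known outcome stems (`iq`, `social`, `internal`, `external`,
#'   `attention`, `adhd`) in the id.
#' @return Named list: outcome id -> character vector of lowercase keywords.
#' @examples
#' default_keyword_profiles(c("iq_age7", "cbcl_social_age7"))
#' @export
default_keyword_profiles <- function(outcome_ids) {
  core <- c("children", "brain", "neuron")
  pick <- function(id) {
    if (grepl("iq", id)) c(core, "intelligent", "intelligence", "iq")
    else if (grepl("internal", id)) c(core, "depressed", "depression", "depressive")
    else if (grepl("external", id)) c(core, "aggression", "aggressive")
    else if (grepl("social", id)) c(core, "autism", "social")
    else if (grepl("attention|adhd", id)) c(core, "attention", "hyperactivity")
    else core
  }
  stats::setNames(lapply(outcome_ids, pick), outcome_ids)
}

# Decoy vocabulary, checked to contain no default keyword as a substring
# (note e.g. "ubiquitin" would contain "iq" and is deliberately absent).
decoy_names <- c(
  "glycolysis and gluconeogenesis", "fatty acid elongation",
  "base excision repair", "homologous recombination",
  "citrate cycle", "pentose phosphate shunt", "sulfur relay system",
  "lysosome membrane transport", "ribosome biogenesis",
  "oxidative phosphorylation", "steroid hormone synthesis",
  "porphyrin metabolism", "glycan degradation", "terpenoid backbone synthesis",
  "peroxisome matrix import", "rna polymerase assembly",
  "spliceosome core complex", "proteasome regulatory particle",
  "folate one-carbon pool", "selenocompound metabolism"
)

#' Generate a synthetic pathway/gene-set fixture
#'
#' Builds a pathway collection over the genes of a generated cohort's
#' manifest, with free-text metadata fields (name, description, disease,
#' reference titles) that the keyword search of the pathway-selection step
#' scans. For every keyword of every outcome's profile there is at least one
#' pathway whose metadata contains the keyword (the field carrying it is
#' rotated across name/description/disease/reference titles so all four are
#' exercised), and the genes of every planted CpG are members of at least one
#' pathway matching a keyword of the planted outcome's profile. Decoy
#' pathways use a vocabulary containing no keyword as a substring.
#'
#' @param config A [sim_config()].
#' @param manifest Manifest data frame from [generate_cohort()] (regenerated
#'   from `config` if omitted).
#' @param profiles Keyword profiles as from [default_keyword_profiles()].
#' @param n_decoys Number of decoy pathways (total pathways >= 20).
#' @return A list: `pathways` (a [pathway_set()]) and `profiles` (the keyword
#'   profiles used).
#' @export
generate_pathway_fixture <- function(config,
                                     manifest = NULL,
                                     profiles = default_keyword_profiles(config$outcomes$id),
                                     n_decoys = 12L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(manifest)) manifest <- generate_cohort(config)$manifest
  set.seed(config$seed + 104729L)  # offset so the fixture is seed-stable

  all_genes <- unique(manifest$gene[manifest$gene != ""])
  planted_genes <- unique(manifest$gene[grepl("^PLGENE", manifest$gene)])
  decoy_pool <- setdiff(all_genes, planted_genes)

  paths <- config$planted_paths
  planted_outcomes <- if (is.null(paths)) character(0) else unique(paths$outcome)

  keywords <- unique(unlist(profiles))
  genes <- list()
  meta <- list()
  fields <- c("name", "description", "disease", "reference_titles")
  blank <- c(name = "pathway", description = "curated gene set",
             disease = "none recorded", reference_titles = "collected references")

  for (i in seq_along(keywords)) {
    kw <- keywords[i]
    id <- sprintf("path%05d", i)
    memb <- sample(decoy_pool, min(8L, length(decoy_pool)))
    # planted genes join every pathway matching a keyword of their outcome
    hit_outcomes <- names(profiles)[vapply(profiles, function(p) kw %in% p, TRUE)]
    if (length(intersect(hit_outcomes, planted_outcomes)) && length(planted_genes))
      memb <- union(planted_genes, memb)
    fld <- fields[(i - 1L) %% 4L + 1L]
    m <- blank
    m[fld] <- sprintf("%s related to %s studies", blank[fld], kw)
    genes[[id]] <- memb
    meta[[id]] <- data.frame(id = id, name = m["name"],
                             description = m["description"],
                             disease = m["disease"],
                             reference_titles = m["reference_titles"],
                             stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_decoys)) {
    id <- sprintf("decoy%04d", j)
    genes[[id]] <- sample(decoy_pool, min(8L, length(decoy_pool)))
    nm <- decoy_names[(j - 1L) %% length(decoy_names) + 1L]
    meta[[id]] <- data.frame(id = id, name = nm,
                             description = paste(nm, "reference set"),
                             disease = "none recorded",
                             reference_titles = paste("notes on", nm),
                             stringsAsFactors = FALSE)
  }
  ps <- pathway_set(genes, do.call(rbind, meta))
  list(pathways = ps, profiles = profiles)
}
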