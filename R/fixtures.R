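# Packaged data: the published 41-gene overlap table.

#' The published AMH-domesticate overlap table
#'
#' The 41 genes with signatures of positive selection in both AMH and at
#' least one of cat, dog, cattle and horse, with the domesticate(s) each
#' overlaps, transcribed from the source publication's main table.
#'
#' @param long if `TRUE` (default) return one row per (gene, species)
#'   pair; otherwise one row per gene with `overlapping_species`
#'   semicolon-joined.
#' @return a data.frame with columns `symbol` and `species`
#'   (long) or `symbol` and `overlapping_species` (wide).
#' @export
table1_overlap <- function(long = TRUE) {
  path <- system.file("extdata", "table1_overlap.tsv",
                      package = "sweepOverlap", mustWork = TRUE)
  wide <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!long) return(wide)
  species <- strsplit(wide$overlapping_species, ";", fixed = TRUE)
  data.frame(
    symbol = rep(wide$symbol, lengths(species)),
    species = unlist(species),
    stringsAsFactors = FALSE
  )
}

#' Gene pools derived from the published overlap table
#'
#' Builds one `gene_pool` per domesticate from the 41-gene overlap table
#' plus an `amh_overlap` pool holding all 41 genes (every listed gene
#' overlaps AMH by construction).
#'
#' @return named list of `gene_pool` objects: `cat`, `dog`, `cattle`,
#'   `horse`, `amh_overlap`.
#' @export
table1_pools <- function() {
  tab <- table1_overlap(long = TRUE)
  out <- list()
  for (sp in sort(unique(tab$species))) {
    out[[sp]] <- gene_pool(sp, tab$symbol[tab$species == sp],
                           species_set = sp)
  }
  out$amh_overlap <- gene_pool("amh_overlap", unique(tab$symbol),
                               species_set = "amh")
  out
}

#' Path to the packaged alias fixture
#'
#' A small table of well-known HGNC symbol renames and aliases
#' (e.g. PPAP2A -> PLPP1) used in examples and tests of alias
#' resolution. It is a demonstration fixture, not a complete
#' nomenclature history.
#'
#' @export
alias_fixture_path <- function() {
  system.file("extdata", "alias_hgnc_renames.tsv",
              package = "sweepOverlap", mustWork = TRUE)
}
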