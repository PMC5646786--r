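# Pairwise and multi-set overlap between gene pools.

#' Pairwise overlap of two gene pools
#'
#' @param poolX,poolY `gene_pool` objects.
#' @return list with `symbols` (sorted intersection) and `v` (its size).
#' @export
pairwise_overlap <- function(poolX, poolY) {
  stopifnot(inherits(poolX, "gene_pool"), inherits(poolY, "gene_pool"))
  ov <- sort(intersect(poolX$symbols, poolY$symbols))
  list(symbols = ov, v = length(ov))
}

#' Map each symbol to the pools containing it
#'
#' @param pools list of `gene_pool` objects with distinct labels.
#' @return named list: canonical symbol -> character vector of pool labels
#'   (sorted); only symbols present in at least one pool appear.
#' @export
overlap_table <- function(pools) {
  labels <- vapply(pools, function(p) p$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate pool labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  univ <- sort(unique(unlist(lapply(pools, function(p) p$symbols))))
  memb <- lapply(univ, function(s) {
    sort(labels[vapply(pools, function(p) s %in% p$symbols, logical(1))])
  })
  stats::setNames(memb, univ)
}

#' Venn decomposition of a set of pools
#'
#' Assigns every symbol in the union of the pools to exactly one cell,
#' keyed by the subset of pool labels containing it; cell counts therefore
#' sum to the size of the union.
#'
#' @param pools list of two or more `gene_pool` objects.
#' @return named integer vector; names are the sorted pool-label subsets
#'   joined with `"&"`, values the number of symbols exactly in that
#'   subset. Cells are ordered alphabetically by key for determinism.
#' @export
venn_decompose <- function(pools) {
  if (length(pools) < 2) stop("venn_decompose() needs at least two pools")
  tab <- overlap_table(pools)
  keys <- vapply(tab, function(lbls) paste(lbls, collapse = "&"), character(1))
  counts <- table(keys)
  out <- stats::setNames(as.integer(counts), names(counts))
  out[order(names(out))]
}

#' Classify convergently selected genes
#'
#' Splits the union of candidate symbols into (i) genes under putative
#' selection in the focal species (AMH) and at least one domesticate —
#' the convergence evidence — and (ii) genes shared by two or more
#' domesticates but absent from the focal pool. A gene shared with
#' several domesticates counts once (gene-level, not gene-by-species).
#'
#' @param amh the focal-species `gene_pool`.
#' @param domesticates list of domesticate `gene_pool`s.
#' @return list with `amh_and_any_dom` and `multi_dom_not_amh`
#'   (sorted character vectors).
#' @export
classify_convergent <- function(amh, domesticates) {
  stopifnot(inherits(amh, "gene_pool"))
  dom_syms <- lapply(domesticates, function(p) p$symbols)
  all_dom <- sort(unique(unlist(dom_syms)))
  n_dom <- vapply(all_dom, function(s) {
    sum(vapply(dom_syms, function(ss) s %in% ss, logical(1)))
  }, integer(1))
  list(
    amh_and_any_dom = sort(intersect(amh$symbols, all_dom)),
    multi_dom_not_amh = sort(setdiff(all_dom[n_dom >= 2], amh$symbols))
  )
}

#' Write an overlap table as TSV
#'
#' Columns `symbol` and `pools` (semicolon-joined, sorted), one row per
#' symbol, rows sorted by symbol.
#'
#' @param tab result of [overlap_table()].
#' @param path output path.
#' @export
write_overlap_tsv <- function(tab, path) {
  df <- data.frame(
    symbol = names(tab),
    pools = vapply(tab, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$symbol), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
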