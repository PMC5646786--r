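# Synteny-based orthology validation.
#
# Two species' candidate lists can share a symbol without sharing a gene:
# paralogs are sometimes given the same name across assemblies on sequence
# identity alone. A shared symbol is accepted as an ortholog only if the
# protein-coding genes flanking it are conserved, in order, across
# species (allowing whole-block inversion and a bounded number of gene
# insertions).

#' Construct a gene neighborhood
#'
#' Ordered flanking protein-coding genes around a focal gene in one
#' species. `upstream` and `downstream` are nearest-first; each side
#' carries between 1 and 8 symbols. Strand is ignored throughout: only
#' gene order enters the synteny comparison.
#'
#' @param species species label.
#' @param focal canonical symbol of the gene of interest.
#' @param upstream,downstream character vectors of flanking symbols,
#'   nearest first.
#' @param chrom optional chromosome/scaffold name.
#' @return a `synteny_neighborhood` object.
#' @export
synteny_neighborhood <- function(species, focal, upstream, downstream,
                                 chrom = NA_character_) {
  focal <- normalize_symbol(focal)
  upstream <- vapply(upstream, normalize_symbol, character(1), USE.NAMES = FALSE)
  downstream <- vapply(downstream, normalize_symbol, character(1), USE.NAMES = FALSE)
  for (side in list(upstream, downstream)) {
    if (length(side) < 1 || length(side) > 8) {
      stop("each side of a neighborhood must carry 1..8 flanking genes")
    }
  }
  flanks <- c(upstream, downstream)
  if (anyDuplicated(flanks)) {
    stop("flanking symbols repeat within the neighborhood of ", focal)
  }
  if (focal %in% flanks) {
    stop("focal gene ", focal, " appears among its own flanks")
  }
  structure(
    list(species = species, focal = focal, upstream = upstream,
         downstream = downstream, chrom = chrom),
    class = "synteny_neighborhood"
  )
}

#' @export
print.synteny_neighborhood <- function(x, ...) {
  cat("<neighborhood> ", x$species, " ",
      paste(rev(x$upstream), collapse = "-"), " [", x$focal, "] ",
      paste(x$downstream, collapse = "-"), "\n", sep = "")
  invisible(x)
}

# Genomic-order sequence: upstream reversed, focal, downstream.
neighborhood_sequence <- function(nb) {
  c(rev(nb$upstream), nb$focal, nb$downstream)
}

#' Reverse the orientation of a neighborhood
#'
#' Whole-block reversal (as produced by an inversion spanning the block
#' or by an assembly reported on the opposite strand): upstream and
#' downstream swap roles.
#'
#' @param nb a `synteny_neighborhood`.
#' @export
reverse_neighborhood <- function(nb) {
  synteny_neighborhood(nb$species, nb$focal,
                       upstream = nb$downstream, downstream = nb$upstream,
                       chrom = nb$chrom)
}

# All shared symbols (plus the focal anchor) must appear in the same
# relative order in both genomic-order sequences, and no more than
# max_insertions non-shared genes may sit between consecutive shared ones.
ordered_consistently <- function(seqA, seqB, keep, max_insertions) {
  idxA <- which(seqA %in% keep)
  idxB <- which(seqB %in% keep)
  identical(seqA[idxA], seqB[idxB]) &&
    all(diff(idxA) - 1L <= max_insertions) &&
    all(diff(idxB) - 1L <= max_insertions)
}

#' Compare two neighborhoods of the same focal gene
#'
#' Counts flanking symbols common to both neighborhoods and tests whether
#' they occur in a consistent relative order, in the given orientation or
#' with one block fully reversed. Up to `max_insertions` unshared genes
#' are tolerated between consecutive shared flanks (gene insertions and
#' local duplications routinely interrupt otherwise clear synteny).
#' The block is called conserved when at least `min_shared` flanks are
#' shared and their order is consistent.
#'
#' @param nbA,nbB `synteny_neighborhood`s with the same focal symbol.
#' @param min_shared minimum number of shared flanking genes (default 4,
#'   half of the canonical 4+4 flank set).
#' @param max_insertions maximum unshared genes tolerated between
#'   consecutive shared flanks (default 1).
#' @return a `synteny_verdict`: list with `focal`, `species_pair`,
#'   `shared_flanks`, `order_consistent`, `conserved`.
#' @export
compare_neighborhoods <- function(nbA, nbB, min_shared = 4, max_insertions = 1) {
  stopifnot(inherits(nbA, "synteny_neighborhood"),
            inherits(nbB, "synteny_neighborhood"))
  if (!identical(nbA$focal, nbB$focal)) {
    stop("neighborhoods have different focal genes: ",
         nbA$focal, " vs ", nbB$focal)
  }
  flanksA <- c(nbA$upstream, nbA$downstream)
  flanksB <- c(nbB$upstream, nbB$downstream)
  shared <- intersect(flanksA, flanksB)
  seqA <- neighborhood_sequence(nbA)
  seqB <- neighborhood_sequence(nbB)
  keep <- c(shared, nbA$focal)
  order_ok <- length(shared) > 0 &&
    (ordered_consistently(seqA, seqB, keep, max_insertions) ||
       ordered_consistently(seqA, rev(seqB), keep, max_insertions))
  structure(
    list(focal = nbA$focal,
         species_pair = c(nbA$species, nbB$species),
         shared_flanks = length(shared),
         order_consistent = order_ok,
         conserved = length(shared) >= min_shared && order_ok),
    class = "synteny_verdict"
  )
}

#' @export
print.synteny_verdict <- function(x, ...) {
  cat("<synteny> ", x$focal, " ", x$species_pair[1], " vs ",
      x$species_pair[2], ": shared=", x$shared_flanks,
      ", order=", x$order_consistent,
      " -> ", if (x$conserved) "conserved" else "NOT conserved",
      "\n", sep = "")
  invisible(x)
}

#' Confirm orthology of a focal gene across species
#'
#' Runs pairwise neighborhood comparisons of every species against a
#' reference species (`amh` when present, otherwise the first listed) and
#' conjoins the verdicts.
#'
#' @param neighborhoods list of `synteny_neighborhood`s (>= 2), one per
#'   species, all with the same focal symbol.
#' @inheritParams compare_neighborhoods
#' @return list with `conserved_in_all_pairs` (logical) and `verdicts`
#'   (list of `synteny_verdict`).
#' @export
confirm_orthology <- function(neighborhoods, min_shared = 4, max_insertions = 1) {
  if (length(neighborhoods) < 2) {
    stop("orthology confirmation needs neighborhoods from at least 2 species")
  }
  species <- vapply(neighborhoods, function(nb) nb$species, character(1))
  ref_i <- if ("amh" %in% species) which(species == "amh")[1] else 1L
  ref <- neighborhoods[[ref_i]]
  verdicts <- lapply(neighborhoods[-ref_i], function(nb) {
    compare_neighborhoods(ref, nb, min_shared, max_insertions)
  })
  list(
    conserved_in_all_pairs = all(vapply(verdicts, function(v) v$conserved,
                                        logical(1))),
    verdicts = verdicts
  )
}

#' Read neighborhoods from TSV
#'
#' Dialect: columns `species`, `focal`, `side` (`up`/`down`), `rank`
#' (1 = nearest), `symbol`, `chrom`; one row per flanking gene.
#'
#' @param path file path.
#' @return list of `synteny_neighborhood`, one per (species, focal) pair.
#' @export
read_neighborhood_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("species", "focal", "side", "rank", "symbol")) {
    if (!col %in% names(tab)) {
      stop("neighborhood file ", path, " is missing required column: ", col)
    }
  }
  if (!all(tab$side %in% c("up", "down"))) {
    stop("side column must be 'up' or 'down'")
  }
  if (!"chrom" %in% names(tab)) tab$chrom <- NA_character_
  groups <- split(tab, paste(tab$species, tab$focal, sep = "\r"))
  nbs <- lapply(groups, function(g) {
    up <- g[g$side == "up", ]
    dn <- g[g$side == "down", ]
    synteny_neighborhood(
      species = g$species[1], focal = g$focal[1],
      upstream = up$symbol[order(up$rank)],
      downstream = dn$symbol[order(dn$rank)],
      chrom = as.character(g$chrom[1])
    )
  })
  unname(nbs)
}

#' Write neighborhoods as TSV
#'
#' Inverse of [read_neighborhood_tsv()].
#'
#' @param neighborhoods list of `synteny_neighborhood`.
#' @param path output path.
#' @export
write_neighborhood_tsv <- function(neighborhoods, path) {
  rows <- lapply(neighborhoods, function(nb) {
    data.frame(
      species = nb$species, focal = nb$focal,
      side = c(rep("up", length(nb$upstream)),
               rep("down", length(nb$downstream))),
      rank = c(seq_along(nb$upstream), seq_along(nb$downstream)),
      symbol = c(nb$upstream, nb$downstream),
      chrom = nb$chrom, stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a neighborhood from a GFF3 annotation
#'
#' Helper for building neighborhoods from a standard GFF3 file: selects
#' protein-coding gene features, orders them by start coordinate within
#' each sequence region, and takes up to `flanks_per_side` genes on each
#' side of the focal gene. Requires the `rtracklayer` package.
#'
#' @param path GFF3 file.
#' @param focal focal gene symbol (matched against the `Name` attribute).
#' @param species species label for the resulting neighborhood.
#' @param flanks_per_side flanks to take on each side (default 4).
#' @return a `synteny_neighborhood`.
#' @export
neighborhood_from_gff <- function(path, focal, species, flanks_per_side = 4) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("neighborhood_from_gff() requires the rtracklayer package")
  }
  focal <- normalize_symbol(focal)
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr <- gr[gr$type == "gene", , drop = FALSE]
  biotype_col <- intersect(c("gene_biotype", "biotype"), names(gr))
  if (length(biotype_col) > 0) {
    bt <- gr[[biotype_col[1]]]
    gr <- gr[!is.na(bt) & bt == "protein_coding", , drop = FALSE]
  }
  gr$symbol <- toupper(as.character(gr$Name))
  hit <- gr[gr$symbol == focal, , drop = FALSE]
  if (nrow(hit) != 1) {
    stop("focal gene ", focal, " matched ", nrow(hit),
         " protein-coding gene(s) in ", path)
  }
  chrom <- as.character(hit$seqnames)
  on_chrom <- gr[as.character(gr$seqnames) == chrom, , drop = FALSE]
  on_chrom <- on_chrom[order(on_chrom$start), , drop = FALSE]
  pos <- which(on_chrom$symbol == focal)
  before <- rev(on_chrom$symbol[seq_len(pos - 1)])   # nearest first
  after <- on_chrom$symbol[seq(pos + 1, length.out = nrow(on_chrom) - pos)]
  synteny_neighborhood(
    species = species, focal = focal,
    upstream = utils::head(before, flanks_per_side),
    downstream = utils::head(after, flanks_per_side),
    chrom = chrom
  )
}
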