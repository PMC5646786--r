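# Gene-list ingestion and harmonization.
#
# Published sweep screens print gene symbols in whatever nomenclature the
# source assembly used. Records are harmonized to canonical uppercase
# symbols (optionally through an alias table) before any set arithmetic.

GENELIST_COLUMNS <- c("species", "comparison", "source", "symbol_raw", "gene_class")

#' Construct a table of candidate-gene records
#'
#' A gene record carries a symbol as printed in its source
#' (`symbol_raw`), the harmonized canonical symbol (`symbol`), the species
#' whose sweep screen reported it, a free-text `comparison` label (which
#' genomes were contrasted), a citation key, and a controlled gene class.
#'
#' @param species character vector of species labels; must be drawn from
#'   [SPECIES_LABELS].
#' @param symbol_raw character vector of symbols as printed in the source.
#' @param comparison free-text label of the selection screen.
#' @param source citation key for the originating study.
#' @param gene_class one of [GENE_CLASSES]; defaults to `"unknown"` because
#'   most published candidate tables do not annotate biotype.
#' @param aliases optional alias table from [read_alias_tsv()] used to
#'   canonicalize symbols.
#' @return a `data.frame` with columns `species`, `comparison`, `source`,
#'   `symbol_raw`, `gene_class`, `symbol`.
#' @export
gene_records <- function(species, symbol_raw, comparison = "", source = "",
                         gene_class = "unknown", aliases = NULL) {
  n <- length(symbol_raw)
  rec <- data.frame(
    species = rep_len(as.character(species), n),
    comparison = rep_len(as.character(comparison), n),
    source = rep_len(as.character(source), n),
    symbol_raw = as.character(symbol_raw),
    gene_class = rep_len(as.character(gene_class), n),
    stringsAsFactors = FALSE
  )
  validate_gene_records(rec)
  rec$symbol <- vapply(rec$symbol_raw, normalize_symbol, character(1),
                       aliases = aliases, USE.NAMES = FALSE)
  rec
}

validate_gene_records <- function(rec) {
  bad_sp <- setdiff(unique(rec$species), SPECIES_LABELS)
  if (length(bad_sp) > 0) {
    stop("unknown species label(s): ", paste(bad_sp, collapse = ", "),
         "; allowed: ", paste(SPECIES_LABELS, collapse = ", "))
  }
  bad_cl <- setdiff(unique(rec$gene_class), GENE_CLASSES)
  if (length(bad_cl) > 0) {
    stop("unknown gene_class label(s): ", paste(bad_cl, collapse = ", "),
         "; allowed: ", paste(GENE_CLASSES, collapse = ", "))
  }
  invisible(rec)
}

#' Canonicalize a gene symbol
#'
#' Canonicalization is deliberately minimal and auditable: strip
#' surrounding whitespace, fold to uppercase, then apply one alias-table
#' lookup. No Greek-letter or hyphen rewriting is attempted; ambiguous
#' nomenclature is resolved only through an explicit, versioned alias
#' table.
#'
#' @param raw a single symbol as printed in a source table.
#' @param aliases optional alias table ([read_alias_tsv()] /
#'   [alias_table()]); keys are matched case-insensitively.
#' @return the canonical uppercase symbol.
#' @examples
#' normalize_symbol("Braf")            # "BRAF"
#' normalize_symbol(" GRIK3 ")         # "GRIK3"
#' @export
normalize_symbol <- function(raw, aliases = NULL) {
  if (length(raw) != 1L || is.na(raw)) {
    stop("normalize_symbol() expects a single non-NA symbol")
  }
  sym <- toupper(trimws(raw))
  if (!nzchar(sym)) {
    stop("empty or whitespace-only gene symbol in input row: ",
         deparse(raw))
  }
  if (!is.null(aliases)) {
    hit <- match(sym, names(aliases))
    if (!is.na(hit)) sym <- unname(aliases[[hit]])
  }
  sym
}

#' Build an alias table
#'
#' The mapping is functional (each raw variant maps to exactly one
#' canonical symbol) and canonical targets are fixed points: a target may
#' not itself appear as a key with a different value.
#'
#' @param raw character vector of symbol variants.
#' @param canonical character vector of canonical targets, same length.
#' @return a named character vector, names uppercase variants, values
#'   uppercase canonical symbols.
#' @export
alias_table <- function(raw, canonical) {
  stopifnot(length(raw) == length(canonical))
  keys <- toupper(trimws(raw))
  vals <- toupper(trimws(canonical))
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    stop("alias table maps variant(s) to multiple targets: ",
         paste(dup, collapse = ", "))
  }
  clash <- intersect(vals, keys)
  clash <- clash[vals[match(clash, keys)] != clash]
  if (length(clash) > 0) {
    stop("canonical symbol(s) are not fixed points of the alias map: ",
         paste(clash, collapse = ", "))
  }
  stats::setNames(vals, keys)
}

#' Read an alias table from TSV
#'
#' Expects a header row with columns `raw` and `canonical`.
#'
#' @param path path to a tab-separated file.
#' @return alias table as from [alias_table()].
#' @export
read_alias_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("raw", "canonical")) {
    if (!col %in% names(tab)) {
      stop("alias file ", path, " is missing required column: ", col)
    }
  }
  alias_table(tab$raw, tab$canonical)
}

#' Recompute canonical symbols for raw records
#'
#' Adds (or replaces) the `symbol` column of a raw 5-column gene-list
#' table by normalizing `symbol_raw`, optionally through an alias table.
#'
#' @param records data.frame with at least the columns of the gene-list
#'   TSV dialect.
#' @param aliases optional alias table.
#' @return the records with a canonical `symbol` column.
#' @export
harmonize_records <- function(records, aliases = NULL) {
  validate_gene_records(records)
  records$symbol <- vapply(records$symbol_raw, normalize_symbol,
                           character(1), aliases = aliases,
                           USE.NAMES = FALSE)
  records
}

#' Drop non-coding contaminant records
#'
#' Published candidate tables often list miRNAs, antisense transcripts and
#' other non-coding products alongside protein-coding genes; the overlap
#' universe is protein-coding, so these are removed. Records with class
#' `unknown` are retained (sources rarely annotate biotype) and their
#' count is reported in a warning-style message.
#'
#' @param records gene-record `data.frame` from [gene_records()] or
#'   [read_genelist_tsv()].
#' @param quiet suppress the unknown-class message.
#' @return the records with `gene_class` `protein_coding` or `unknown`.
#' @export
filter_noncoding <- function(records, quiet = FALSE) {
  if (nrow(records) == 0) return(records)
  keep <- records$gene_class %in% c("protein_coding", "unknown")
  out <- records[keep, , drop = FALSE]
  n_unknown <- sum(out$gene_class == "unknown")
  if (!quiet && n_unknown > 0) {
    message(n_unknown, " record(s) with gene_class 'unknown' retained; ",
            sum(!keep), " non-coding record(s) removed")
  }
  rownames(out) <- NULL
  out
}

#' Build a deduplicated gene pool
#'
#' A pool is the set-union of canonical symbols across one or more record
#' lists; duplicates within and across lists collapse, so pooling is
#' order- and repetition-invariant.
#'
#' @param label pool label (e.g. `"dom"` for a pooled domesticate set).
#' @param ... one or more gene-record `data.frame`s, or a single list of
#'   them.
#' @return a `gene_pool` object: list with `label`, `species_set`,
#'   `symbols` (sorted character vector) and `size`.
#' @export
build_pool <- function(label, ...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1]]) &&
      !is.data.frame(lists[[1]])) {
    lists <- lists[[1]]
  }
  if (length(lists) == 0) stop("build_pool() needs at least one record list")
  symbols <- sort(unique(unlist(lapply(lists, function(r) r$symbol),
                                use.names = FALSE)))
  species <- sort(unique(unlist(lapply(lists, function(r) r$species),
                                use.names = FALSE)))
  new_gene_pool(label, species, symbols)
}

new_gene_pool <- function(label, species_set, symbols) {
  symbols <- as.character(symbols)
  stopifnot(!anyDuplicated(symbols), all(nzchar(symbols)))
  structure(
    list(label = label, species_set = species_set,
         symbols = symbols, size = length(symbols)),
    class = "gene_pool"
  )
}

#' Construct a pool directly from symbols
#'
#' Convenience constructor for size-driven analyses and tests; symbols are
#' normalized and deduplicated.
#'
#' @param label pool label.
#' @param symbols character vector of symbols.
#' @param species_set species labels covered by the pool.
#' @export
gene_pool <- function(label, symbols, species_set = character(0)) {
  symbols <- sort(unique(vapply(symbols, normalize_symbol, character(1),
                                USE.NAMES = FALSE)))
  new_gene_pool(label, species_set, symbols)
}

#' @export
print.gene_pool <- function(x, ...) {
  cat("<gene_pool> ", x$label, ": ", x$size, " symbols",
      if (length(x$species_set) > 0)
        paste0(" [", paste(x$species_set, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Read a gene-list TSV
#'
#' Dialect: UTF-8, tab-separated, header row, columns
#' `species`, `comparison`, `source`, `symbol_raw` and optionally
#' `gene_class` (defaulting to `unknown`).
#'
#' @param path file path.
#' @param aliases optional alias table applied during normalization.
#' @return gene-record `data.frame` (see [gene_records()]).
#' @export
read_genelist_tsv <- function(path, aliases = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- setdiff(GENELIST_COLUMNS, "gene_class")
  for (col in required) {
    if (!col %in% names(tab)) {
      stop("gene list ", path, " is missing required column: ", col)
    }
  }
  if (!"gene_class" %in% names(tab)) tab$gene_class <- "unknown"
  gene_records(species = tab$species, symbol_raw = tab$symbol_raw,
               comparison = tab$comparison, source = tab$source,
               gene_class = tab$gene_class, aliases = aliases)
}

#' Write gene records as TSV
#'
#' Writes the five-column dialect read by [read_genelist_tsv()];
#' `write` then `read` reproduces the records exactly.
#'
#' @param records gene-record `data.frame`.
#' @param path output path.
#' @export
write_genelist_tsv <- function(records, path) {
  utils::write.table(records[, GENELIST_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
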