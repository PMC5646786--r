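# Synthetic data with the statistical structure the analysis assumes.
#
# The generator models exactly the level at which the overlap statistics
# operate: gene-list membership. Pools are uniform draws without
# replacement from a universe of synthetic symbols, optionally with a
# planted shared component (the alternative hypothesis), alias-spelling
# noise, and non-coding contaminant records. No sweep detection or
# sequence evolution is simulated.

#' Generate synthetic candidate-gene pools
#'
#' Symbols are drawn uniformly without replacement from a universe of
#' `universe_n` synthetic identifiers (`G00001`, `G00002`, ...; disjoint
#' from real gene symbols so fixtures cannot cross-contaminate).
#' `planted_overlap` symbols are deterministically forced into every
#' designated pool — planting is exact, not probabilistic, so power
#' statements are crisp. Noise is applied after membership is fixed:
#' a fraction `alias_noise_rate` of records is emitted under a variant
#' spelling (resolvable through the returned alias table), and a
#' fraction `noncoding_rate` of extra non-coding contaminant records is
#' appended. The returned truth table records the intended memberships,
#' so tests never re-derive ground truth from generator internals.
#'
#' @param universe_n number of symbols in the synthetic universe.
#' @param pool_sizes named integer vector: intended (deduplicated) size
#'   of each pool, before noise.
#' @param planted_overlap number of symbols forced into all designated
#'   pools; must not exceed the smallest designated pool.
#' @param planted_pools labels of pools receiving the planted symbols
#'   (default: all).
#' @param alias_noise_rate fraction of records emitted under a variant
#'   spelling (a `-V1` suffixed raw symbol mapped back by the alias
#'   table).
#' @param noncoding_rate fraction of contaminant records (miRNA /
#'   antisense / other non-coding) appended per pool.
#' @param seed integer RNG seed.
#' @return list with `records` (named list of raw 5-column gene-list
#'   data.frames, as a source table would arrive: no `symbol` column),
#'   `truth` (data.frame `symbol`, `pool`, `planted`), and `aliases`
#'   (alias table resolving the variant spellings).
#' @export
generate_pools <- function(universe_n, pool_sizes, planted_overlap = 0,
                           planted_pools = names(pool_sizes),
                           alias_noise_rate = 0, noncoding_rate = 0, seed) {
  stopifnot(length(pool_sizes) >= 1, !is.null(names(pool_sizes)),
            all(nzchar(names(pool_sizes))))
  if (any(pool_sizes > universe_n)) {
    stop("pool size exceeds the universe size")
  }
  if (alias_noise_rate < 0 || alias_noise_rate > 1 ||
      noncoding_rate < 0 || noncoding_rate > 1) {
    stop("noise rates must lie in [0, 1]")
  }
  if (planted_overlap > min(pool_sizes[planted_pools])) {
    stop("planted_overlap exceeds the smallest designated pool")
  }
  set.seed(as.integer(seed))
  width <- max(5, nchar(universe_n))
  universe <- sprintf("G%0*d", width, seq_len(universe_n))
  planted <- if (planted_overlap > 0) sample(universe, planted_overlap)
             else character(0)

  truth <- list()
  records <- list()
  alias_raw <- character(0)
  alias_canon <- character(0)
  nc_counter <- 0L
  for (lbl in names(pool_sizes)) {
    size <- pool_sizes[[lbl]]
    if (lbl %in% planted_pools) {
      rest <- sample(setdiff(universe, planted), size - planted_overlap)
      members <- c(planted, rest)
      is_planted <- c(rep(TRUE, length(planted)), rep(FALSE, length(rest)))
    } else {
      members <- sample(setdiff(universe, planted), size)
      is_planted <- rep(FALSE, size)
    }
    truth[[lbl]] <- data.frame(symbol = members, pool = lbl,
                               planted = is_planted,
                               stringsAsFactors = FALSE)
    raw <- members
    n_alias <- round(alias_noise_rate * size)
    if (n_alias > 0) {
      idx <- sample(size, n_alias)
      raw[idx] <- paste0(members[idx], "-V1")
      alias_raw <- c(alias_raw, raw[idx])
      alias_canon <- c(alias_canon, members[idx])
    }
    species <- if (lbl %in% SPECIES_LABELS) lbl else "other"
    df <- data.frame(
      species = species, comparison = "synthetic null",
      source = "generate_pools", symbol_raw = raw,
      gene_class = "protein_coding", stringsAsFactors = FALSE
    )
    n_nc <- round(noncoding_rate * size)
    if (n_nc > 0) {
      nc_sym <- sprintf("XNC%05d", nc_counter + seq_len(n_nc))
      nc_counter <- nc_counter + n_nc
      df <- rbind(df, data.frame(
        species = species, comparison = "synthetic null",
        source = "generate_pools", symbol_raw = nc_sym,
        gene_class = sample(c("miRNA", "antisense", "other_noncoding"),
                            n_nc, replace = TRUE),
        stringsAsFactors = FALSE
      ))
    }
    records[[lbl]] <- df
  }
  dup <- duplicated(alias_raw)
  list(
    records = records,
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
    aliases = if (length(alias_raw) > 0) {
      alias_table(alias_raw[!dup], alias_canon[!dup])
    } else {
      alias_table(character(0), character(0))
    }
  )
}

#' Generate gene neighborhoods with a planted rearrangement
#'
#' Builds one neighborhood of `flanks_per_side` synthetic flanking genes
#' per side around a focal symbol, replicates it across species, then
#' applies the named rearrangement to the last species:
#' \describe{
#'   \item{none}{all neighborhoods identical.}
#'   \item{insertion}{one novel gene inserted among the flanks of one
#'     side (tolerated by the default `max_insertions = 1`).}
#'   \item{inversion}{whole-block reversal (orientation-free comparison
#'     must still call it conserved).}
#'   \item{shuffle}{random permutation of all flanks, redrawn until it is
#'     neither the identity nor the full reversal (breaks order).}
#'   \item{translocation}{all flanks replaced by fresh symbols (the focal
#'     symbol sits in an unrelated neighborhood).}
#' }
#'
#' @param focal focal symbol (default a synthetic identifier).
#' @param species_list species labels, one neighborhood each.
#' @param flanks_per_side flanks per side, 1..8.
#' @param rearrangement one of `"none"`, `"insertion"`, `"inversion"`,
#'   `"shuffle"`, `"translocation"`.
#' @param seed integer RNG seed.
#' @return list with `neighborhoods` (list of `synteny_neighborhood`),
#'   `altered_species`, and `truth_conserved` — the expected
#'   [confirm_orthology()] outcome under default thresholds.
#' @export
generate_neighborhoods <- function(focal = "GFOCAL",
                                   species_list = c("amh", "cattle", "horse",
                                                    "dog", "cat"),
                                   flanks_per_side = 4,
                                   rearrangement = c("none", "insertion",
                                                     "inversion", "shuffle",
                                                     "translocation"),
                                   seed = 1) {
  rearrangement <- match.arg(rearrangement)
  if (flanks_per_side < 1 || flanks_per_side > 8) {
    stop("flanks_per_side must lie in 1..8")
  }
  set.seed(as.integer(seed))
  f <- flanks_per_side
  up <- sprintf("GFLU%02d", seq_len(f))     # nearest first
  dn <- sprintf("GFLD%02d", seq_len(f))
  base <- lapply(species_list, function(sp) {
    synteny_neighborhood(sp, focal, upstream = up, downstream = dn)
  })
  k <- length(base)
  truth <- rearrangement %in% c("none", "insertion", "inversion")
  alt <- base[[k]]
  if (rearrangement == "insertion") {
    side <- if (f < 8) sample(c("upstream", "downstream"), 1) else
      stop("insertion needs a side with fewer than 8 flanks")
    pos <- sample(f + 1, 1)
    alt[[side]] <- append(alt[[side]], "GINS01", after = pos - 1)
    alt <- synteny_neighborhood(alt$species, alt$focal,
                                alt$upstream, alt$downstream)
  } else if (rearrangement == "inversion") {
    alt <- reverse_neighborhood(alt)
  } else if (rearrangement == "shuffle") {
    if (f < 2) stop("shuffle needs at least 2 flanks per side")
    seq0 <- c(rev(up), dn)                  # flanks in genomic order
    repeat {
      perm <- sample(seq0)
      if (!identical(perm, seq0) && !identical(perm, rev(seq0))) break
    }
    alt <- synteny_neighborhood(alt$species, focal,
                                upstream = rev(perm[seq_len(f)]),
                                downstream = perm[f + seq_len(f)])
  } else if (rearrangement == "translocation") {
    alt <- synteny_neighborhood(alt$species, focal,
                                upstream = sprintf("GTRU%02d", seq_len(f)),
                                downstream = sprintf("GTRD%02d", seq_len(f)))
  }
  base[[k]] <- alt
  list(neighborhoods = base,
       altered_species = species_list[k],
       truth_conserved = truth)
}
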