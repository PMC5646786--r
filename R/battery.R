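# Batteries of overlap comparisons.
#
# A battery is a configured list of comparisons, each either pool-driven
# (two gene pools whose overlap v is computed here) or size-driven
# (a, b, v quoted from a publication whose underlying lists are not
# machine-readable). Every row gets the exact tail probability and,
# optionally, a seeded Monte Carlo estimate.

#' Run a battery of intersection tests
#'
#' @param config a list (or path to a YAML file, see
#'   [read_battery_config()]) with fields:
#'   \describe{
#'     \item{universe_n}{default universe size for all rows.}
#'     \item{mc_reps}{default Monte Carlo replicates; 0 disables MC.}
#'     \item{seed}{base RNG seed; row i uses `seed + i` unless the row
#'       sets its own.}
#'     \item{comparisons}{list of rows. A row has `label`, optionally
#'       `n`, `mc_reps`, `seed` overrides, and either sizes `a`, `b`,
#'       `v`, or pools `poolX`, `poolY` (`gene_pool` objects or gene-list
#'       TSV paths) from which `a`, `b`, `v` are computed.}
#'   }
#' @param alpha significance thresholds to report (default 0.05 and
#'   0.01, the two conventional levels).
#' @return a `battery_result`: list with `rows` (data.frame: `label`,
#'   `n`, `a`, `b`, `v`, `p_exact`, `mc_fraction`, `mc_ci_lo`,
#'   `mc_ci_hi`, `mc_reps`, `seed`, `significant_at`) and `config`.
#' @export
run_battery <- function(config, alpha = c(0.05, 0.01)) {
  if (is.character(config) && length(config) == 1) {
    config <- read_battery_config(config)
  }
  if (is.null(config$comparisons)) stop("config has no comparisons")
  if (length(config$comparisons) == 0) {
    empty <- data.frame(
      label = character(0), n = numeric(0), a = numeric(0), b = numeric(0),
      v = numeric(0), p_exact = numeric(0), mc_fraction = numeric(0),
      mc_ci_lo = numeric(0), mc_ci_hi = numeric(0), mc_reps = integer(0),
      seed = integer(0), significant_at = character(0),
      stringsAsFactors = FALSE
    )
    return(structure(list(rows = empty, config = config),
                     class = "battery_result"))
  }
  default_n <- config$universe_n %||% 19500
  default_reps <- config$mc_reps %||% 0
  base_seed <- config$seed %||% 1
  rows <- lapply(seq_along(config$comparisons), function(i) {
    cmp <- config$comparisons[[i]]
    n <- cmp$n %||% default_n
    reps <- cmp$mc_reps %||% default_reps
    seed <- cmp$seed %||% (base_seed + i)
    has_pools <- !is.null(cmp$poolX) || !is.null(cmp$poolY)
    if (has_pools) {
      px <- as_pool(cmp$poolX, "poolX")
      py <- as_pool(cmp$poolY, "poolY")
      a <- px$size
      b <- py$size
      v <- pairwise_overlap(px, py)$v
    } else {
      if (is.null(cmp$a) || is.null(cmp$b) || is.null(cmp$v)) {
        stop("size-driven comparison '", cmp$label,
             "' needs a, b and v (nothing to test otherwise)")
      }
      a <- cmp$a; b <- cmp$b; v <- cmp$v
    }
    p <- intersection_tail_ge(n, a, b, v)
    mc_f <- mc_lo <- mc_hi <- NA_real_
    if (reps > 0) {
      mc <- estimate_tail(n, a, b, v, reps = reps, seed = seed)
      mc_f <- mc$fraction; mc_lo <- mc$ci95[1]; mc_hi <- mc$ci95[2]
    }
    data.frame(
      label = cmp$label %||% paste0("cmp", i),
      n = n, a = a, b = b, v = v, p_exact = p,
      mc_fraction = mc_f, mc_ci_lo = mc_lo, mc_ci_hi = mc_hi,
      mc_reps = as.integer(reps), seed = as.integer(seed),
      significant_at = paste(alpha[p < alpha], collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  structure(list(rows = do.call(rbind, rows), config = config),
            class = "battery_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

as_pool <- function(x, what) {
  if (inherits(x, "gene_pool")) return(x)
  if (is.character(x) && length(x) == 1) {
    return(build_pool(x, filter_noncoding(read_genelist_tsv(x), quiet = TRUE)))
  }
  stop(what, " must be a gene_pool or a gene-list TSV path")
}

#' Read a battery configuration from YAML
#'
#' @param path YAML file with the structure documented in
#'   [run_battery()].
#' @export
read_battery_config <- function(path) {
  yaml::read_yaml(path)
}

#' Path to the packaged default battery configuration
#'
#' Encodes the published comparisons: pooled domesticates vs the AMH
#' pool (691/742/41), the per-source AMH subsets (108/9 and 419/24), the
#' great-ape controls (chimp 415/16, orangutan 500/20, gorilla 426/12)
#' and the wolf and wisent wild-relative controls.
#'
#' @export
default_battery_config <- function() {
  system.file("extdata", "configs", "paper_battery.yaml",
              package = "sweepOverlap", mustWork = TRUE)
}

#' @export
print.battery_result <- function(x, ...) {
  cat("<battery_result> ", nrow(x$rows), " comparison(s)\n", sep = "")
  print(x$rows[, c("label", "n", "a", "b", "v", "p_exact", "mc_fraction",
                   "significant_at")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Render a battery report
#'
#' Deterministic TSV or JSON rendering: rows in configuration order,
#' floating-point columns formatted to 4 significant digits, so the same
#' config and seed always produce byte-identical reports.
#'
#' @param result a `battery_result`.
#' @param format `"tsv"` or `"json"`.
#' @param path optional output file; when `NULL` the text is returned.
#' @export
render_report <- function(result, format = c("tsv", "json"), path = NULL) {
  stopifnot(inherits(result, "battery_result"))
  format <- match.arg(format)
  rows <- result$rows
  for (col in c("p_exact", "mc_fraction", "mc_ci_lo", "mc_ci_hi")) {
    rows[[col]] <- signif(rows[[col]], 4)
  }
  txt <- if (format == "tsv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paste0(paste(out, collapse = "\n"), "\n")
  } else {
    jsonlite::toJSON(rows, dataframe = "rows", na = "null",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(path)) {
    writeLines(txt, path, sep = if (format == "tsv") "" else "\n")
    invisible(path)
  } else {
    txt
  }
}
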