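# File formats: a tab-delimited expression-matrix dialect (genes in rows,
# one column per measurement, header "time:replicate[:strain]") and TSV
# result tables.

#' Read a tab-delimited expression matrix
#'
#' The first column holds gene ids; every other column is one measurement
#' labelled `time:replicate` or `time:replicate:strain` (e.g. `3:2` or
#' `3:2:dYAP1`). Empty cells and `NA` are missing values. Genes missing
#' more than `max_missing` of their measurements are dropped with a
#' warning.
#'
#' @param path File path.
#' @param max_missing Maximal tolerated fraction of missing values per
#'   gene.
#' @return A [as_tvn_expr()] dataset.
#' @export
read_expression <- function(path, max_missing = 0.2) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  if (ncol(raw) < 2) abort("expression file needs a gene column plus measurements",
                           class = "tvn_io_error")
  genes <- as.character(raw[[1]])
  if (any(duplicated(genes))) {
    abort(sprintf("duplicate gene id at line %d",
                  which(duplicated(genes))[1] + 1L), class = "tvn_io_error")
  }
  hdr <- names(raw)[-1]
  parts <- strsplit(hdr, ":", fixed = TRUE)
  bad <- which(!lengths(parts) %in% c(2L, 3L))
  if (length(bad)) {
    abort(sprintf("unparseable header column '%s' (expect time:replicate[:strain])",
                  hdr[bad[1]]), class = "tvn_io_error")
  }
  meta <- tibble::tibble(
    time = as.integer(vapply(parts, `[[`, "", 1)),
    replicate = as.integer(vapply(parts, `[[`, "", 2)),
    strain = vapply(parts, function(x) if (length(x) == 3) x[3] else "WT", "")
  )
  if (any(is.na(meta$time)) || any(is.na(meta$replicate))) {
    abort("non-integer time or replicate in header", class = "tvn_io_error")
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  frac_missing <- rowMeans(is.na(vals))
  drop <- frac_missing > max_missing
  if (any(drop)) {
    warn(sprintf("dropping %d gene(s) with more than %.0f%% missing values: %s",
                 sum(drop), 100 * max_missing,
                 paste(head(genes[drop], 5), collapse = ", ")))
    vals <- vals[!drop, , drop = FALSE]
    genes <- genes[!drop]
  }
  long <- tibble::tibble(
    gene = rep(genes, times = nrow(meta)),
    time = rep(meta$time, each = length(genes)),
    replicate = rep(meta$replicate, each = length(genes)),
    strain = rep(meta$strain, each = length(genes)),
    value = as.numeric(vals)
  )
  as_tvn_expr(long)
}

#' Write an expression dataset in the package's matrix dialect
#' @param data A [as_tvn_expr()] dataset.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(tibble::as_tibble(data),
                  col = if (length(unique(.data$strain)) > 1 || any(.data$strain != "WT")) {
                    paste(.data$time, .data$replicate, .data$strain, sep = ":")
                  } else {
                    paste(.data$time, .data$replicate, sep = ":")
                  }),
    id_cols = "gene", names_from = "col", values_from = "value"
  )
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write selected networks to TSV tables
#'
#' Produces `<prefix>_changepoints.tsv` (gene, position, posterior, bf,
#' support), `<prefix>_edges.tsv` (target, parent, phase_start, phase_end,
#' posterior, bf, support, coef, sign) and `<prefix>_summary.tsv` (one row
#' per gene with its selected `k` and edge count, including genes with
#' neither changepoints nor edges). Optionally a Graphviz DOT export with
#' one colour per phase.
#'
#' @param networks A `tvn_network` or list of them.
#' @param prefix Output path prefix.
#' @param dot Also write `<prefix>.dot`?
#' @return Invisible character vector of the files written.
#' @export
write_results <- function(networks, prefix, dot = FALSE) {
  if (inherits(networks, "tvn_network")) networks <- list(networks)
  cps <- purrr::map_dfr(networks, function(nw) {
    if (!nrow(nw$changepoints)) return(tibble::tibble())
    dplyr::mutate(nw$changepoints, gene = nw$target, .before = 1)
  })
  edges <- purrr::map_dfr(networks, function(nw) nw$edges)
  summary <- purrr::map_dfr(networks, function(nw) {
    tibble::tibble(gene = nw$target, k = nw$k, n_edges = nrow(nw$edges))
  })
  files <- paste0(prefix, c("_changepoints.tsv", "_edges.tsv", "_summary.tsv"))
  write_tsv0 <- function(df, path, cols) {
    if (!nrow(df)) df <- setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv0(cps, files[1], c("gene", "position", "posterior", "bf", "support"))
  write_tsv0(edges, files[2], c("target", "parent", "phase_index", "phase_start",
                                "phase_end", "posterior", "bf", "support", "coef", "sign"))
  write_tsv0(summary, files[3], c("gene", "k", "n_edges"))
  if (dot) {
    dot_path <- paste0(prefix, ".dot")
    phases <- unique(edges[, c("phase_start", "phase_end")])
    palette <- grDevices::rainbow(max(nrow(phases), 1))
    lines <- c("digraph tvn {", "  rankdir=LR;")
    if (nrow(edges)) {
      key <- match(paste(edges$phase_start, edges$phase_end),
                   paste(phases$phase_start, phases$phase_end))
      lines <- c(lines, sprintf(
        '  "%s" -> "%s" [color="%s", label="%d-%d"];',
        edges$parent, edges$target, palette[key],
        edges$phase_start, edges$phase_end - 1L
      ))
    }
    lines <- c(lines, "}")
    writeLines(lines, dot_path)
    files <- c(files, dot_path)
  }
  invisible(files)
}

#' Re-read result tables written by [write_results()]
#' @param prefix The prefix passed to [write_results()].
#' @return A list with tibbles `changepoints`, `edges`, `summary`.
#' @export
read_results <- function(prefix) {
  rd <- function(suffix) {
    tibble::as_tibble(read.delim(paste0(prefix, suffix), stringsAsFactors = FALSE))
  }
  list(changepoints = rd("_changepoints.tsv"),
       edges = rd("_edges.tsv"),
       summary = rd("_summary.tsv"))
}

#' Infer and select networks for several target genes
#'
#' Convenience pipeline: runs [tvn_sample()] and [tvn_select()] for each
#' target against a common candidate list.
#'
#' @param data A [as_tvn_expr()] dataset.
#' @param targets Character vector of target gene ids.
#' @param candidates Candidate regulators (targets are excluded per gene
#'   unless `allow_self`).
#' @param iterations,burn_in,hyper,seed,bf_threshold,allow_self Passed on.
#' @return A list of `tvn_network` objects, one per target.
#' @export
tvn_infer <- function(data, targets, candidates, iterations = 50000,
                      burn_in = 0.25, hyper = tvn_hyper(), seed = NULL,
                      bf_threshold = 3, allow_self = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(targets))
  purrr::map2(targets, seeds, function(tg, sd) {
    cand <- if (allow_self) candidates else setdiff(candidates, tg)
    tr <- tvn_sample(data, tg, cand, iterations = iterations,
                     burn_in = burn_in, hyper = hyper, seed = sd,
                     allow_self = allow_self)
    tvn_select(tr, bf_threshold = bf_threshold)
  })
}
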