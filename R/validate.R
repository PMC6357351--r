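#' Collapse probe-level expression to gene symbols
#'
#' @param matrix Numeric matrix with probe ids as rownames.
#' @param probe2gene Mapping probe -> gene symbol: a named character vector
#'   or a two-column data.frame (probe, gene).
#' @param method `"max_mean"` (keep the probe with the highest mean
#'   expression, the default), `"mean"` or `"median"` (aggregate across a
#'   gene's probes per sample).
#' @return Numeric matrix keyed by gene symbol, with attribute `n_dropped`
#'   (probes without a mapping).
#' @export
collapse_probes <- function(matrix, probe2gene,
                            method = c("max_mean", "median", "mean")) {
  method <- match.arg(method)
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  if (is.data.frame(probe2gene)) {
    probe2gene <- stats::setNames(as.character(probe2gene[[2]]),
                                  as.character(probe2gene[[1]]))
  }
  hit <- rownames(matrix) %in% names(probe2gene)
  if (!any(hit)) stop("no matrix rows covered by probe2gene", call. = FALSE)
  n_dropped <- sum(!hit)
  m <- matrix[hit, , drop = FALSE]
  gene <- unname(probe2gene[rownames(m)])
  if (method == "max_mean") {
    means <- rowMeans(m, na.rm = TRUE)
    keep <- unlist(lapply(split(seq_len(nrow(m)), gene), function(idx) {
      idx[which.max(means[idx])]
    }))
    out <- m[keep, , drop = FALSE]
    rownames(out) <- names(keep)
  } else {
    fun <- if (method == "mean") {
      function(x) colMeans(x, na.rm = TRUE)
    } else {
      function(x) apply(x, 2, stats::median, na.rm = TRUE)
    }
    rows <- lapply(split(seq_len(nrow(m)), gene), function(idx) {
      fun(m[idx, , drop = FALSE])
    })
    out <- do.call(rbind, rows)
    colnames(out) <- colnames(m)
  }
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Pearson correlation of one edge's expression profiles
#'
#' Pairwise-complete observations; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, with
#' `|r| = 1` giving p = 0 by convention.
#'
#' @param x,y Numeric sample vectors of equal length.
#' @return List with `r`, `p`, `n_used`, and `status` (`"ok"` or
#'   `"untestable"` when fewer than 3 complete pairs remain or either vector
#'   has zero variance).
#' @export
pearson_edge <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  n_used <- sum(ok)
  if (n_used < 3L ||
      stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_used = n_used,
                status = "untestable"))
  }
  r <- stats::cor(x[ok], y[ok])
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- r * sqrt((n_used - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n_used - 2)
  }
  list(r = r, p = p, n_used = n_used, status = "ok")
}

#' Map human symbols onto expression-matrix rows
#'
#' Default heuristic for cross-species (human vs mouse) matching:
#' case-normalized symbol equality (e.g. human `WNT3A` matches mouse
#' `Wnt3a`). An explicit map (named character vector or two-column
#' data.frame, source -> target) overrides the heuristic.
#'
#' @param symbols Character vector of network symbols.
#' @param matrix_rows Rownames of the expression matrix.
#' @param ortholog_map Optional explicit mapping.
#' @return Character vector parallel to `symbols`: the matched matrix row or
#'   `NA` when unmapped.
#' @export
map_symbols <- function(symbols, matrix_rows, ortholog_map = NULL) {
  if (!is.null(ortholog_map)) {
    if (is.data.frame(ortholog_map)) {
      ortholog_map <- stats::setNames(as.character(ortholog_map[[2]]),
                                      as.character(ortholog_map[[1]]))
    }
    mapped <- unname(ortholog_map[symbols])
    mapped[!mapped %in% matrix_rows] <- NA_character_
    return(mapped)
  }
  direct <- match(symbols, matrix_rows)
  lookup <- matrix_rows[!duplicated(toupper(matrix_rows))]
  ci <- match(toupper(symbols), toupper(lookup))
  out <- ifelse(!is.na(direct), matrix_rows[direct], lookup[ci])
  out
}

#' Validate TF-gene edges against an independent expression matrix
#'
#' Each TF-gene edge is tested for co-expression: Pearson `r` over
#' pairwise-complete samples, two-sided p, and Benjamini-Hochberg q computed
#' across all testable edges of the queried network. An edge is `verified`
#' iff `|r| > r_min` and `p < p_max` and `q < q_max`. Edges whose TF or gene
#' is missing from the matrix (after ortholog mapping), or with fewer than 3
#' complete pairs or zero variance, are `untestable`; they stay in the
#' denominator of the headline verified fraction.
#'
#' @param network A `regulatory_network` with at least one TF_gene edge.
#' @param matrix Numeric expression matrix, rownames = gene symbols (collapse
#'   probes first with [collapse_probes()] if needed).
#' @param ortholog_map Optional explicit symbol map (see [map_symbols()]).
#' @param r_min,p_max,q_max Verification thresholds (defaults 0.3, 0.05, 0.1).
#' @return List with `results` (one row per TF_gene edge: `tf`, `gene`, `r`,
#'   `n_used`, `p`, `q`, `status`) and `summary` (`n_edges`, `n_testable`,
#'   `n_verified`, `fraction`).
#' @export
validate_edges <- function(network, matrix, ortholog_map = NULL,
                           r_min = 0.3, p_max = 0.05, q_max = 0.1) {
  stopifnot(inherits(network, "regulatory_network"), is.matrix(matrix))
  e <- network$edges[network$edges$edge_type == "TF_gene", , drop = FALSE]
  if (nrow(e) == 0L) stop("network has no TF_gene edges", call. = FALSE)

  tf_row <- map_symbols(e$source, rownames(matrix), ortholog_map)
  g_row <- map_symbols(e$target, rownames(matrix), ortholog_map)

  res <- data.frame(tf = e$source, gene = e$target, r = NA_real_,
                    n_used = NA_integer_, p = NA_real_, q = NA_real_,
                    status = "untestable", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(e))) {
    if (is.na(tf_row[i]) || is.na(g_row[i])) next
    pe <- pearson_edge(matrix[tf_row[i], ], matrix[g_row[i], ])
    res$r[i] <- pe$r
    res$p[i] <- pe$p
    res$n_used[i] <- pe$n_used
    res$status[i] <- pe$status
  }
  testable <- res$status == "ok"
  if (!any(testable)) stop("no testable TF_gene edges", call. = FALSE)
  res$q[testable] <- stats::p.adjust(res$p[testable], method = "BH")
  verified <- testable & abs(res$r) > r_min & res$p < p_max & res$q < q_max
  res$status[verified] <- "verified"
  res$status[testable & !verified] <- "not_verified"

  list(results = res,
       summary = list(n_edges = nrow(res),
                      n_testable = sum(testable),
                      n_verified = sum(verified),
                      fraction = sum(verified) / nrow(res)))
}
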