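#' Read a normalized expression matrix
#'
#' Two dialects are supported: plain TSV (first column = probe/gene ids,
#' remaining columns = samples, header row of sample names) and the GEO
#' Series-Matrix layout, where the numeric table is fenced between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` and the
#' `!`-prefixed header lines carry series/sample metadata. Values are assumed
#' already normalized (log scale); missing values are permitted.
#'
#' @param path Path to the file.
#' @param format `"tsv"`, `"series_matrix"`, or `"auto"` (series-matrix if a
#'   begin fence is found).
#' @return Numeric matrix with probe/gene rownames and sample colnames. For
#'   series-matrix input the header lines are attached as attribute
#'   `metadata` (character vector).
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "series_matrix")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  if (format == "auto") {
    format <- if (length(begin)) "series_matrix" else "tsv"
  }
  meta <- NULL
  if (format == "series_matrix") {
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (!length(begin) || !length(end) || end[1] <= begin[1]) {
      stop("series-matrix fences not found in ", path, call. = FALSE)
    }
    meta <- grep("^!", lines[-(begin[1]:end[1])], value = TRUE)
    lines <- lines[(begin[1] + 1):(end[1] - 1)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (length(unique(nf)) != 1L) {
    stop("ragged rows in ", path, ": rows have ",
         paste(unique(nf), collapse = "/"), " fields", call. = FALSE)
  }
  strip <- function(x) gsub('^"|"$', "", x)
  header <- strip(parts[[1]])
  samples <- header[-1]
  if (length(samples) == 0L) stop("zero sample columns in ", path, call. = FALSE)
  if (anyDuplicated(samples)) {
    stop("duplicate sample column names in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  body <- parts[-1]
  ids <- strip(vapply(body, `[[`, character(1), 1L))
  vals <- vapply(body, function(p) {
    suppressWarnings(as.numeric(strip(p[-1])))
  }, numeric(length(samples)))
  m <- t(matrix(vals, nrow = length(samples)))
  dimnames(m) <- list(ids, samples)
  if (!is.null(meta)) attr(m, "metadata") <- meta
  m
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `term<TAB>description<TAB>member...`.
#' Members repeated within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of unique
#'   member vectors), `descriptions` (named character), and `background`
#'   (NULL; see [enrich()] for the default universe).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(gene_set_collection(list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("GMT line with fewer than 3 fields at line ", which(nf < 3L)[1],
         " of ", path, call. = FALSE)
  }
  terms <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(trimws(p[-(1:2)])))
  gene_set_collection(stats::setNames(sets, terms),
                      descriptions = stats::setNames(desc, terms))
}

#' Build a gene-set collection
#'
#' @param sets Named list of character vectors (term id -> member symbols).
#' @param descriptions Optional named character vector of term descriptions.
#' @param background Optional character vector: the symbol universe.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, background = NULL) {
  stopifnot(is.list(sets))
  if (length(sets)) {
    stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
    if (any(lengths(sets) == 0L)) stop("empty gene set(s)", call. = FALSE)
    sets <- lapply(sets, function(s) unique(as.character(s)))
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions,
                 background = background),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(term) {
    paste(c(term, collection$descriptions[[term]], collection$sets[[term]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
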