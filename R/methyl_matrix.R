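#' Methylation beta-value matrix
#'
#' A `methyl_matrix` holds beta values (fraction of methylated copies, in
#' \[0,1\]) for a set of CpG dinucleotides (rows) across samples (columns),
#' optionally together with the chronological age of each sample in years.
#'
#' @param values Numeric matrix, CpGs in rows, samples in columns. Rownames
#'   are taken as CpG identifiers and colnames as sample identifiers.
#' @param ages Optional numeric vector of sample ages (years), one per
#'   column of `values`, in column order or named by sample id.
#'
#' @return An object of class `methyl_matrix`: the numeric matrix with an
#'   `ages` attribute (or `NULL`).
#' @export
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.4), nrow = 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' mm <- methyl_matrix(m, ages = c(30, 60))
#' sample_ages(mm)
methyl_matrix <- function(values, ages = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (CpGs x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (CpG ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate CpG ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  bad <- which(!is.finite(values) | values < 0 | values > 1)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf(
      "beta value out of [0,1] or non-finite at CpG '%s', sample '%s' (%s)",
      rownames(values)[i], colnames(values)[j],
      format(values[bad[1]])))
  }
  if (!is.null(ages)) {
    if (!is.null(names(ages))) {
      missing_ids <- setdiff(colnames(values), names(ages))
      if (length(missing_ids))
        stop("ages missing for samples: ", paste(missing_ids, collapse = ", "))
      ages <- unname(ages[colnames(values)])
    }
    if (length(ages) != ncol(values))
      stop("`ages` must have one entry per sample")
    if (any(!is.finite(ages) | ages < 0))
      stop("ages must be finite and non-negative")
  }
  structure(values, ages = ages, class = c("methyl_matrix", class(values)))
}

#' @rdname methyl_matrix
#' @param x A `methyl_matrix`.
#' @export
sample_ages <- function(x) attr(x, "ages")

#' @rdname methyl_matrix
#' @export
cpg_ids <- function(x) rownames(x)

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("methyl_matrix: %d CpGs x %d samples%s\n",
              nrow(x), ncol(x),
              if (is.null(attr(x, "ages"))) "" else " (with ages)"))
  invisible(x)
}

#' Read a beta-value matrix from a delimited file
#'
#' Expects a TSV/CSV table with CpGs in rows and samples in columns; the
#' first column holds the CpG identifier. An optional metadata table keyed
#' by sample id supplies chronological ages. The GEO series-matrix layout
#' (comment lines starting with `!`, table delimited by
#' `!series_matrix_table_begin` / `!series_matrix_table_end`) is also
#' understood when `format = "series_matrix"`.
#'
#' @param path Path to the beta-value table.
#' @param metadata Optional path to a TSV with columns `sample_id`, `age`.
#' @param transpose If `TRUE`, the file is samples x CpGs and is transposed
#'   on read.
#' @param format `"table"` (default) or `"series_matrix"`.
#' @return A [methyl_matrix].
#' @export
read_beta_matrix <- function(path, metadata = NULL, transpose = FALSE,
                             format = c("table", "series_matrix")) {
  format <- match.arg(format)
  if (format == "series_matrix") {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg)
      stop("series-matrix table delimiters not found in ", path)
    body <- lines[(beg + 1L):(end - 1L)]
    dt <- data.table::fread(text = body, sep = "\t", header = TRUE)
  } else {
    dt <- data.table::fread(path, header = TRUE)
  }
  ids <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    nonnum <- which(is.na(suppressWarnings(as.numeric(vals))) & !is.na(vals))
    stop("non-numeric beta values in ", path,
         if (length(nonnum)) paste0(" (first at flat index ", nonnum[1], ")"))
  }
  rownames(vals) <- ids
  if (transpose) vals <- t(vals)
  ages <- NULL
  if (!is.null(metadata)) {
    md <- data.table::fread(metadata, header = TRUE)
    if (!all(c("sample_id", "age") %in% names(md)))
      stop("metadata must have columns `sample_id` and `age`")
    ages <- stats::setNames(as.numeric(md$age), as.character(md$sample_id))
    missing_ids <- setdiff(colnames(vals), names(ages))
    if (length(missing_ids))
      stop("metadata missing samples: ", paste(missing_ids, collapse = ", "))
  }
  methyl_matrix(vals, ages = ages)
}

#' Write a beta-value matrix (and optional metadata) to TSV
#'
#' @param x A [methyl_matrix].
#' @param path Output path for the beta table.
#' @param metadata Optional output path for the `sample_id`/`age` table
#'   (requires ages).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, metadata = NULL) {
  vals <- unclass_matrix(x)
  # doubles are serialised at 17 significant digits so the text round-trip
  # is bit-exact
  chr <- matrix(format_full(vals), nrow(vals),
                dimnames = dimnames(vals))
  dt <- data.table::data.table(cpg_id = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(chr))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  if (!is.null(metadata)) {
    ages <- sample_ages(x)
    if (is.null(ages)) stop("matrix has no ages to write")
    data.table::fwrite(
      data.table::data.table(sample_id = colnames(x),
                             age = format_full(ages)),
      metadata, sep = "\t", quote = FALSE)
  }
  invisible(path)
}

unclass_matrix <- function(x) {
  attr(x, "ages") <- NULL
  class(x) <- "matrix"
  x
}

#' Mean per-CpG standard deviation
#'
#' For each CpG, the standard deviation of its beta values across samples;
#' the mean of these over CpGs. Twice this quantity is the default
#' perturbation size applied to a single methylation level, so that the
#' perturbation is of the order of the variation present in the cohort.
#'
#' @param x A [methyl_matrix] with at least two samples.
#' @return A single non-negative number.
#' @export
mean_cpg_std <- function(x) {
  if (ncol(x) < 2L) stop("need at least two samples to estimate deviations")
  mean(apply(unclass_matrix(x), 1L, stats::sd))
}
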