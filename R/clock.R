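#' Epigenetic clock model
#'
#' A linear epigenetic clock: a coefficient per CpG plus an adult age
#' threshold. The clock maps a methylation profile to an age estimate via a
#' piecewise transform that is linear above the adult threshold and
#' exponential below it (see [horvath_age()]).
#'
#' The transform as implemented carries no global intercept beyond the
#' adult threshold itself. A published clock with an extra intercept can be
#' represented by adding a pseudo-CpG whose level is held at 1 and whose
#' coefficient is the intercept.
#'
#' @param coefficients Named numeric vector, CpG id -> coefficient.
#' @param adult_threshold Adult age threshold in years (default 20).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(coefficients, adult_threshold = 20) {
  if (length(coefficients) == 0L || all(coefficients == 0))
    stop("clock must have at least one non-zero coefficient")
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stop("coefficients must be named by CpG id")
  if (anyDuplicated(names(coefficients)))
    stop("duplicate CpG ids in clock: ",
         paste(unique(names(coefficients)[duplicated(names(coefficients))]),
               collapse = ", "))
  if (any(!is.finite(coefficients)))
    stop("non-finite clock coefficient")
  if (!is.numeric(adult_threshold) || length(adult_threshold) != 1L ||
      adult_threshold <= -1)
    stop("adult_threshold must be a single number > -1")
  structure(list(coefficients = coefficients,
                 adult_threshold = adult_threshold),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("clock_model: %d CpGs, adult threshold %.3g years\n",
              length(x$coefficients), x$adult_threshold))
  invisible(x)
}

#' Read / write a clock-coefficient file
#'
#' CSV with columns `cpg_id`, `coefficient`; the adult threshold may be
#' given in a comment header line `# adult_threshold=20` or through the
#' `adult_threshold` argument (the argument wins).
#'
#' @param path Path to the clock CSV.
#' @param adult_threshold Adult threshold in years; if `NULL`, taken from
#'   the file header, defaulting to 20.
#' @return A [clock_model].
#' @export
read_clock <- function(path, adult_threshold = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(adult_threshold)) {
    at_line <- grep("adult_threshold\\s*=", hdr, value = TRUE)
    adult_threshold <- if (length(at_line))
      as.numeric(sub(".*adult_threshold\\s*=\\s*", "", at_line[1])) else 20
  }
  dt <- data.table::fread(text = lines[!startsWith(lines, "#")],
                          header = TRUE)
  if (!all(c("cpg_id", "coefficient") %in% names(dt)))
    stop("clock file must have columns `cpg_id` and `coefficient`")
  if (nrow(dt) == 0L) stop("clock file has no coefficients")
  co <- suppressWarnings(as.numeric(dt$coefficient))
  if (any(is.na(co))) stop("non-numeric coefficient in clock file")
  clock_model(stats::setNames(co, as.character(dt$cpg_id)),
              adult_threshold = adult_threshold)
}

#' @rdname read_clock
#' @param clock A [clock_model] to serialise.
#' @export
write_clock <- function(clock, path) {
  writeLines(sprintf("# adult_threshold=%s",
                     format_full(clock$adult_threshold)), path)
  data.table::fwrite(
    data.table::data.table(cpg_id = names(clock$coefficients),
                           coefficient = format_full(clock$coefficients)),
    path, sep = ",", quote = FALSE, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Clock-estimated (DNAm) age of a methylation profile
#'
#' Computes the age estimate `a` from a profile `m` as
#' \deqn{a = (a_t + 1)\,S + a_t \quad (S \ge 0), \qquad
#'       a = e^{S + \ln(a_t + 1)} - 1 \quad (S < 0),}
#' where \eqn{S = \sum_i H_i m_i}, \eqn{H} are the clock coefficients and
#' \eqn{a_t} the adult age threshold. The two branches join continuously at
#' \eqn{S = 0} with value \eqn{a_t}.
#'
#' @param profile Named numeric vector of methylation levels, covering
#'   every CpG of the clock.
#' @param clock A [clock_model].
#' @return Estimated age in years.
#' @export
#' @examples
#' cl <- clock_model(c(cg1 = 0.5), adult_threshold = 20)
#' horvath_age(c(cg1 = 0.1), cl)  # 21 * 0.05 + 20 = 21.05
horvath_age <- function(profile, clock) {
  h <- clock$coefficients
  absent <- setdiff(names(h), names(profile))
  if (length(absent))
    stop("profile missing clock CpGs: ", paste(absent, collapse = ", "))
  s <- sum(h * profile[names(h)])
  at <- clock$adult_threshold
  if (s >= 0) (at + 1) * s + at else exp(s + log(at + 1)) - 1
}

#' @rdname horvath_age
#' @param x A [methyl_matrix]; ages are estimated column-wise.
#' @return `horvath_age_matrix()`: named numeric vector of estimated ages,
#'   one per sample.
#' @export
horvath_age_matrix <- function(x, clock) {
  h <- clock$coefficients
  absent <- setdiff(names(h), rownames(x))
  if (length(absent))
    stop("matrix missing clock CpGs: ", paste(absent, collapse = ", "))
  s <- drop(crossprod(unclass_matrix(x)[names(h), , drop = FALSE], h))
  at <- clock$adult_threshold
  ifelse(s >= 0, (at + 1) * s + at, exp(s + log(at + 1)) - 1)
}
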