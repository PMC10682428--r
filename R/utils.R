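#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum distance between the empirical cumulative distribution functions
#' of two samples: `D = sup_t |F_x(t) - F_y(t)|`. `D = 0` for identical
#' samples, `D = 1` for disjoint supports. This is the distribution-shape
#' component of the combination stability score; the test p-value is not used
#' by default because it depends on sample size.
#'
#' @param x,y numeric vectors (NAs removed).
#' @return the statistic, a number in \[0, 1\].
#' @examples
#' ks_stat(c(0, 0), c(-1, -3))  # disjoint supports -> 1
#' @export
ks_stat <- function(x, y) {
  x <- sort(x[!is.na(x)])
  y <- sort(y[!is.na(y)])
  if (length(x) == 0L || length(y) == 0L) return(NA_real_)
  pts <- c(x, y)
  # ECDFs are right-continuous step functions; the sup is attained at a jump
  max(abs(findInterval(pts, x) / length(x) - findInterval(pts, y) / length(y)))
}

# sample SD that returns NA (not an error) below n = 2
.sd_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# comma/tab sniffing on the header line; anything else needs an explicit sep
.detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) {
    if (!sep %in% c(",", "\t")) {
      .stopf("only comma or tab delimiters are supported (got %s)", deparse(sep))
    }
    return(sep)
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) .stopf("empty file: %s", path)
  if (grepl("\t", header)) "\t" else ","
}
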