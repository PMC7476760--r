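#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova as.formula coef dbinom glm lm median model.matrix
#'   pchisq pf pnorm poisson predict quantile rbeta rbinom rlnorm rmultinom
#'   rnbinom rnorm rpois runif setNames vcov wilcox.test nls sd cor complete.cases
#' @importFrom utils read.delim write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

#' Convert BED (0-based, half-open) interval bounds to 1-based inclusive
#'
#' All genomic coordinates inside the package are 1-based inclusive (the VCF
#' and GFF3 convention); this is the single place where the BED convention is
#' translated.
#'
#' @param start0,end0 integer vectors, BED `chromStart`/`chromEnd`.
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @examples
#' bed_to_1based(99, 101) # covers 1-based positions 100 and 101
#' @export
bed_to_1based <- function(start0, end0) {
  stopifnot(all(end0 >= start0))
  data.frame(start = as.integer(start0) + 1L, end = as.integer(end0))
}

## Position membership in a 1-based inclusive interval table (chrom, start, end)
pos_in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0L) return(logical(length(pos)))
  vapply(seq_along(pos), function(i) {
    any(intervals$chrom == chrom[i] &
        intervals$start <= pos[i] &
        intervals$end >= pos[i])
  }, logical(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: for order statistics
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, the adjusted value is
#' \eqn{\min_{j \ge i} (m/j) p_{(j)}}, capped at 1. `NA` inputs propagate and
#' are excluded from `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_input("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    adj <- pmin(1, cummin(pv[o] * m / seq.int(m, 1L)))
    out[ok][o] <- adj
    out[ok] <- pmax(out[ok], pv)  # monotonicity enforcement: adjusted >= raw
  }
  out
}

## Deterministic child seeds derived from one user seed (kept < 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}
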