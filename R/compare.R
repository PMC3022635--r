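#' Descending ranks with average ties
#'
#' Ranks a vector of index values with rank 1 for the highest value, ties
#' receiving the average of the ranks they span. Facility counts are heavily
#' tied (many municipalities share a count of 0 or 1), so the tie convention
#' materially affects rank comparisons and is fixed here.
#'
#' @param values finite numeric vector.
#' @return numeric vector of ranks (1 = highest value).
#' @examples
#' rank_values(c(5, 3, 5, 1))  # 1.5 3 1.5 4
#' @export
rank_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("cannot rank an empty vector")
  if (any(!is.finite(values))) stop("values must be finite")
  rank(-values, ties.method = "average")
}

#' Spearman rank correlation
#'
#' Pearson correlation of the tie-averaged rank vectors of the two inputs.
#' Rank correlation is the right tool for skewed index distributions (raw
#' facility counts span orders of magnitude), and is invariant under any
#' strictly monotone transform of either input. An informational large-sample
#' t-test is attached.
#'
#' @param values_a,values_b equal-length finite numeric vectors, `n >= 3`.
#' @return the correlation, with attributes `t` and `p_value` from the
#'   large-sample approximation `t = rho * sqrt((n-2)/(1-rho^2))`. A constant
#'   input leaves the correlation undefined: `NA` with a warning.
#' @export
spearman_rho <- function(values_a, values_b) {
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  n <- length(values_a)
  if (length(values_b) != n) stop("inputs must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    stop("values must be finite")
  }
  ra <- rank_values(values_a); rb <- rank_values(values_b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    warning("Spearman correlation undefined for a constant input")
    return(NA_real_)
  }
  rho <- stats::cor(ra, rb)
  tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  structure(rho, t = tval,
            p_value = 2 * stats::pt(-abs(tval), df = n - 2))
}

#' Rank-based comparison of two accessibility indices
#'
#' Assembles values, descending ranks and the Spearman correlation of two
#' indices observed on the same municipalities — e.g. raw facility counts
#' versus potential accessibility, or resident versus commuter potential.
#'
#' @param ids municipality ids.
#' @param values_a,values_b the two index value vectors, aligned with `ids`.
#' @param labels length-2 character labels for the two indices.
#' @return an object of class `index_comparison`: list with `table` (a data
#'   frame `id`, `value_a`, `value_b`, `rank_a`, `rank_b`), `labels` and
#'   `spearman_rho`.
#' @export
compare_indices <- function(ids, values_a, values_b,
                            labels = c("index_a", "index_b")) {
  ids <- as.character(ids)
  n <- length(ids)
  if (length(values_a) != n || length(values_b) != n) {
    stop("ids, values_a and values_b must have equal length")
  }
  stopifnot(length(labels) == 2L)
  rho <- spearman_rho(values_a, values_b)
  tab <- data.frame(id = ids,
                    value_a = as.numeric(values_a),
                    value_b = as.numeric(values_b),
                    rank_a = rank_values(values_a),
                    rank_b = rank_values(values_b),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, labels = as.character(labels),
                 spearman_rho = rho),
            class = "index_comparison")
}

#' @export
print.index_comparison <- function(x, ...) {
  rho <- x$spearman_rho
  cat(sprintf("Index comparison: %s vs %s (n = %d)\n",
              x$labels[1], x$labels[2], nrow(x$table)))
  if (is.na(rho)) {
    cat("Spearman rho: undefined (constant input)\n")
  } else {
    cat(sprintf("Spearman rho = %.3f (t = %.2f, p = %.3g; large-sample approximation)\n",
                rho, attr(rho, "t"), attr(rho, "p_value")))
  }
  invisible(x)
}

#' @export
as.data.frame.index_comparison <- function(x, ...) {
  # long form, one row per (municipality, index), convenient for plotting
  tab <- x$table
  data.frame(id = rep(tab$id, 2L),
             index = rep(x$labels, each = nrow(tab)),
             value = c(tab$value_a, tab$value_b),
             rank = c(tab$rank_a, tab$rank_b),
             stringsAsFactors = FALSE)
}

#' @export
plot.index_comparison <- function(x, what = c("value", "rank"), ...) {
  what <- match.arg(what)
  tab <- x$table
  if (what == "value") {
    graphics::plot(tab$value_a, tab$value_b, xlab = x$labels[1],
                   ylab = x$labels[2], ...)
  } else {
    graphics::plot(tab$rank_a, tab$rank_b, xlab = paste(x$labels[1], "rank"),
                   ylab = paste(x$labels[2], "rank"), ...)
  }
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
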