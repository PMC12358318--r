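#' Jenks natural-breaks classification (exact)
#'
#' Exact Fisher optimal partitioning of one-dimensional data into `k`
#' classes minimising the total within-class sum of squared deviations,
#' computed by dynamic programming (no sampling). Ties between equally
#' optimal partitions break toward the lowest break values, so results are
#' deterministic. This classifier drives the pinch-point, barrier-point,
#' resistance-ratio and centrality classes downstream.
#'
#' @param values finite numeric vector (at least `k` distinct values).
#' @param k number of classes (>= 2).
#' @return an object of class `pan_breaks`: list with `k`, `breaks`
#'   (ascending interior cut values, length `k - 1`), `method`, and
#'   `objective` (the minimised within-class SSD).
#' @export
jenks_breaks <- function(values, k) {
  values <- values[is.finite(values)]
  if (k < 2) stop("k must be at least 2")
  if (length(unique(values)) < k)
    stop("fewer distinct values (", length(unique(values)), ") than classes (", k, ")")
  x <- sort(values)
  starts <- cpp_jenks_starts(x, as.integer(k))
  # interior break = midpoint between a class's last value and the next first
  breaks <- (x[starts[-1] - 1L] + x[starts[-1]]) / 2
  structure(list(k = as.integer(k), breaks = as.numeric(breaks),
                 method = "jenks",
                 objective = cpp_jenks_objective(x, starts)),
            class = "pan_breaks")
}

#' Fixed-break classification rule
#' @param breaks ascending interior cut values.
#' @param method label stored on the object.
#' @return a `pan_breaks`.
#' @export
class_breaks <- function(breaks, method = "table") {
  breaks <- as.numeric(breaks)
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be strictly ascending")
  structure(list(k = length(breaks) + 1L, breaks = breaks, method = method,
                 objective = NA_real_), class = "pan_breaks")
}

#' @exportS3Method base::print
print.pan_breaks <- function(x, ...) {
  cat(sprintf("<pan_breaks> %d classes (%s); cuts: %s\n", x$k, x$method,
              paste(signif(x$breaks, 6), collapse = ", ")))
  invisible(x)
}

#' Classify values with a break rule
#'
#' Class `i` is the interval `(break[i-1], break[i]]`; every finite value
#' falls in exactly one class `1..k`.
#'
#' @param values numeric vector or `pan_grid`.
#' @param rule a `pan_breaks`.
#' @return integer classes (vector, or `pan_grid` when given one).
#' @export
jenks_classify <- function(values, rule) {
  stopifnot(inherits(rule, "pan_breaks"))
  cls <- function(v) {
    out <- rep(NA_integer_, length(v))
    ok <- is.finite(v)
    out[ok] <- findInterval(v[ok], rule$breaks, left.open = TRUE) + 1L
    out
  }
  if (inherits(values, "pan_grid")) {
    g <- values
    g$values <- matrix(cls(as.vector(g$values)), nrow(g$values), ncol(g$values))
    g
  } else cls(values)
}
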