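#' Expert pairwise comparison matrix
#'
#' Validates an AHP reciprocal comparison matrix: positive entries, unit
#' diagonal, and approximate reciprocity `a_ij * a_ji = 1`. Published
#' matrices are printed with rounding, so reciprocity is a soft check:
#' relative errors above `tol` warn, above `reject_tol` the matrix is
#' rejected.
#'
#' @param a square numeric matrix of positive pairwise ratios.
#' @param labels factor identifiers (defaults to dimnames or F1..Fn).
#' @param tol warn threshold on `|a_ij * a_ji - 1|` (default 0.02).
#' @param reject_tol hard rejection threshold (default 0.10).
#' @return an object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(a, labels = NULL, tol = 0.02, reject_tol = 0.10) {
  a <- as.matrix(a)
  n <- nrow(a)
  if (n != ncol(a)) stop("matrix must be square")
  if (any(!is.finite(a)) || any(a <= 0)) stop("all entries must be positive and finite")
  if (any(abs(diag(a) - 1) > 1e-9)) stop("diagonal entries must equal 1")
  if (is.null(labels)) labels <- rownames(a)
  if (is.null(labels)) labels <- paste0("F", seq_len(n))
  rec_err <- max(abs(a * t(a) - 1))
  if (rec_err > reject_tol)
    stop(sprintf("reciprocity violated: max |a_ij*a_ji - 1| = %.4f > %.2f", rec_err, reject_tol))
  if (rec_err > tol)
    warning(sprintf("imperfect reciprocity (max |a_ij*a_ji - 1| = %.4f); entries look rounded", rec_err))
  dimnames(a) <- list(labels, labels)
  structure(list(a = a, labels = labels), class = "pairwise_matrix")
}

#' Read a labelled comparison matrix from CSV
#' @param path CSV with factor labels in the first column and header row.
#' @param ... passed to [pairwise_matrix()].
#' @return a `pairwise_matrix`.
#' @export
read_pairwise_matrix <- function(path, ...) {
  d <- utils::read.csv(path, check.names = FALSE)
  labels <- as.character(d[[1]])
  a <- as.matrix(d[, -1, drop = FALSE])
  rownames(a) <- labels
  pairwise_matrix(a, labels = labels, ...)
}

# Saaty's random consistency index by matrix order
saaty_ri <- c(`3` = 0.58, `4` = 0.90, `5` = 1.12, `6` = 1.24, `7` = 1.32,
              `8` = 1.41, `9` = 1.45, `10` = 1.49)

#' AHP factor weights and consistency statistics
#'
#' Weights are the normalised principal right eigenvector of the comparison
#' matrix, found by power iteration (tolerance 1e-10, at most 10,000
#' iterations); the principal eigenvalue comes from the Rayleigh quotient at
#' convergence. Consistency follows Saaty: `CI = (lambda_max - n)/(n - 1)`,
#' `CR = CI / RI(n)`; judgements with `CR < 0.10` are conventionally
#' acceptable.
#'
#' @param m a `pairwise_matrix`.
#' @param tol convergence tolerance on the weight vector.
#' @param max_iter iteration cap.
#' @return an object of class `ahp_fit` with elements `weights` (tibble:
#'   `label`, `weight`), `lambda_max`, `ci`, `cr`, `ri`, `n`.
#' @export
ahp_weights <- function(m, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(m, "pairwise_matrix"))
  a <- m$a; n <- nrow(a)
  w <- rep(1 / n, n)
  lambda <- NA_real_
  for (it in seq_len(max_iter)) {
    w_new <- as.vector(a %*% w)
    w_new <- w_new / sum(w_new)
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < tol) break
  }
  if (delta >= tol) stop("power iteration did not converge")
  aw <- as.vector(a %*% w)
  lambda <- sum(w * aw) / sum(w * w)  # Rayleigh quotient
  ci <- (lambda - n) / (n - 1)
  ri <- if (n >= 3 && n <= 10) unname(saaty_ri[as.character(n)]) else NA_real_
  cr <- if (is.na(ri)) NA_real_ else ci / ri
  structure(list(
    weights = tibble::tibble(label = m$labels, weight = w),
    lambda_max = lambda, ci = ci, cr = cr, ri = ri, n = n),
    class = "ahp_fit")
}

#' Consistency index and ratio of a comparison matrix
#'
#' @param m a `pairwise_matrix` of order 3..10 (Saaty's RI table bound).
#' @return named list with `ci` and `cr`.
#' @export
consistency_ratio <- function(m) {
  stopifnot(inherits(m, "pairwise_matrix"))
  n <- nrow(m$a)
  if (n < 3) stop("consistency ratio undefined for n < 3")
  if (n > 10) stop("random-index table covers n <= 10 only")
  fit <- ahp_weights(m)
  list(ci = fit$ci, cr = fit$cr)
}

#' @exportS3Method base::print
print.ahp_fit <- function(x, ...) {
  cat(sprintf("<ahp_fit> n = %d, lambda_max = %.6f, CI = %.6f, CR = %s\n",
              x$n, x$lambda_max, x$ci,
              if (is.na(x$cr)) "NA" else sprintf("%.6f", x$cr)))
  print(dplyr::mutate(x$weights, weight = round(.data$weight, 4)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy AHP results
#' @param x an `ahp_fit`.
#' @param ... unused.
#' @return `tidy`: tibble of labels and weights; `glance`: one-row tibble of
#'   fit statistics.
#' @export
tidy.ahp_fit <- function(x, ...) x$weights

#' @rdname tidy.ahp_fit
#' @export
glance.ahp_fit <- function(x, ...) {
  tibble::tibble(n = x$n, lambda_max = x$lambda_max, ci = x$ci, cr = x$cr,
                 ri = x$ri, consistent = !is.na(x$cr) && x$cr < 0.10)
}

#' Write AHP weights to CSV
#' @param fit an `ahp_fit`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_ahp_weights <- function(fit, path) {
  d <- fit$weights
  utils::write.csv(d, path, row.names = FALSE)
  footer <- sprintf("# lambda_max=%.10f ci=%.10f cr=%.10f ri=%.4f",
                    fit$lambda_max, fit$ci, fit$cr, fit$ri)
  cat(footer, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}

#' Bundled expert comparison matrix for the ten resistance factors
#'
#' Returns the package's bundled 10x10 expert pairwise comparison matrix for
#' the resistance factors (E1 elevation, E2 slope, E3 relief, E4 NDVI,
#' E5 distance to water, A1 land use, A2.1-A2.3 distance to expressways /
#' primary / secondary roads, A3 distance to settlements), as elicited from
#' a protected-area expert panel.
#'
#' @return a `pairwise_matrix`.
#' @export
expert_matrix <- function() {
  path <- system.file("extdata", "expert_comparison_matrix.csv",
                      package = "panlink", mustWork = TRUE)
  suppressWarnings(read_pairwise_matrix(path))
}
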