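#' Assemble the standardized tachogram matrix
#'
#' Stacks m-interval windows as the columns of an `m x n` matrix, subtracts
#' the mean column vector (the cross-record mean profile, so that the
#' leading components capture shared within-window structure such as a
#' steady drift in N-N interval), then divides each column by its own
#' population standard deviation so every column has unit variance.
#'
#' @param windows A list of numeric vectors, all of length m.
#' @param ids Optional record ids used in error messages.
#' @return A list with `matrix` (standardized m x n), `mean_profile`
#'   (length m, seconds) and `scales` (per-column standard deviations).
#' @export
assemble_matrix <- function(windows, ids = NULL) {
  m <- unique(lengths(windows))
  if (length(m) != 1L) stop("all windows must have equal length", call. = FALSE)
  X <- matrix(unlist(windows, use.names = FALSE), nrow = m)
  mean_profile <- rowMeans(X)
  X <- X - mean_profile
  scales <- sqrt(colMeans(X^2))
  zero <- which(scales <= 0 | !is.finite(scales))
  if (length(zero)) {
    id <- if (!is.null(ids)) ids[zero[1]] else sprintf("column %d", zero[1])
    stop(sprintf("degenerate record (zero variance after centering): %s", id),
         call. = FALSE)
  }
  X <- sweep(X, 2, scales, "/")
  list(matrix = X, mean_profile = mean_profile, scales = scales)
}

#' Gavish-Donoho threshold coefficient
#'
#' Cubic approximation of the optimal hard-threshold coefficient for
#' singular values of an `m x n` matrix (aspect ratio `beta = n/m <= 1`)
#' observed under additive white noise of unknown level:
#' `omega(beta) = 0.56 beta^3 - 0.95 beta^2 + 1.82 beta + 1.43`.
#' The cutoff applied to the singular-value spectrum is
#' `tau* = omega(beta) * median(singular values)`.
#'
#' @param beta Aspect ratio in (0, 1].
#' @return The dimensionless coefficient `omega(beta)`.
#' @export
gavish_donoho_omega <- function(beta) {
  if (!is.numeric(beta) || any(beta <= 0) || any(beta > 1)) {
    stop("beta must lie in (0, 1]", call. = FALSE)
  }
  0.56 * beta^3 - 0.95 * beta^2 + 1.82 * beta + 1.43
}

#' Fit the tachogram principal-component decomposition
#'
#' Computes the reduced singular value decomposition `R = U S V^T` of the
#' standardized window matrix and retains the `k` components whose
#' singular values exceed the Gavish-Donoho optimal hard threshold
#' `tau* = omega(n/m) * median(singular values)` (`k` is floored at 1 so
#' downstream feature rows are always well-formed). `U S` encodes the
#' principal components; `V` the per-record projection magnitudes.
#'
#' @param std A list from [assemble_matrix()], or a bare standardized
#'   matrix.
#' @return An object of class `tachogram_pca`: list with `m`, `n`,
#'   `mean_profile`, `left_vectors` (U), `singular_values`,
#'   `right_vectors` (V), `threshold` (tau*), `omega`, and retained rank
#'   `k`.
#' @export
fit_decomposition <- function(std) {
  if (is.matrix(std)) std <- list(matrix = std, mean_profile = rep(0, nrow(std)))
  X <- std$matrix
  if (!all(is.finite(X))) stop("matrix must be finite", call. = FALSE)
  if (ncol(X) < 2L) stop("need at least 2 records", call. = FALSE)
  sv <- svd(X)
  beta <- min(nrow(X), ncol(X)) / max(nrow(X), ncol(X))
  omega <- gavish_donoho_omega(beta)
  tau <- omega * stats::median(sv$d)
  k <- max(1L, sum(sv$d > tau))
  structure(
    list(m = nrow(X), n = ncol(X),
         mean_profile = std$mean_profile,
         left_vectors = sv$u, singular_values = sv$d, right_vectors = sv$v,
         omega = omega, threshold = tau, k = k),
    class = "tachogram_pca"
  )
}

#' @export
print.tachogram_pca <- function(x, ...) {
  cat(sprintf("<tachogram_pca> %d x %d, k = %d of %d singular values above tau* = %.3f\n",
              x$m, x$n, x$k, length(x$singular_values), x$threshold))
  invisible(x)
}

#' Project a window onto the retained principal components
#'
#' Standardizes the window with the decomposition's training mean profile
#' and the window's own population standard deviation (mirroring the
#' per-column rule used at fit time), then returns the coefficients
#' `U^T x` for the first `k` components. For a training column this
#' reproduces the corresponding entries of `S V^T`.
#'
#' @param decomp A `tachogram_pca` from [fit_decomposition()].
#' @param window Numeric vector of length `decomp$m`.
#' @return Numeric vector of `decomp$k` coefficients.
#' @export
project_record <- function(decomp, window) {
  stopifnot(inherits(decomp, "tachogram_pca"))
  x <- as.numeric(window)
  if (length(x) != decomp$m) {
    stop(sprintf("window length %d != decomposition m = %d", length(x), decomp$m),
         call. = FALSE)
  }
  x <- x - decomp$mean_profile
  s <- sqrt(mean(x^2))
  if (s <= 0 || !is.finite(s)) stop("degenerate window (zero variance)", call. = FALSE)
  drop(crossprod(decomp$left_vectors[, seq_len(decomp$k), drop = FALSE], x / s))
}

#' @method tidy tachogram_pca
#' @export
tidy.tachogram_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$singular_values),
    singular_value = x$singular_values,
    retained = seq_along(x$singular_values) <= x$k
  )
}

#' @method glance tachogram_pca
#' @export
glance.tachogram_pca <- function(x, ...) {
  tibble::tibble(m = x$m, n = x$n, k = x$k,
                 omega = x$omega, threshold = x$threshold,
                 frac_energy_retained =
                   sum(x$singular_values[seq_len(x$k)]^2) / sum(x$singular_values^2))
}

#' Singular-value spectrum plot with the hard-threshold cutoff
#'
#' @param object A `tachogram_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tachogram_pca
#' @export
autoplot.tachogram_pca <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$singular_value,
                                  colour = .data$retained)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey40")) +
    ggplot2::labs(x = "component", y = "singular value",
                  title = sprintf("Optimal hard threshold retains k = %d components",
                                  object$k)) +
    ggplot2::theme_minimal()
}

#' Serialize / restore a fitted decomposition as portable text
#'
#' Stores the mean profile, the first `k` left singular vectors, the
#' singular values and the threshold in a versioned JSON container.
#'
#' @param decomp A `tachogram_pca`.
#' @param path Output path.
#' @return `write_decomposition()` returns `path` invisibly;
#'   `read_decomposition()` returns a `tachogram_pca` truncated to the
#'   retained components.
#' @export
write_decomposition <- function(decomp, path) {
  stopifnot(inherits(decomp, "tachogram_pca"))
  payload <- list(
    format = "vtwarn_pca", version = 1L,
    m = decomp$m, n = decomp$n, k = decomp$k,
    omega = decomp$omega, threshold = decomp$threshold,
    mean_profile = decomp$mean_profile,
    singular_values = decomp$singular_values,
    left_vectors = decomp$left_vectors[, seq_len(decomp$k), drop = FALSE]
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "vtwarn_pca")) stop("not a decomposition archive", call. = FALSE)
  structure(
    list(m = p$m, n = p$n, mean_profile = p$mean_profile,
         left_vectors = matrix(p$left_vectors, nrow = p$m),
         singular_values = p$singular_values, right_vectors = NULL,
         omega = p$omega, threshold = p$threshold, k = p$k),
    class = "tachogram_pca"
  )
}
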