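#' Specification of a hierarchical Gaussian-mixture benchmark
#'
#' Describes a mixture of spherical unit-variance Gaussians in
#' `dimension` dimensions, organised hierarchically into classes of
#' types. Each class mean is shifted from the origin by
#' `between_shift` along its own basis direction; each type within a
#' class is additionally shifted by the class's `within_shift` along a
#' type-specific basis direction. Class directions and type directions
#' are distinct standard basis vectors (classes first, then types), so
#' all shift directions are mutually orthonormal and class/type
#' geometry stays separable. Consequently two class means lie
#' `between_shift * sqrt(2)` apart and two type means within a class
#' `within_shift * sqrt(2)` apart.
#'
#' The defaults reproduce the benchmark used throughout this package:
#' three classes of five types each, with 2000, 1000 and 100 points per
#' type, between-class shift 20 and within-class shifts 4, 10 and 10,
#' in 50 dimensions -- 15 types and 15,500 points in total. The types
#' of the 2000-point class (shift 4) partially overlap; the other two
#' classes have well-separated types.
#'
#' @param dimension ambient dimension (default 50).
#' @param n_types integer vector, number of types per class.
#' @param points_per_type integer vector, points in each type of the
#'   corresponding class.
#' @param between_shift magnitude of the class-mean shifts.
#' @param within_shift numeric vector, magnitude of the type shifts
#'   within each class.
#' @param seed integer seed used by [simulate_mixture()].
#' @return An object of class `"mixture_spec"`.
#' @seealso [simulate_mixture()]
#' @export
#' @examples
#' spec <- mixture_spec()
#' sum(spec$n_types * spec$points_per_type)  # 15500
mixture_spec <- function(dimension = 50,
                         n_types = c(5, 5, 5),
                         points_per_type = c(2000, 1000, 100),
                         between_shift = 20,
                         within_shift = c(4, 10, 10),
                         seed = 42) {
  n_classes <- length(n_types)
  stopifnot(n_classes >= 1,
            length(points_per_type) == n_classes,
            length(within_shift) == n_classes,
            all(n_types >= 1), all(points_per_type >= 1),
            dimension >= 1, between_shift >= 0, all(within_shift >= 0))
  structure(list(dimension = as.integer(dimension),
                 n_types = as.integer(n_types),
                 points_per_type = as.integer(points_per_type),
                 between_shift = between_shift,
                 within_shift = within_shift,
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Gaussian mixture benchmark spec\n")
  cat(sprintf("  dimension: %d, classes: %d, types: %d, total n: %d\n",
              x$dimension, length(x$n_types), sum(x$n_types),
              sum(x$n_types * x$points_per_type)))
  cat(sprintf("  between-class shift: %g; within-class shifts: %s\n",
              x$between_shift, paste(x$within_shift, collapse = ", ")))
  cat(sprintf("  points per type: %s; seed: %d\n",
              paste(x$points_per_type, collapse = ", "), x$seed))
  invisible(x)
}

#' Sample a hierarchical Gaussian-mixture data set
#'
#' Draws standard-normal points and applies the class and type shifts
#' of a [mixture_spec()]. Rows are grouped by class, then type
#' (a `shuffle` option randomises row order; the sampled values are
#' unchanged). The generator is reproducible: the same spec (including
#' its seed) always yields the same matrix.
#'
#' @param spec a [mixture_spec()].
#' @param shuffle randomise row order (default `FALSE`).
#' @return A list of class `"labeled_matrix"` with elements
#'   `data` (n x dimension matrix), `type` (integer labels, `1..n_types`
#'   across all classes), `class` (integer labels `1..n_classes`) and
#'   `spec`.
#' @export
#' @examples
#' xs <- simulate_mixture(mixture_spec(points_per_type = c(20, 10, 5)))
#' dim(xs$data)
#' table(xs$class)
simulate_mixture <- function(spec = mixture_spec(), shuffle = FALSE) {
  stopifnot(inherits(spec, "mixture_spec"))
  n_classes <- length(spec$n_types)
  max_types <- max(spec$n_types)
  need <- n_classes + max_types
  if (spec$dimension < need) {
    stop(sprintf(paste0("dimension %d too small: need at least %d ",
                        "(%d class + %d type orthogonal shift directions)"),
                 spec$dimension, need, n_classes, max_types))
  }
  n <- sum(spec$n_types * spec$points_per_type)
  p <- spec$dimension

  set.seed(spec$seed)
  x <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)

  type_lab <- integer(n)
  class_lab <- integer(n)
  row <- 0L
  type_id <- 0L
  for (cl in seq_len(n_classes)) {
    for (ty in seq_len(spec$n_types[cl])) {
      type_id <- type_id + 1L
      m <- spec$points_per_type[cl]
      rows <- row + seq_len(m)
      # class shift on basis vector cl, type shift on basis vector
      # n_classes + ty (shared across classes; orthogonal within class)
      x[rows, cl] <- x[rows, cl] + spec$between_shift
      x[rows, n_classes + ty] <- x[rows, n_classes + ty] +
        spec$within_shift[cl]
      type_lab[rows] <- type_id
      class_lab[rows] <- cl
      row <- row + m
    }
  }
  if (shuffle) {
    ord <- sample.int(n)
    x <- x[ord, , drop = FALSE]
    type_lab <- type_lab[ord]
    class_lab <- class_lab[ord]
  }
  structure(list(data = x, type = type_lab, class = class_lab, spec = spec),
            class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix: %d points x %d dims, %d types in %d classes\n",
              nrow(x$data), ncol(x$data), length(unique(x$type)),
              length(unique(x$class))))
  invisible(x)
}

#' Write a simulated mixture to delimited text files
#'
#' Writes `data.tsv` (coordinates, no header) and `labels.tsv`
#' (columns `cell_id`, `type`, `class`) into `dir`.
#'
#' @param x a `"labeled_matrix"` from [simulate_mixture()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_mixture <- function(x, dir) {
  stopifnot(inherits(x, "labeled_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data_path <- file.path(dir, "data.tsv")
  labels_path <- file.path(dir, "labels.tsv")
  utils::write.table(x$data, data_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  labels <- data.frame(cell_id = sprintf("cell_%d", seq_len(nrow(x$data))),
                       type = x$type, class = x$class)
  utils::write.table(labels, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(data = data_path, labels = labels_path))
}
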