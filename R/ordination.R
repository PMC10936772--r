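#' Column-standardize a numeric matrix
#'
#' Centers each column to mean 0 and scales to unit standard deviation —
#' the correlation-matrix convention, required when variables mix units
#' (degrees, millimetres, metres; or the six trait units). Rows with any
#' missing value are dropped first (complete-case analysis).
#'
#' @param x Numeric matrix or data frame of numeric columns (row names
#'   kept as labels).
#' @return A standardized numeric matrix.
#' @export
#' @examples
#' standardize_matrix(cbind(a = 1:5, b = c(2, 4, 6, 8, 11)))
standardize_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("matrix must be numeric", call. = FALSE)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need at least 2 complete rows and 2 columns", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Principal component analysis of a standardized matrix
#'
#' Singular-value decomposition PCA with components ordered by decreasing
#' explained variance and a deterministic sign convention: the
#' largest-magnitude loading of each component is made nonnegative.
#' Explained fractions are computed over all components of the input, so
#' they sum to 1 even when `n_components` truncates the output.
#'
#' @param x A column-standardized matrix (see [standardize_matrix()]); if
#'   the columns are not yet standardized they are standardized first.
#' @param n_components Number of components to keep (default: all);
#'   values beyond the matrix rank are truncated with a message.
#' @return A `trait_pca` list: `explained` (fraction per kept component),
#'   `explained_all`, `loadings` (variable x component), `scores`
#'   (row x component), `n_components`.
#' @export
#' @examples
#' m <- standardize_matrix(matrix(rnorm(40), 10, 4,
#'                                dimnames = list(NULL, letters[1:4])))
#' p <- run_pca(m)
#' p$explained
run_pca <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  means <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (max(abs(means)) > 1e-8 || max(abs(sds - 1)) > 1e-8) {
    x <- standardize_matrix(x)
  }
  pr <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  eig <- pr$sdev^2
  rank_x <- sum(eig > max(eig) * 1e-12)
  if (is.null(n_components)) n_components <- rank_x
  if (n_components > rank_x) {
    message("n_components truncated to matrix rank (", rank_x, ")")
    n_components <- rank_x
  }
  keep <- seq_len(n_components)
  load <- pr$rotation[, keep, drop = FALSE]
  scores <- pr$x[, keep, drop = FALSE]
  # sign convention: dominant loading of each component nonnegative
  for (j in keep) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(load) <- colnames(scores) <- paste0("PC", keep)
  structure(
    list(explained = eig[keep] / sum(eig),
         explained_all = eig / sum(eig),
         loadings = load,
         scores = scores,
         n_components = n_components),
    class = "trait_pca"
  )
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Standardized PCA:", x$n_components, "components\n")
  cat("Explained:", paste0(sprintf("%.1f%%", 100 * x$explained),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Tidy PCA loadings
#'
#' @param x A `trait_pca`.
#' @param ... Unused.
#' @return Long tibble: `variable`, `component`, `loading`.
#' @export
tidy.trait_pca <- function(x, ...) {
  load <- x$loadings
  tibble::tibble(
    variable = rep(rownames(load), times = ncol(load)),
    component = rep(colnames(load), each = nrow(load)),
    loading = as.vector(load)
  )
}

#' One-row-per-component PCA summary
#'
#' @param x A `trait_pca`.
#' @param ... Unused.
#' @return Tibble: `component`, `explained`, `cumulative`.
#' @export
glance.trait_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$explained)),
    explained = x$explained,
    cumulative = cumsum(x$explained)
  )
}

#' Per-stage trait matrix for ordination
#'
#' Extracts the individuals of one ontogenetic stage as a complete-case
#' numeric matrix (individuals x traits) on the log scale by default —
#' the input to the per-stage trait PCAs.
#'
#' @param table A trait table.
#' @param stage `"adult"` or `"juvenile"`.
#' @param log_scale Log-transform raw values first (default `TRUE`;
#'   ignored for traits already stored on the log scale).
#' @return A numeric matrix with individual ids as row names and a
#'   `population` attribute giving each row's population.
#' @export
stage_trait_matrix <- function(table, stage, log_scale = TRUE) {
  table <- as_trait_tbl(table)
  reg <- get_registry(table)
  df <- tibble::as_tibble(table)[table$stage == stage, , drop = FALSE]
  m <- as.matrix(df[, reg$acronym, drop = FALSE])
  if (log_scale) {
    for (j in seq_len(ncol(m))) {
      if (reg$transform[j] == "none") m[, j] <- log(m[, j])
    }
  }
  rownames(m) <- df$individual_id
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  attr(m, "population") <- df$population[keep]
  m
}
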