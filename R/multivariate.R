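# Multivariate stage: PCA of cultivar trait profiles (active variables,
# e.g. fatty-acid percentages) with the fitted germination parameters
# projected as supplementary variables, followed by hierarchical clustering
# on the principal-component scores (HCPC).

#' Principal component analysis of a cultivar trait matrix
#'
#' Eigen-decomposition of the correlation matrix (default) or covariance
#' matrix of the active variables. Reports, per component: eigenvalue,
#' percent of variance, row scores, variable loadings (unit eigenvectors),
#' variable coordinates (loading * sqrt(eigenvalue); the variable-component
#' correlation in the standardized case), percent contributions of each
#' variable, and cos2, the squared quality of representation of each
#' variable on each component. Supplementary variables are projected as
#' correlations with the scores and never influence the decomposition.
#'
#' The sign of each component is fixed so that its largest-magnitude
#' loading is positive.
#'
#' @param x data frame or matrix of traits, one row per cultivar (row names
#'   kept as labels).
#' @param active column names of the active variables (default: all numeric
#'   columns not listed as supplementary).
#' @param supplementary column names projected post hoc (e.g. fitted
#'   \code{Tb}, \code{psi_b50}, \code{theta_HT}).
#' @param standardize use the correlation matrix (\code{TRUE}, default,
#'   appropriate when variables live on different scales) or the covariance
#'   matrix.
#' @return Object of class \code{trait_pca}: \code{eigenvalues},
#'   \code{percent_variance}, \code{scores}, \code{loadings},
#'   \code{coordinates}, \code{contributions}, \code{cos2},
#'   \code{supplementary} (list with \code{coordinates} and \code{cos2}) and
#'   bookkeeping fields.
#' @export
trait_pca <- function(x, active = NULL, supplementary = NULL,
                      standardize = TRUE) {
  x <- as.data.frame(x)
  if (is.null(active)) {
    num <- names(x)[vapply(x, is.numeric, TRUE)]
    active <- setdiff(num, supplementary)
  }
  missing_cols <- setdiff(c(active, supplementary), names(x))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf("column(s) not in trait table: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(x[, active, drop = FALSE])
  if (nrow(X) < 3) abort_data("PCA needs at least 3 rows")
  if (length(active) < 2) abort_data("PCA needs at least 2 active variables")
  if (any(!is.finite(X))) abort_data("missing values in active columns")
  sds <- apply(X, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    abort_data(sprintf("zero-variance active column(s): %s",
                       paste(active[sds == 0], collapse = ", ")))
  }
  Xs <- scale(X, center = TRUE, scale = standardize)
  S <- crossprod(Xs) / (nrow(Xs) - 1)  # correlation or covariance matrix
  eig <- eigen(S, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  # sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(vectors))) {
    k <- which.max(abs(vectors[, j]))
    if (vectors[k, j] < 0) vectors[, j] <- -vectors[, j]
  }
  comp <- paste0("PC", seq_along(values))
  dimnames(vectors) <- list(active, comp)
  scores <- Xs %*% vectors
  coords <- sweep(vectors, 2, sqrt(values), `*`)
  contrib <- 100 * vectors^2
  quality <- coords^2
  denom <- rowSums(quality)
  cos2 <- sweep(quality, 1, ifelse(denom > 0, denom, 1), `/`)
  supp <- NULL
  if (!is.null(supplementary)) {
    Sup <- as.matrix(x[, supplementary, drop = FALSE])
    keep <- values > max(values) * 1e-12
    sc <- matrix(NA_real_, length(supplementary), length(values),
                 dimnames = list(supplementary, comp))
    sc[, keep] <- stats::cor(Sup, scores[, keep, drop = FALSE])
    supp <- list(coordinates = sc, cos2 = sc^2)
  }
  structure(class = "trait_pca", list(
    eigenvalues = values,
    percent_variance = 100 * values / sum(values),
    scores = scores,
    loadings = vectors,
    coordinates = coords,
    contributions = contrib,
    cos2 = cos2,
    supplementary = supp,
    active = active,
    standardized = standardize,
    labels = rownames(x) %||% as.character(seq_len(nrow(x)))))
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("PCA of %d rows x %d active variables (%s matrix)\n",
              nrow(x$scores), length(x$active),
              if (x$standardized) "correlation" else "covariance"))
  pv <- round(x$percent_variance, 1)
  cat("  % variance:", paste(pv[seq_len(min(5, length(pv)))],
                             collapse = ", "),
      if (length(pv) > 5) "..." else "", "\n")
  if (!is.null(x$supplementary)) {
    cat("  supplementary variables:",
        paste(rownames(x$supplementary$coordinates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hierarchical clustering on principal components
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of the
#' row scores on the retained components, cut into \code{k} clusters.
#' Cluster labels are renumbered by decreasing cluster size, ties broken by
#' first-member order, so the labelling is deterministic.
#'
#' @param pca a [trait_pca()] result.
#' @param k number of clusters (<= number of rows).
#' @param n_components how many leading components to cluster on: a count,
#'   or a fraction in (0,1) interpreted as the minimum cumulative share of
#'   variance to retain; default all components.
#' @return Integer vector of cluster labels named by row, with the
#'   \code{hclust} tree and retained component count as attributes.
#' @export
hcpc <- function(pca, k, n_components = NULL) {
  stopifnot(inherits(pca, "trait_pca"))
  n <- nrow(pca$scores)
  if (k > n) abort_data("k cannot exceed the number of rows")
  ncomp <- ncol(pca$scores)
  if (!is.null(n_components)) {
    if (n_components > 0 && n_components < 1) {
      cum <- cumsum(pca$percent_variance) / 100
      ncomp <- which(cum >= n_components)[1]
    } else {
      ncomp <- min(as.integer(n_components), ncomp)
    }
  }
  sc <- pca$scores[, seq_len(ncomp), drop = FALSE]
  tree <- stats::hclust(stats::dist(sc), method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  sizes <- table(raw)
  first <- vapply(names(sizes), function(l) which(raw == l)[1], 0)
  ord <- order(-as.vector(sizes), first)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  out <- relabel[raw]
  names(out) <- pca$labels
  attr(out, "tree") <- tree
  attr(out, "n_components") <- ncomp
  out
}

#' Correlation of each trait with a fitted parameter
#'
#' Pearson correlation (with two-sided t-test p-value) of every active
#' trait column against a target column, e.g. each fatty acid against the
#' hydrothermal time constant. With few rows the test has little power; a
#' \code{low_power} flag marks n < 10. Constant columns yield \code{NA}
#' correlations, flagged rather than dropped.
#'
#' @param x trait data frame.
#' @param active trait column names.
#' @param target name of the target column.
#' @return Data frame with \code{trait}, \code{r}, \code{p_value}, \code{n}
#'   and \code{low_power}.
#' @export
trait_correlations <- function(x, active, target) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(c(active, target), names(x))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf("column(s) not in trait table: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) < 3) abort_data("correlation needs at least 3 rows")
  y <- x[[target]]
  rows <- lapply(active, function(a) {
    v <- x[[a]]
    if (stats::sd(v) == 0 || stats::sd(y) == 0) {
      return(data.frame(trait = a, r = NA_real_, p_value = NA_real_,
                        n = length(v), low_power = length(v) < 10,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(v, y)
    data.frame(trait = a, r = unname(ct$estimate), p_value = ct$p.value,
               n = length(v), low_power = length(v) < 10,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
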