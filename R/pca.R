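# Correlation-matrix PCA. Variables are standardized, so each contributes
# unit variance and the eigenvalues sum to the number of variables; percent
# variance of a component is 100 * eigenvalue / 14. Loadings are
# eigenvector * sqrt(eigenvalue), i.e. correlations between variables and
# component scores. Eigenvectors are sign-ambiguous; each component is
# oriented so its loading sum is positive, which makes a general-size
# component load positively on every measurement.

#' Principal component analysis of a herd
#'
#' Eigendecomposition of the 14 x 14 correlation matrix of the measurements.
#'
#' @param herd A herd data frame with more records than variables
#'   (at least 15).
#' @return A `morpho_pca` object: `eigenvalues` (descending),
#'   `pct_variance`, `loadings` (variable x component), `scores`
#'   (animal x component, on standardized data), `retained` (Kaiser set),
#'   `communalities` (over retained components), `n`.
#' @examples
#' fit <- morpho_pca(simulate_herd(herd_sim_spec(seed = 1)))
#' glance(fit)
#' @export
morpho_pca <- function(herd) {
  herd <- validate_herd(herd, min_records = 15)
  v <- zoo_variables()
  x <- as.matrix(herd[v])
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant variable(s): ",
                 paste(v[sds == 0], collapse = ", "),
                 "; correlation matrix undefined."))
  }
  rmat <- cor(x)
  e <- eigen(rmat, symmetric = TRUE)
  if (min(e$values) < 1e-10) {
    off <- abs(rmat); diag(off) <- 0
    culprit <- which(off > 1 - 1e-8, arr.ind = TRUE)
    pair_txt <- if (nrow(culprit) > 0) {
      paste(unique(apply(culprit, 1, function(i)
        paste(sort(v[i]), collapse = "~"))), collapse = ", ")
    } else "unidentified"
    abort(paste0("Singular correlation matrix; collinear variable pair(s): ",
                 pair_txt, "."))
  }
  vectors <- e$vectors
  # orient each component so its loading sum is positive
  flip <- colSums(vectors) < 0
  vectors[, flip] <- -vectors[, flip]
  loadings <- vectors %*% diag(sqrt(e$values))
  dimnames(loadings) <- list(v, paste0("PC", seq_along(e$values)))
  scores <- scale(x) %*% vectors
  dimnames(scores) <- list(herd$animal_id, colnames(loadings))
  fit <- structure(
    list(
      eigenvalues = e$values,
      pct_variance = 100 * e$values / length(v),
      loadings = loadings,
      scores = scores,
      locality = herd$locality,
      n = nrow(herd)
    ),
    class = "morpho_pca"
  )
  fit$retained <- kaiser_retain(fit)
  fit$communalities <- communalities(fit)
  fit
}

#' Kaiser retention
#'
#' Components with eigenvalue strictly greater than the threshold
#' (default 1: a retained component must explain more than one
#' standardized variable's worth of variance).
#'
#' @param result A `morpho_pca` object or numeric vector of eigenvalues.
#' @param threshold Retention threshold.
#' @return Integer vector of retained component indices, in order.
#' @examples
#' kaiser_retain(c(6.39, 1.88, 1.18, 0.97)) # 1 2 3
#' @export
kaiser_retain <- function(result, threshold = 1.0) {
  ev <- if (inherits(result, "morpho_pca")) result$eigenvalues else result
  stopifnot(is.numeric(ev))
  which(ev > threshold)
}

#' Communalities over retained components
#'
#' Per variable, the sum of squared loadings across the retained
#' components: the share of that variable's (unit) variance the retained
#' components reproduce. Variables below `threshold` are flagged as
#' under-represented.
#'
#' @param result A `morpho_pca` object, or a numeric matrix / data frame of
#'   loadings (rows = variables, columns = the retained components; a
#'   `variable` column is used for names if present).
#' @param retained Component indices to sum over; defaults to the object's
#'   Kaiser set (ignored for plain loading matrices, which are taken
#'   as-is).
#' @param threshold Adequacy cutoff (default 0.5).
#' @return A tibble with `variable`, `communality`, `under_represented`.
#' @examples
#' communalities(data.frame(variable = "RL", pc1 = 0.34, pc2 = 0.77,
#'                          pc3 = 0.02))
#' @export
communalities <- function(result, retained = NULL, threshold = 0.5) {
  if (inherits(result, "morpho_pca")) {
    if (is.null(retained)) retained <- kaiser_retain(result)
    stopifnot(length(retained) > 0)
    lmat <- result$loadings[, retained, drop = FALSE]
    vars <- rownames(lmat)
  } else {
    lmat <- as.data.frame(result)
    vars <- if ("variable" %in% names(lmat)) {
      as.character(lmat$variable)
    } else {
      rownames(lmat)
    }
    lmat <- lmat[setdiff(names(lmat), "communality")]
    lmat <- as.matrix(lmat[vapply(lmat, is.numeric, logical(1))])
  }
  h2 <- rowSums(lmat^2)
  tibble::tibble(
    variable = vars,
    communality = unname(h2),
    under_represented = unname(h2) < threshold
  )
}

#' @export
print.morpho_pca <- function(x, ...) {
  k <- length(x$retained)
  cat(sprintf("Correlation-matrix PCA of %d animals, 14 variables\n", x$n))
  cat(sprintf("  retained (Kaiser > 1): %d component(s), %.2f%% of variance\n",
              k, sum(x$pct_variance[x$retained])))
  ev <- paste(sprintf("%.2f", x$eigenvalues[seq_len(min(4, length(x$eigenvalues)))]),
              collapse = ", ")
  cat(sprintf("  leading eigenvalues: %s, ...\n", ev))
  invisible(x)
}

#' Tidy a morpho_pca object
#'
#' @param x A `morpho_pca`.
#' @param matrix One of `"eigenvalues"`, `"loadings"`, `"scores"`.
#' @param ... Unused.
#' @return A tibble in long form for loadings/scores; one row per component
#'   for eigenvalues.
#' @exportS3Method generics::tidy
tidy.morpho_pca <- function(x, matrix = c("eigenvalues", "loadings", "scores"),
                            ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble::tibble(
      component = seq_along(x$eigenvalues),
      eigenvalue = x$eigenvalues,
      pct_variance = x$pct_variance,
      cumulative = cumsum(x$pct_variance),
      retained = seq_along(x$eigenvalues) %in% x$retained
    ))
  }
  m <- x[[matrix]]
  id <- if (matrix == "loadings") "variable" else "animal_id"
  tibble::as_tibble(m, rownames = id) |>
    tidyr::pivot_longer(-dplyr::all_of(id), names_to = "component",
                        values_to = if (matrix == "loadings") "loading"
                        else "score")
}

#' @exportS3Method generics::glance
glance.morpho_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_retained = length(x$retained),
    pct_variance_retained = sum(x$pct_variance[x$retained]),
    pc1_pct_variance = x$pct_variance[1],
    min_communality = min(x$communalities$communality)
  )
}

#' Plot a morpho_pca object
#'
#' @param object A `morpho_pca`.
#' @param type `"scores"` (PC1-PC2 scatter coloured by locality) or
#'   `"scree"` (eigenvalues with the Kaiser line).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.morpho_pca <- function(object, type = c("scores", "scree"), ...) {
  type <- match.arg(type)
  if (type == "scree") {
    df <- tidy(object, "eigenvalues")
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                       y = .data$eigenvalue)) +
        ggplot2::geom_col(ggplot2::aes(fill = .data$retained)) +
        ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
        ggplot2::labs(x = "Component", y = "Eigenvalue",
                      fill = "Retained") +
        ggplot2::theme_minimal()
    )
  }
  df <- tibble::tibble(
    pc1 = object$scores[, 1], pc2 = object$scores[, 2],
    locality = object$locality
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$locality)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$pct_variance[1]),
      y = sprintf("PC2 (%.1f%%)", object$pct_variance[2]),
      colour = "Locality"
    ) +
    ggplot2::theme_minimal()
}
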