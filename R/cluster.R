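# Locality-level structure: mean profiles, standardized Euclidean distances
# and Ward agglomeration. Variables are z-scored across localities before
# distancing by default, so that all fourteen measurements weigh equally
# regardless of their cm scale (a raw-scale distance would be dominated by
# the ~70-85 cm trunk measurements); an unstandardized mode is available.

#' Locality mean profiles
#'
#' Per-locality arithmetic means of the fourteen measurements.
#'
#' @param herd A herd data frame covering at least 2 localities.
#' @return A tibble with `locality`, `n_animals` and one column per
#'   variable. Single-animal localities are allowed but flagged with a
#'   warning.
#' @examples
#' herd <- simulate_herd(herd_sim_spec(seed = 1))
#' locality_profiles(herd)
#' @export
locality_profiles <- function(herd) {
  herd <- validate_herd(herd, min_records = 2)
  if (dplyr::n_distinct(herd$locality) < 2) {
    abort("At least 2 localities are required (nothing to cluster).")
  }
  out <- herd |>
    dplyr::group_by(.data$locality) |>
    dplyr::summarise(
      n_animals = dplyr::n(),
      dplyr::across(dplyr::all_of(zoo_variables()), mean),
      .groups = "drop"
    )
  if (any(out$n_animals == 1)) {
    warn(paste0("Single-animal localit(ies): ",
                paste(out$locality[out$n_animals == 1], collapse = ", "),
                "; their profiles are single observations."))
  }
  out
}

#' Euclidean distance matrix among locality profiles
#'
#' @param profiles A tibble from [locality_profiles()].
#' @param standardize Z-score each variable across localities (sample SD)
#'   before distancing (default `TRUE`). A variable with zero
#'   across-locality variance is dropped from the standardized distance
#'   with a warning.
#' @return A symmetric matrix of Euclidean distances with zero diagonal and
#'   locality names as dimnames.
#' @examples
#' herd <- simulate_herd(herd_sim_spec(seed = 1))
#' locality_distances(locality_profiles(herd))
#' @export
locality_distances <- function(profiles, standardize = TRUE) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 2,
            "locality" %in% names(profiles))
  vars <- intersect(zoo_variables(), names(profiles))
  stopifnot(length(vars) > 0)
  m <- as.matrix(profiles[vars])
  rownames(m) <- profiles$locality
  if (standardize) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      warn(paste0("Dropping zero-variance variable(s) from standardized ",
                  "distance: ", paste(vars[sds == 0], collapse = ", ")))
      m <- m[, sds > 0, drop = FALSE]
    }
    m <- scale(m)
  }
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(d) <- list(profiles$locality, profiles$locality)
  d
}

#' Ward hierarchical clustering of localities
#'
#' Agglomerative clustering of a precomputed Euclidean distance matrix
#' under Ward's minimum-variance criterion (Lance-Williams recurrence on
#' squared distances, merge heights reported on the input-distance scale).
#' Labels are ordered lexicographically before clustering so ties merge
#' deterministically.
#'
#' @param dist A symmetric nonnegative matrix with zero diagonal (or a
#'   `dist` object) with locality labels.
#' @return A `locality_dendro` object wrapping the merge tree; heights are
#'   non-decreasing along merges.
#' @examples
#' dendro <- ward_cluster(ref_locality_distances())
#' dendro
#' @export
ward_cluster <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  stopifnot(is.matrix(dist), nrow(dist) >= 2)
  if (is.null(rownames(dist))) {
    dimnames(dist) <- list(paste0("L", seq_len(nrow(dist))),
                           paste0("L", seq_len(nrow(dist))))
  }
  if (max(abs(dist - t(dist))) > 1e-8) {
    abort("Distance matrix must be symmetric.")
  }
  if (any(diag(dist) != 0) || any(dist < 0)) {
    abort("Distances must be nonnegative with a zero diagonal.")
  }
  ord <- order(rownames(dist))
  dist <- dist[ord, ord]
  hc <- hclust(as.dist(dist), method = "ward.D2")
  structure(
    list(hclust = hc, labels = hc$labels,
         merge = hc$merge, height = hc$height),
    class = "locality_dendro"
  )
}

#' @export
print.locality_dendro <- function(x, ...) {
  cat(sprintf("Ward dendrogram over %d localities\n", length(x$labels)))
  first <- which(x$merge[1, ] < 0)
  cat(sprintf("  first merge: %s at height %.3f\n",
              paste(x$labels[-x$merge[1, first]], collapse = " ~ "),
              x$height[1]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.locality_dendro <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$height),
    member1 = x$merge[, 1],
    member2 = x$merge[, 2],
    height = x$height
  )
}

#' Cut a dendrogram into k clusters
#'
#' The partition obtained by undoing the last k - 1 merges.
#'
#' @param dendro A `locality_dendro`.
#' @param k Number of clusters, between 1 and the leaf count.
#' @return A tibble with `locality` and `cluster` (integer labels in
#'   dendrogram merge order).
#' @examples
#' cut_clusters(ward_cluster(ref_locality_distances()), k = 3)
#' @export
cut_clusters <- function(dendro, k) {
  stopifnot(inherits(dendro, "locality_dendro"))
  if (k < 1 || k > length(dendro$labels)) {
    abort(sprintf("k must be between 1 and %d.", length(dendro$labels)))
  }
  cl <- cutree(dendro$hclust, k = k)
  tibble::tibble(locality = names(cl), cluster = unname(cl))
}

#' Dendrogram-ordered z-score heatmap matrix
#'
#' Locality-by-variable matrix of per-variable z-scores (computed across
#' localities with the sample SD), rows ordered by the dendrogram leaf
#' order, so a monotone colour scale renders higher means lighter.
#'
#' @param profiles A tibble from [locality_profiles()].
#' @param dendro A `locality_dendro` over the same localities.
#' @return A numeric matrix (localities x variables).
#' @export
heatmap_matrix <- function(profiles, dendro) {
  stopifnot(is.data.frame(profiles), inherits(dendro, "locality_dendro"))
  if (!setequal(profiles$locality, dendro$labels)) {
    abort("Profiles and dendrogram cover different locality labels.")
  }
  vars <- intersect(zoo_variables(), names(profiles))
  m <- as.matrix(profiles[vars])
  rownames(m) <- profiles$locality
  z <- scale(m)
  z[is.nan(z)] <- 0  # zero-variance column: centred value is 0
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  leaf_order <- dendro$labels[dendro$hclust$order]
  z[leaf_order, , drop = FALSE]
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths place each leaf and internal node at its merge height.
#'
#' @param dendro A `locality_dendro`.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @examples
#' as_newick(ward_cluster(ref_locality_distances()))
#' @export
as_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "locality_dendro"))
  phy <- ape::as.phylo(dendro$hclust)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Plot a locality dendrogram or heatmap
#'
#' @param object A `locality_dendro`.
#' @param profiles Optional locality profiles; when supplied, a
#'   dendrogram-ordered z-score heatmap is drawn instead of the tree.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.locality_dendro <- function(object, profiles = NULL, ...) {
  if (!is.null(profiles)) {
    hm <- heatmap_matrix(profiles, object)
    df <- tibble::as_tibble(hm, rownames = "locality") |>
      tidyr::pivot_longer(-"locality", names_to = "variable",
                          values_to = "z") |>
      dplyr::mutate(
        locality = factor(.data$locality, levels = rownames(hm)),
        variable = factor(.data$variable, levels = zoo_variables())
      )
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$variable,
                                       y = .data$locality,
                                       fill = .data$z)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                      high = "#b2182b") +
        ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
        ggplot2::theme_minimal()
    )
  }
  seg <- dendro_segments(object$hclust)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(object$labels),
      labels = object$labels[object$hclust$order]
    ) +
    ggplot2::labs(x = NULL, y = "Merge height (Ward)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

# segment coordinates for a ggplot dendrogram
dendro_segments <- function(hc) {
  pos <- match(seq_along(hc$labels), hc$order)  # leaf -> x position
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  segs <- list()
  branch_xy <- function(idx) {
    if (idx < 0) c(pos[-idx], 0) else c(node_x[idx], node_y[idx])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- branch_xy(hc$merge[i, 1])
    b <- branch_xy(hc$merge[i, 2])
    node_x[i] <- mean(c(a[1], b[1]))
    segs[[length(segs) + 1]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], hc$height[i]),
      yend = c(hc$height[i], hc$height[i], hc$height[i])
    )
  }
  dplyr::bind_rows(segs)
}
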