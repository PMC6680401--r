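# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (loops, power iteration, from-scratch criterion
# recomputation) and never call the code paths they check.

# a small fully-specified herd with hand-controllable measurements
make_herd <- function(n = 3, locality = "A", ...) {
  base <- tibble::tibble(
    animal_id = sprintf("id%02d", seq_len(n)),
    locality = rep_len(locality, n),
    sex = "female",
    age_class = "adult"
  )
  for (v in zoo_variables()) base[[v]] <- seq(10, 20, length.out = n)
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}

# brute-force harmony count: double loop over cells
oracle_harmony_count <- function(cells, alpha = 0.05) {
  count <- 0L
  for (i in seq_len(nrow(cells))) {
    rho <- cells$rho[i]
    sig <- if ("p_value" %in% names(cells) && !all(is.na(cells$p_value))) {
      !is.na(cells$p_value[i]) && cells$p_value[i] < alpha
    } else {
      !is.na(cells$stars[i]) && nzchar(cells$stars[i])
    }
    if (!is.na(rho) && rho > 0 && sig) count <- count + 1L
  }
  count
}

# classical no-ties Spearman formula: 1 - 6 sum(d^2) / (n (n^2 - 1))
oracle_spearman_noties <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# power iteration with deflation: all eigenpairs of a symmetric PSD matrix
oracle_eigen <- function(m, iters = 5000) {
  p <- nrow(m)
  values <- numeric(p)
  vectors <- matrix(0, p, p)
  a <- m
  for (k in seq_len(p)) {
    v <- rep(1 / sqrt(p), p)
    for (i in seq_len(iters)) {
      w <- a %*% v
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      v <- as.numeric(w) / nw
    }
    lam <- as.numeric(t(v) %*% a %*% v)
    values[k] <- lam
    vectors[, k] <- v
    a <- a - lam * tcrossprod(v)
  }
  list(values = values, vectors = vectors)
}

# from-scratch Ward agglomeration on coordinates: at every step recompute
# the ESS increase of every candidate merge and take the minimum
oracle_ward <- function(coords) {
  ess <- function(rows) {
    if (length(rows) == 1) return(0)
    x <- coords[rows, , drop = FALSE]
    sum(scale(x, scale = FALSE)^2)
  }
  clusters <- as.list(seq_len(nrow(coords)))
  merges <- list()
  deltas <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        delta <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (is.null(best) || delta < best$delta - 1e-12) {
          best <- list(i = i, j = j, delta = delta)
        }
      }
    }
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best$i]], clusters[[best$j]]))
    deltas <- c(deltas, best$delta)
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
  }
  list(merges = merges, deltas = deltas)
}

# member sets produced by each merge of a locality_dendro, as row indices
# into the lexicographically ordered label set
dendro_merge_sets <- function(dendro) {
  sets <- list()
  out <- list()
  for (i in seq_len(nrow(dendro$merge))) {
    members <- unlist(lapply(dendro$merge[i, ], function(m) {
      if (m < 0) -m else sets[[m]]
    }))
    sets[[i]] <- sort(members)
    out[[i]] <- sets[[i]]
  }
  out
}

partition_sets <- function(partition) {
  unname(lapply(split(partition$locality, partition$cluster), sort))
}
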