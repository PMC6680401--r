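test_that("locality profiles are per-locality means", {
  herd <- make_herd(4, locality = c("A", "A", "B", "B"),
                    WH = c(60, 80, 65, 75))
  prof <- locality_profiles(herd)
  expect_equal(prof$WH[prof$locality == "A"], 70)
  expect_equal(prof$n_animals, c(2, 2))

  expect_error(locality_profiles(make_herd(5, locality = "only")),
               "2 localities")
  herd2 <- make_herd(3, locality = c("A", "A", "B"))
  expect_warning(locality_profiles(herd2), "Single-animal")
})

test_that("default synthetic herd yields the eight study localities", {
  herd <- simulate_herd(herd_sim_spec(seed = 27))
  prof <- locality_profiles(herd)
  sizes <- ref_locality_sizes()
  expect_identical(nrow(prof), 8L)
  expect_equal(prof$n_animals[match(sizes$locality, prof$locality)],
               sizes$n)
})

test_that("distances follow the Euclidean metric and z-score oracle", {
  p0 <- tibble::tibble(locality = c("a", "b"), HW = c(5, 5), HL = c(7, 7))
  expect_equal(unname(locality_distances(p0, standardize = FALSE)["a", "b"]),
               0)

  p1 <- tibble::tibble(locality = c("a", "b"), HW = c(0, 3), HL = c(0, 4))
  expect_equal(unname(locality_distances(p1, standardize = FALSE)["a", "b"]),
               5)

  # hand-computed standardized distance for three profiles, two variables:
  # HW (2, 4, 6): mean 4, sd 2 -> z (-1, 0, 1)
  # HL (10, 16, 10): mean 12, sd 2*sqrt(3) -> z (-1/sqrt(3), 2/sqrt(3), -1/sqrt(3))
  p2 <- tibble::tibble(locality = c("a", "b", "c"),
                       HW = c(2, 4, 6), HL = c(10, 16, 10))
  d <- locality_distances(p2)
  expect_equal(unname(d["a", "b"]), sqrt(1 + 3), tolerance = 1e-12)
  expect_equal(unname(d["a", "c"]), 2, tolerance = 1e-12)
  expect_equal(unname(d["b", "c"]), sqrt(1 + 3), tolerance = 1e-12)

  # permutation equivariance
  perm <- c(3, 1, 2)
  d_perm <- locality_distances(p2[perm, ])
  expect_equal(d_perm[p2$locality, p2$locality], d, tolerance = 1e-12)
})

test_that("zero-variance variables are dropped from standardized distances", {
  p <- tibble::tibble(locality = c("a", "b"), HW = c(3, 3), HL = c(1, 2))
  expect_warning(d <- locality_distances(p), "HW")
  expect_equal(unname(d["a", "b"]), sqrt(2), tolerance = 1e-12)
})

test_that("ward clustering matches a from-scratch criterion oracle", {
  set.seed(51)
  for (rep in 1:8) {
    n_leaves <- sample(4:8, 1)
    coords <- matrix(rnorm(n_leaves * 3), n_leaves, 3)
    rownames(coords) <- sprintf("L%02d", seq_len(n_leaves))
    d <- as.matrix(dist(coords))
    dendro <- ward_cluster(d)
    ora <- oracle_ward(coords)
    expect_equal(dendro_merge_sets(dendro), ora$merges)
    # ward.D2 heights relate to the ESS increase as sqrt(2 * delta)
    expect_equal(dendro$height, sqrt(2 * ora$deltas), tolerance = 1e-8)
  }
})

test_that("merge heights never invert on Euclidean inputs", {
  set.seed(52)
  for (rep in 1:10) {
    coords <- matrix(runif(8 * 4), 8, 4)
    dendro <- ward_cluster(as.matrix(dist(coords)))
    expect_true(all(diff(dendro$height) >= -1e-12))
  }
})

test_that("the reference distance matrix reproduces the study grouping", {
  d <- ref_locality_distances()
  dendro <- ward_cluster(d)
  first <- dendro$labels[-dendro$merge[1, ]]
  expect_setequal(first, c("Zapote Viejo", "Tlacote el Alto"))
  expect_equal(dendro$height[1], 2.34)

  part <- cut_clusters(dendro, 3)
  expect_setequal(partition_sets(part), list(
    c("Amazcala", "Norita", "Venado"),
    c("Mompani", "Tlacote el Alto", "Zapote Viejo"),
    c("Tlacote el Bajo", "Zapote")
  ))
})

test_that("tie-breaking is deterministic for equidistant points", {
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(c("b", "c", "a"), c("b", "c", "a"))
  d1 <- ward_cluster(d)
  d2 <- ward_cluster(d[c(2, 3, 1), c(2, 3, 1)])
  expect_identical(dendro_merge_sets(d1), dendro_merge_sets(d2))
  expect_identical(d1$labels, c("a", "b", "c"))
})

test_that("cut_clusters covers the degenerate cuts and rejects bad k", {
  dendro <- ward_cluster(ref_locality_distances())
  expect_identical(max(cut_clusters(dendro, 1)$cluster), 1L)
  expect_identical(sort(cut_clusters(dendro, 8)$cluster), 1:8)
  expect_error(cut_clusters(dendro, 0), "between")
  expect_error(cut_clusters(dendro, 9), "between")
})

test_that("heatmap matrix is z-scored and dendrogram-ordered", {
  herd <- simulate_herd(herd_sim_spec(seed = 28))
  prof <- locality_profiles(herd)
  dendro <- ward_cluster(locality_distances(prof))
  hm <- heatmap_matrix(prof, dendro)
  expect_identical(dim(hm), c(8L, 14L))
  expect_identical(rownames(hm), dendro$labels[dendro$hclust$order])
  expect_equal(unname(colMeans(hm)), rep(0, 14), tolerance = 1e-12)
  expect_equal(unname(apply(hm, 2, sd)), rep(1, 14), tolerance = 1e-12)

  p2 <- tibble::tibble(locality = c("a", "b"), HW = c(10, 20))
  small <- heatmap_matrix(p2, ward_cluster(
    locality_distances(p2, standardize = FALSE)))
  expect_equal(sort(unname(small[, "HW"])), c(-1, 1) / sqrt(2),
               tolerance = 1e-12)

  p3 <- tibble::tibble(locality = c("a", "b"), HW = c(10, 10), HL = c(3, 3))
  hm3 <- heatmap_matrix(p3, ward_cluster(
    locality_distances(p3, standardize = FALSE)))
  expect_true(all(hm3 == 0))

  expect_error(heatmap_matrix(prof[-1, ], dendro), "different")
})

test_that("newick export round-trips through ape", {
  dendro <- ward_cluster(ref_locality_distances())
  txt <- as_newick(dendro)
  phy <- ape::read.tree(text = txt)
  expect_setequal(gsub("_", " ", phy$tip.label), dendro$labels)
  expect_identical(ape::Ntip(phy), 8L)
})

test_that("dendrogram plots build", {
  herd <- simulate_herd(herd_sim_spec(seed = 29))
  prof <- locality_profiles(herd)
  dendro <- ward_cluster(locality_distances(prof))
  expect_s3_class(autoplot(dendro), "ggplot")
  expect_s3_class(autoplot(dendro, profiles = prof), "ggplot")
})
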