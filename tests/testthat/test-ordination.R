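test_that("dissimilarities match hand-evaluated Bray-Curtis and Jaccard", {
  prof <- tibble::tibble(
    plot_id = rep(c("x", "y"), each = 3),
    genus = rep(c("a", "b", "c"), 2),
    abundance = c(2, 1, 0, 1, 1, 1)
  )
  bc <- dissimilarity_matrix(prof, "bray")
  expect_equal(as.numeric(bc), (1 + 0 + 1) / (3 + 3))
  jc <- dissimilarity_matrix(prof, "jaccard")
  expect_equal(as.numeric(jc), 1 - 2 / 3)

  same <- tibble::tibble(plot_id = rep(c("x", "y"), each = 2),
                         genus = rep(c("a", "b"), 2), abundance = rep(3, 4))
  expect_equal(as.numeric(dissimilarity_matrix(same, "bray")), 0)
  disjoint <- tibble::tibble(plot_id = c("x", "y"), genus = c("a", "b"),
                             abundance = c(5, 4))
  expect_equal(as.numeric(dissimilarity_matrix(disjoint, "bray")), 1)
  expect_equal(as.numeric(dissimilarity_matrix(disjoint, "jaccard")), 1)
})

test_that("dissimilarity matrices are symmetric, bounded, and Bray on binary equals Sorensen", {
  set.seed(4)
  for (rep in 1:5) {
    m <- matrix(rpois(60, 3), nrow = 6,
                dimnames = list(paste0("p", 1:6), paste0("g", 1:10)))
    d <- as.matrix(dissimilarity_matrix(m, "bray"))
    expect_true(all(abs(d - t(d)) < 1e-12))
    expect_true(all(d >= 0 & d <= 1))
    expect_true(all(diag(d) == 0))
    # Bray-Curtis on presence-absence is the binary Sorensen dissimilarity
    pa <- (m > 0) * 1
    d_bc <- as.matrix(dissimilarity_matrix(pa, "bray"))
    sor <- matrix(0, 6, 6)
    for (i in 1:6) for (j in 1:6) {
      a <- sum(pa[i, ] & pa[j, ]); b <- sum(pa[i, ] > pa[j, ])
      c2 <- sum(pa[j, ] > pa[i, ])
      sor[i, j] <- (b + c2) / (2 * a + b + c2)
    }
    expect_equal(unname(d_bc), sor, tolerance = 1e-12)
  }
})

test_that("NMDS recovers embeddable configurations with vanishing stress", {
  set.seed(2)
  pts <- matrix(rnorm(12), ncol = 2) # 6 points in the plane
  d <- stats::dist(pts)
  o <- nmds(d, k = 2, n_starts = 10, seed = 1)
  expect_lt(o$stress, 1e-4)
  # k = n - 1 embeds any small metric configuration
  o5 <- nmds(stats::dist(matrix(rnorm(10), ncol = 2)), k = 4, n_starts = 10, seed = 1)
  expect_lt(o5$stress, 1e-4)
})

test_that("stress does not increase with dimensionality and seeds freeze scores", {
  ds <- generate_dataset(synth_config(seed = 8))
  prof <- genus_profiles(ds$counts, ds$samples)
  d <- dissimilarity_matrix(prof, "bray")
  s <- vapply(1:3, function(k) nmds(d, k = k, n_starts = 8, seed = 5)$stress,
              numeric(1))
  expect_true(all(diff(s) <= 1e-8))
  a <- nmds(d, k = 3, n_starts = 5, seed = 7)
  b <- nmds(d, k = 3, n_starts = 5, seed = 7)
  expect_identical(a$scores, b$scores)
  # scores are centred at the origin
  expect_true(all(abs(colMeans(as.matrix(a$scores[, -1]))) < 1e-8))
})

test_that("well-separated clusters stay separated in score space", {
  set.seed(31)
  # three clusters, each dominated by its own genus pair; small shared noise
  prof <- purrr::map_dfr(1:30, function(i) {
    cl <- (i - 1) %/% 10 + 1
    ab <- abs(rnorm(6, 1, 0.3))
    ab[(2 * cl - 1):(2 * cl)] <- ab[(2 * cl - 1):(2 * cl)] + 40
    tibble::tibble(plot_id = sprintf("p%02d", i), genus = letters[1:6],
                   abundance = ab)
  })
  o <- nmds(dissimilarity_matrix(prof, "bray"), k = 2, n_starts = 10, seed = 2)
  sc <- as.matrix(o$scores[, c("NMDS1", "NMDS2")])
  cl <- rep(1:3, each = 10)
  cent <- rowsum(sc, cl) / 10
  within_sd <- sqrt(mean(unlist(lapply(1:3, function(k) {
    apply(sc[cl == k, , drop = FALSE], 2, var)
  }))))
  dists <- as.matrix(stats::dist(cent))
  expect_true(all(dists[upper.tri(dists)] > within_sd))
})

test_that("vector fitting matches least squares and never returns p = 0", {
  ds <- generate_dataset(synth_config(seed = 17))
  prof <- genus_profiles(ds$counts, ds$samples)
  o <- nmds(dissimilarity_matrix(prof, "bray"), k = 3, n_starts = 8, seed = 3)
  vf <- fit_genus_vectors(o, prof, n_perm = 99, seed = 9)
  expect_true(all(vf$r2 >= 0 & vf$r2 <= 1))
  expect_true(all(vf$p > 0 & vf$p <= 1))

  # independent oracle: vegan envfit r2 on the same scores
  comm <- community_matrix(prof)[o$scores$plot_id, ]
  sc <- as.matrix(o$scores[, c("NMDS1", "NMDS2", "NMDS3")])
  ev <- vegan::envfit(sc, comm, permutations = 0, choices = 1:3)
  expect_equal(vf$r2[match(names(ev$vectors$r), vf$genus)],
               unname(ev$vectors$r), tolerance = 1e-8)

  # abundance equal to an axis gives r2 = 1; constant abundance r2 = 0, p = 1
  toy <- purrr::map_dfr(seq_len(nrow(o$scores)), function(i) {
    tibble::tibble(
      plot_id = o$scores$plot_id[i],
      genus = c("axisg", "constg"),
      abundance = c(o$scores$NMDS1[i] + 10, 5)
    )
  })
  vf2 <- fit_genus_vectors(o, toy, n_perm = 99, seed = 1)
  expect_gt(vf2$r2[vf2$genus == "axisg"], 1 - 1e-9)
  expect_equal(vf2$r2[vf2$genus == "constg"], 0)
  expect_equal(vf2$p[vf2$genus == "constg"], 1)
})

test_that("indicator values flag perfect and balanced indicators correctly", {
  # genus occurring in every plot of exactly one group and nowhere else
  prof <- tibble::tibble(
    plot_id = sprintf("p%02d", 1:20),
    genus = "only",
    abundance = c(rep(4, 10), rep(0, 10))
  )
  filler <- tibble::tibble(plot_id = sprintf("p%02d", 1:20), genus = "bg",
                           abundance = 1)
  groups <- tibble::tibble(plot_id = sprintf("p%02d", 1:20),
                           group = rep(c("lo", "hi"), each = 10))
  ia <- indicator_analysis(dplyr::bind_rows(prof, filler), groups,
                           n_perm = 99, seed = 2)
  perfect <- ia[ia$genus == "only" & ia$groups == "lo", ]
  expect_equal(perfect$A, 1); expect_equal(perfect$B, 1)
  expect_equal(perfect$stat, 1)
  expect_lte(perfect$p, 0.05)
  # equal mean abundance in two equal groups, present everywhere
  even <- ia[ia$genus == "bg" & ia$groups == "lo", ]
  expect_equal(even$A, 0.5); expect_equal(even$B, 1)
  expect_equal(even$stat, sqrt(0.5), tolerance = 1e-12)
  expect_true(all(ia$p > 0))
  # fixed seeds reproduce p exactly
  ia2 <- indicator_analysis(dplyr::bind_rows(prof, filler), groups,
                            n_perm = 99, seed = 2)
  expect_identical(ia$p, ia2$p)
})

test_that("SD ellipse areas follow the principal-axis eigenvalues", {
  set.seed(12)
  z <- matrix(rnorm(400), ncol = 2)
  z <- scale(z, scale = FALSE)
  z <- z %*% solve(chol(stats::cov(z))) # exact identity sample covariance
  sc <- z %*% diag(c(0.5, 0.2))         # principal SDs 0.5 and 0.2
  scores <- tibble::tibble(plot_id = as.character(1:200),
                           NMDS1 = sc[, 1], NMDS2 = sc[, 2])
  area <- sd_ellipse_area(scores, rep("g", 200))
  expect_equal(area$area, pi * 0.1, tolerance = 1e-9)
  # scaling scores by c scales areas by c^2
  scores2 <- dplyr::mutate(scores, NMDS1 = NMDS1 * 3, NMDS2 = NMDS2 * 3)
  area2 <- sd_ellipse_area(scores2, rep("g", 200))
  expect_equal(area2$area, 9 * area$area, tolerance = 1e-9)
  # collinear scores are degenerate
  flat <- tibble::tibble(plot_id = as.character(1:10), NMDS1 = 1:10,
                         NMDS2 = 2 * (1:10))
  expect_equal(sd_ellipse_area(flat, rep("g", 10))$area, 0, tolerance = 1e-9)
})
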