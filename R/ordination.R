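#' Plot-by-genus community matrix
#'
#' @param profiles Long profile tibble (`plot_id`, `genus`, `abundance`),
#'   e.g. from [genus_profiles()].
#' @return A numeric matrix, plots in rows (rownames = plot ids), genera in
#'   columns, zero-filled.
#' @export
community_matrix <- function(profiles) {
  wide <- profiles %>%
    tidyr::pivot_wider(
      id_cols = "plot_id", names_from = "genus",
      values_from = "abundance", values_fill = 0, values_fn = sum
    )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$plot_id
  m
}

#' Pairwise community dissimilarity
#'
#' Bray-Curtis dissimilarity on abundances,
#' \eqn{d(x,y) = \sum |x_g - y_g| / \sum (x_g + y_g)}, or the Jaccard
#' dissimilarity \eqn{1 - |X \cap Y| / |X \cup Y|} on presence-absence.
#' Pairs of all-empty profiles have no defined dissimilarity and yield
#' `NaN` entries.
#'
#' @inheritParams community_matrix
#' @param method `"bray"` (abundance) or `"jaccard"` (presence-absence).
#' @return A `stats::dist` object with a `method_tag` attribute.
#' @export
dissimilarity_matrix <- function(profiles, method = c("bray", "jaccard")) {
  method <- match.arg(method)
  m <- if (is.matrix(profiles)) profiles else community_matrix(profiles)
  if (nrow(m) < 2) {
    abort("need at least two profiles", class = "nemacomm_input_error")
  }
  d <- if (method == "bray") {
    vegan::vegdist(m, method = "bray")
  } else {
    vegan::vegdist(m, method = "jaccard", binary = TRUE)
  }
  attr(d, "method_tag") <- method
  d
}

#' Non-metric multidimensional scaling of a community dissimilarity matrix
#'
#' Rank-based ordination minimising Kruskal stress-1 (monotone regression of
#' configuration distances on observed dissimilarities), run from multiple
#' random starts and returned centred and rotated to principal axes.
#' Backed by [vegan::metaMDS()]; the seed makes the solution reproducible
#' bit for bit.
#'
#' @param d A dissimilarity matrix from [dissimilarity_matrix()] (or any
#'   `dist`).
#' @param k Number of ordination dimensions (default 3).
#' @param n_starts Maximum number of random starts (default 20).
#' @param seed Integer seed.
#' @return An object of class `nema_nmds`: list with `scores` (tibble:
#'   `plot_id`, `NMDS1..NMDSk`), `stress` (Kruskal stress-1 in [0, 1]),
#'   `converged` (logical), `n_starts`, `k` and the underlying `engine` fit.
#' @export
nmds <- function(d, k = 3, n_starts = 20, seed = 1) {
  stopifnot(inherits(d, "dist"), k >= 1)
  # near-saturated settings (k close to n) can make the engine collapse to a
  # degenerate configuration; retry deterministically from shifted seeds
  fit <- NULL
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        vegan::metaMDS(d, k = k, trymax = n_starts, trace = 0,
                       autotransform = FALSE, wascores = FALSE)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort("NMDS failed to produce a configuration", class = "nemacomm_nmds_error")
  }
  sc <- vegan::scores(fit, display = "sites")
  sc <- sweep(sc, 2, colMeans(sc))
  ids <- rownames(sc)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(sc)))
  scores <- dplyr::bind_cols(tibble(plot_id = ids), as_tibble(sc))
  structure(
    list(scores = scores, stress = fit$stress,
         converged = isTRUE(fit$converged > 0 | isTRUE(fit$converged)),
         n_starts = n_starts, k = k, engine = fit),
    class = "nema_nmds"
  )
}

#' @export
print.nema_nmds <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d plots, k = %d, stress = %.4f (%s)\n",
              nrow(x$scores), x$k, x$stress,
              if (x$converged) "converged" else "no convergent solution"))
  invisible(x)
}

#' @rdname nmds
#' @param x A `nema_nmds` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nema_nmds <- function(x, ...) x$scores

#' @rdname nmds
#' @exportS3Method generics::glance
glance.nema_nmds <- function(x, ...) {
  tibble(stress = x$stress, converged = x$converged,
         n_starts = x$n_starts, k = x$k, n = nrow(x$scores))
}

#' Ordination plot with per-group SD ellipses
#'
#' @param object A `nema_nmds` object.
#' @param groups Optional grouping: a vector aligned with the plots or a
#'   tibble with `plot_id` and `group` columns.
#' @param axes Which two axes to draw (default 1 and 2).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nema_nmds <- function(object, groups = NULL, axes = c(1, 2), ...) {
  df <- object$scores
  ax <- paste0("NMDS", axes)
  df$.x <- df[[ax[1]]]; df$.y <- df[[ax[2]]]
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      df <- left_join(df, groups, by = "plot_id")
    } else {
      df$group <- groups
    }
    df$group <- factor(df$group)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$.x, .data$.y, colour = .data$group)) +
      ggplot2::stat_ellipse(level = 0.68)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$.x, .data$.y))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = ax[1], y = ax[2],
                  subtitle = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Fit genus abundance vectors to an ordination
#'
#' For every genus, regresses its abundance on the ordination axes,
#' reporting the squared multiple correlation r2, the fitted direction
#' cosines on the axes, and a permutation p-value from random row
#' permutations of the abundance vector with the add-one estimator
#' `p = (1 + #{r2_perm >= r2}) / (1 + n_perm)` (p is never 0).
#' Genera with constant abundance get r2 = 0 and p = 1.
#'
#' @param ordination A `nema_nmds` object.
#' @param profiles Long profile tibble covering the ordinated plots.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Tibble: `genus`, direction cosines `NMDS1..NMDSk`, `r2`, `p`.
#' @export
fit_genus_vectors <- function(ordination, profiles, n_perm = 999, seed = 1) {
  stopifnot(inherits(ordination, "nema_nmds"))
  m <- community_matrix(profiles)
  ids <- ordination$scores$plot_id
  if (!all(ids %in% rownames(m))) {
    abort("profiles do not cover all ordinated plots",
          class = "nemacomm_input_error")
  }
  m <- m[ids, , drop = FALSE]
  S <- as.matrix(ordination$scores[, paste0("NMDS", seq_len(ordination$k))])
  Sc <- sweep(S, 2, colMeans(S))
  qrS <- qr(Sc)
  Q <- qr.Q(qrS)
  n <- nrow(Sc)

  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))

  purrr::map_dfr(colnames(m), function(g) {
    y <- m[, g]
    yc <- y - mean(y)
    ss <- sum(yc^2)
    axes <- setNames(rep(NA_real_, ncol(S)), colnames(S))
    if (ss == 0) {
      return(dplyr::bind_cols(tibble(genus = g), as_tibble(t(axes)),
                              tibble(r2 = 0, p = 1)))
    }
    r2 <- sum(crossprod(Q, yc)^2) / ss
    b <- qr.coef(qrS, yc)
    b[is.na(b)] <- 0
    nb <- sqrt(sum(b^2))
    if (nb > 0) axes[] <- b / nb
    Yp <- matrix(yc[perms], nrow = n)
    r2p <- colSums(crossprod(Q, Yp)^2) / ss
    p <- (1 + sum(r2p >= r2)) / (1 + n_perm)
    dplyr::bind_cols(tibble(genus = g), as_tibble(t(axes)),
                     tibble(r2 = r2, p = p))
  })
}

# all non-empty proper subsets of group levels, ordered by size then lex
group_combos <- function(levels, max_order) {
  combos <- list()
  for (k in seq_len(min(max_order, length(levels) - 1))) {
    cc <- combn(levels, k, simplify = FALSE)
    combos <- c(combos, cc)
  }
  combos
}

indval_stats <- function(m, f, combos) {
  lev <- levels(f)
  grp_mean <- apply(m, 2, function(y) tapply(y, f, mean))        # L x g
  pres <- m > 0
  out <- lapply(combos, function(G) {
    in_g <- f %in% G
    pooled_mean <- colMeans(m[in_g, , drop = FALSE])
    other <- setdiff(lev, G)
    denom <- pooled_mean +
      if (length(other) > 0) colSums(grp_mean[other, , drop = FALSE]) else 0
    A <- ifelse(denom > 0, pooled_mean / denom, 0)
    B <- colMeans(pres[in_g, , drop = FALSE])
    list(A = A, B = B, stat = sqrt(A * B))
  })
  out
}

#' Indicator-value analysis of genera across groups
#'
#' For every genus and every group (or combination of groups) G, computes
#' the indicator value IndVal = sqrt(A * B), where A (specificity) is the
#' mean abundance in the pooled plots of G divided by the sum of that mean
#' and the per-group mean abundances outside G, and B (fidelity) is the
#' fraction of plots in G where the genus occurs. Significance is assessed
#' by permuting group labels (add-one p, never 0). Genera absent from all
#' plots are excluded.
#'
#' @inheritParams fit_genus_vectors
#' @param profiles Long profile tibble.
#' @param groups Grouping: tibble with `plot_id` and `group`, or a vector
#'   named by (or aligned with) the plot ids in the community matrix.
#' @param max_order Largest size of group combinations to scan (default all
#'   proper subsets).
#' @return Tibble with one row per genus x group set: `genus`, `groups`
#'   (labels joined by `+`), `A`, `B`, `stat`, `p`, and `best` marking each
#'   genus's highest-statistic group set.
#' @export
indicator_analysis <- function(profiles, groups, n_perm = 999, seed = 1,
                               max_order = NULL) {
  m <- community_matrix(profiles)
  if (is.data.frame(groups)) {
    idx <- match(rownames(m), groups$plot_id)
    if (anyNA(idx)) abort("groups must cover all profiled plots",
                          class = "nemacomm_input_error")
    f <- factor(groups$group[idx])
  } else {
    if (!is.null(names(groups))) groups <- groups[rownames(m)]
    f <- factor(groups)
  }
  if (nlevels(f) < 2) abort("need at least two groups",
                            class = "nemacomm_input_error")
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (is.null(max_order)) max_order <- nlevels(f) - 1
  combos <- group_combos(levels(f), max_order)

  obs <- indval_stats(m, f, combos)
  set.seed(seed)
  exceed <- lapply(obs, function(o) rep(0L, length(o$stat)))
  for (b in seq_len(n_perm)) {
    fp <- f[sample.int(length(f))]
    perm <- indval_stats(m, fp, combos)
    for (j in seq_along(combos)) {
      exceed[[j]] <- exceed[[j]] + (perm[[j]]$stat >= obs[[j]]$stat)
    }
  }
  res <- purrr::map_dfr(seq_along(combos), function(j) {
    tibble(
      genus = colnames(m),
      groups = paste(combos[[j]], collapse = "+"),
      A = unname(obs[[j]]$A), B = unname(obs[[j]]$B),
      stat = unname(obs[[j]]$stat),
      p = unname((1 + exceed[[j]]) / (1 + n_perm))
    )
  })
  res %>%
    group_by(.data$genus) %>%
    mutate(best = dplyr::row_number(dplyr::desc(.data$stat)) == 1 & .data$stat > 0) %>%
    ungroup()
}

#' Standard-deviation ellipse area of group ordination scores
#'
#' For each group, the area pi * s1 * s2, where s1 and s2 are the standard
#' deviations of the group's scores along the principal axes of its 2-D
#' score covariance (ordination axes 1 and 2). Groups whose scores are
#' collinear get area 0.
#'
#' @param ordination A `nema_nmds` object, or a tibble with `plot_id`,
#'   `NMDS1`, `NMDS2` columns.
#' @param groups Grouping as in [indicator_analysis()].
#' @param axes Which two axes to use (default 1 and 2).
#' @return Tibble: `group`, `n`, `area`. Groups with fewer than 3 plots are
#'   dropped with a warning.
#' @export
sd_ellipse_area <- function(ordination, groups, axes = c(1, 2)) {
  scores <- if (inherits(ordination, "nema_nmds")) ordination$scores else ordination
  ax <- paste0("NMDS", axes)
  stopifnot(all(ax %in% names(scores)))
  if (is.data.frame(groups)) {
    idx <- match(scores$plot_id, groups$plot_id)
    g <- factor(groups$group[idx])
  } else {
    g <- factor(groups)
  }
  res <- purrr::map_dfr(levels(g), function(lv) {
    sub <- as.matrix(scores[g == lv, ax])
    if (nrow(sub) < 3) return(tibble(group = lv, n = nrow(sub), area = NA_real_))
    ev <- eigen(stats::cov(sub), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    tibble(group = lv, n = nrow(sub), area = pi * sqrt(prod(ev)))
  })
  dropped <- res$group[is.na(res$area)]
  if (length(dropped) > 0) {
    warn(paste0("group(s) with fewer than 3 plots dropped: ",
                paste(dropped, collapse = ", ")))
    res <- filter(res, !is.na(.data$area))
  }
  res
}
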