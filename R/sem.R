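#' Specify a piecewise structural equation model
#'
#' A piecewise SEM is a directed acyclic graph over named variables, fitted
#' as one (mixed-effects) regression per endogenous variable and judged as a
#' whole through the independence claims the graph implies. Supply one
#' formula per endogenous variable (`y ~ x1 + x2`); exogenous variables
#' appear only on right-hand sides. Pairs listed in `correlated` are treated
#' as having correlated errors: no directed path is claimed between them and
#' they are excluded from the d-separation basis set.
#'
#' @param formulas A list of component-model formulas.
#' @param correlated List of length-2 character vectors naming
#'   correlated-error pairs.
#' @param random Character vector of random-intercept grouping factors
#'   present in the data (default `c("block", "mixture_id")`); use `NULL`
#'   for ordinary least squares components.
#' @return An object of class `nema_sem_model`.
#' @examples
#' m <- sem_model(list(y ~ x, z ~ y), random = NULL)
#' basis_set(m) # one claim: x _||_ z | y
#' @export
sem_model <- function(formulas, correlated = list(),
                      random = c("block", "mixture_id")) {
  stopifnot(is.list(formulas), all(vapply(formulas, inherits, TRUE, "formula")))
  edges <- purrr::map_dfr(formulas, function(f) {
    y <- as.character(f[[2]])
    xs <- all.vars(f[[3]])
    tibble(from = xs, to = y)
  })
  if (anyDuplicated(vapply(formulas, function(f) as.character(f[[2]]), ""))) {
    abort("each endogenous variable may have only one component model",
          class = "nemacomm_sem_error")
  }
  nodes <- unique(c(edges$from, edges$to))
  parents <- lapply(setNames(nodes, nodes), function(v) edges$from[edges$to == v])
  order <- topo_sort(nodes, edges)
  for (pr in correlated) {
    stopifnot(length(pr) == 2, all(pr %in% nodes))
  }
  structure(
    list(nodes = nodes, edges = edges, parents = parents,
         correlated = correlated, random = random, order = order),
    class = "nema_sem_model"
  )
}

# Kahn's algorithm; stable in declaration order; errors on cycles
topo_sort <- function(nodes, edges) {
  indeg <- setNames(vapply(nodes, function(v) sum(edges$to == v), 0L), nodes)
  out <- character(0)
  avail <- nodes[indeg[nodes] == 0]
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    kids <- edges$to[edges$from == v]
    for (w in kids) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(out) != length(nodes)) {
    abort("model graph contains a cycle", class = "nemacomm_sem_error")
  }
  out
}

#' D-separation basis set of a piecewise SEM
#'
#' Every pair of non-adjacent variables, conditioned on the union of both
#' variables' parents, forms an independence claim that the model asserts.
#' The downstream variable (in topological order) is the claim's response;
#' correlated-error pairs are exempt.
#'
#' @param model A [sem_model()].
#' @return Tibble: `x` (putative independent cause), `y` (response),
#'   `conditioning` (list-column of conditioning variable names).
#' @export
basis_set <- function(model) {
  stopifnot(inherits(model, "nema_sem_model"))
  nodes <- model$order
  adj <- paste(model$edges$from, model$edges$to)
  corr <- vapply(model$correlated, function(p) paste(sort(p), collapse = " "), "")
  out <- list()
  if (length(nodes) >= 2) {
    for (i in seq_len(length(nodes) - 1)) {
      for (j in seq(i + 1, length(nodes))) {
        u <- nodes[i]; v <- nodes[j]
        if (paste(u, v) %in% adj || paste(v, u) %in% adj) next
        if (paste(sort(c(u, v)), collapse = " ") %in% corr) next
        cond <- setdiff(unique(c(model$parents[[u]], model$parents[[v]])), c(u, v))
        out[[length(out) + 1]] <- tibble(
          x = u, y = v, conditioning = list(cond)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(x = character(0), y = character(0), conditioning = list()))
  }
  bind_rows(out)
}

#' Fisher's C statistic
#'
#' Combines the p-values of the d-separation claims:
#' \eqn{C = -2 \sum \ln p_i}, chi-square distributed with 2k degrees of
#' freedom under the model. A fit p-value above 0.05 indicates the data are
#' consistent with the hypothesised causal structure. An empty claim set
#' (saturated model) gives C = 0 with fit p = 1.
#'
#' @param pvals Numeric vector of claim p-values in (0, 1].
#' @return One-row tibble: `c`, `df`, `p`.
#' @examples
#' fisher_c(c(0.5, 0.5)) # C = 2.77, df = 4
#' @export
fisher_c <- function(pvals) {
  if (length(pvals) == 0) return(tibble(c = 0, df = 0L, p = 1))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("claim p-values must lie in (0, 1]; floor zero p upstream",
          class = "nemacomm_input_error")
  }
  C <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  tibble(c = C, df = df, p = pchisq(C, df, lower.tail = FALSE))
}

quiet_fit <- function(formula_str, data, random) {
  if (length(random) > 0) {
    re <- paste(sprintf("(1 | %s)", random), collapse = " + ")
    f <- as.formula(paste(formula_str, "+", re))
    withCallingHandlers(
      suppressMessages(lme4::lmer(f, data = data, REML = FALSE)),
      warning = function(w) invokeRestart("muffleWarning")
    )
  } else {
    lm(as.formula(formula_str), data = data)
  }
}

loglik_of <- function(fit) as.numeric(logLik(fit))

lrt_p <- function(full, reduced) {
  chi2 <- max(0, 2 * (loglik_of(full) - loglik_of(reduced)))
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = max(p, 1e-300))
}

r2_variance_parts <- function(fit) {
  if (inherits(fit, "merMod")) {
    X <- lme4::getME(fit, "X")
    var_f <- var(as.vector(X %*% lme4::fixef(fit)))
    vc <- lme4::VarCorr(fit)
    var_r <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
    var_e <- attr(vc, "sc")^2
  } else {
    var_f <- var(fitted(fit))
    var_r <- 0
    var_e <- summary(fit)$sigma^2
  }
  tot <- var_f + var_r + var_e
  list(r2_marginal = if (tot > 0) var_f / tot else NA_real_,
       r2_conditional = if (tot > 0) (var_f + var_r) / tot else NA_real_)
}

#' Fit a piecewise structural equation model
#'
#' Each endogenous variable's component model is fit by maximum likelihood
#' with the model's random intercepts. Per directed path the raw
#' coefficient, the standardized coefficient `b * sd(x) / sd(y)` (on the
#' analysis scales) and a single-df likelihood-ratio p-value are reported;
#' per component model the marginal R2 (fixed effects over total variance)
#' and conditional R2 (fixed + random); each d-separation claim is tested by
#' adding the claimed-independent cause to the response's conditioning model
#' and t-testing its coefficient (REML fits with Satterthwaite degrees of
#' freedom); model-level fit is Fisher's C over the claim p-values.
#' Rows with missing values in any model variable are dropped (count
#' reported), mirroring analyses restricted to plots with complete root
#' data.
#'
#' @param model A [sem_model()].
#' @param data Tibble containing every model variable plus the random-effect
#'   grouping columns.
#' @return Object of class `nema_sem` with elements `paths`, `components`,
#'   `claims`, `fisher` (tibble `c`, `df`, `p`), `n`, `n_dropped`.
#' @export
fit_piecewise_sem <- function(model, data) {
  stopifnot(inherits(model, "nema_sem_model"))
  vars <- model$nodes
  missing_vars <- setdiff(c(vars, model$random), names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("data lacks model variable(s): ",
                 paste(missing_vars, collapse = ", ")),
          class = "nemacomm_sem_error")
  }
  keep <- stats::complete.cases(data[, c(vars, model$random)])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]

  cache <- new.env(parent = emptyenv())
  fit_cached <- function(y, xs) {
    rhs <- if (length(xs) == 0) "1" else paste(sort(xs), collapse = " + ")
    key <- paste(y, "~", rhs)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- quiet_fit(key, d, model$random)
    cache[[key]] <- fit
    fit
  }

  endo <- unique(model$edges$to)
  paths <- list()
  components <- list()
  for (y in endo) {
    px <- model$parents[[y]]
    full <- fit_cached(y, px)
    beta <- if (inherits(full, "merMod")) lme4::fixef(full) else coef(full)
    r2 <- r2_variance_parts(full)
    components[[y]] <- tibble(
      response = y,
      r2_marginal = r2$r2_marginal, r2_conditional = r2$r2_conditional,
      singular = inherits(full, "merMod") && lme4::isSingular(full)
    )
    for (x in px) {
      red <- fit_cached(y, setdiff(px, x))
      lr <- lrt_p(full, red)
      est <- unname(beta[x])
      paths[[paste(y, x)]] <- tibble(
        response = y, term = x, estimate = est,
        std_estimate = est * sd(d[[x]]) / sd(d[[y]]),
        chi2 = lr$chi2, p = lr$p
      )
    }
  }

  # claims: REML fits with Satterthwaite-df t-tests of the added cause --
  # better calibrated at moderate n than ML likelihood-ratio tests, whose
  # slight liberality would accumulate over the basis set into Fisher's C
  claim_cache <- new.env(parent = emptyenv())
  claim_fit <- function(y, xs) {
    rhs <- if (length(xs) == 0) "1" else paste(sort(xs), collapse = " + ")
    key <- paste(y, "~", rhs)
    if (!is.null(claim_cache[[key]])) return(claim_cache[[key]])
    fit <- if (length(model$random) > 0) {
      re <- paste(sprintf("(1 | %s)", model$random), collapse = " + ")
      withCallingHandlers(
        suppressMessages(lmerTest::lmer(as.formula(paste(key, "+", re)),
                                        data = d, REML = TRUE)),
        warning = function(w) invokeRestart("muffleWarning")
      )
    } else {
      lm(as.formula(key), data = d)
    }
    claim_cache[[key]] <- fit
    fit
  }
  claims_spec <- basis_set(model)
  claims <- purrr::map_dfr(seq_len(nrow(claims_spec)), function(i) {
    x <- claims_spec$x[i]; y <- claims_spec$y[i]
    cond <- claims_spec$conditioning[[i]]
    fit <- claim_fit(y, c(cond, x))
    cf <- suppressMessages(summary(fit))$coefficients
    pcol <- grep("^Pr", colnames(cf), value = TRUE)[1]
    tibble(x = x, y = y,
           conditioning = paste(cond, collapse = " + "),
           statistic = cf[x, "t value"],
           p = max(cf[x, pcol], 1e-300))
  })
  if (nrow(claims) == 0) {
    claims <- tibble(x = character(0), y = character(0),
                     conditioning = character(0),
                     statistic = numeric(0), p = numeric(0))
  }
  fc <- fisher_c(claims$p)

  structure(
    list(model = model, paths = bind_rows(paths),
         components = bind_rows(components), claims = claims,
         fisher = fc, n = nrow(d), n_dropped = n_dropped),
    class = "nema_sem"
  )
}

#' @export
print.nema_sem <- function(x, ...) {
  cat(sprintf(
    "Piecewise SEM: %d observations (%d dropped), %d paths, %d claims\n",
    x$n, x$n_dropped, nrow(x$paths), nrow(x$claims)
  ))
  cat(sprintf("Fisher's C = %.2f, df = %d, p = %.3f\n",
              x$fisher$c, x$fisher$df, x$fisher$p))
  invisible(x)
}

#' @rdname fit_piecewise_sem
#' @param x A `nema_sem` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nema_sem <- function(x, ...) x$paths

#' @rdname fit_piecewise_sem
#' @exportS3Method generics::glance
glance.nema_sem <- function(x, ...) {
  tibble(
    fisher_c = x$fisher$c, df = x$fisher$df, p = x$fisher$p,
    n = x$n, n_dropped = x$n_dropped, n_claims = nrow(x$claims)
  )
}

#' Default trophic-abundance SEM
#'
#' The causal structure linking sown plant species richness (log scale) to
#' trophic-group abundances: richness drives the plant and soil layer
#' (shoot mass, root mass, specific root length, leaf C/N, soil organic
#' carbon); bacterial feeders respond to soil carbon (resource quantity via
#' microbial biomass); plant feeders to leaf C/N (resource quality, +) and
#' shoot mass (-); omnivores+predators to both prey pools. Bacterial- and
#' plant-feeder abundances share a correlated error: both are measured from
#' the same identification subsample, so their measured shares are
#' compositionally dependent.
#'
#' Analysis scales follow the transformation ledger: `log_bf` and
#' `log_ompr` are log abundances, `pf` is untransformed.
#'
#' @return A `nema_sem_model`.
#' @export
sem_model_trophic <- function() {
  sem_model(
    list(
      shoot_mass ~ log_sr,
      root_mass ~ log_sr,
      srl ~ log_sr,
      cn_leaf ~ log_sr,
      soil_corg ~ log_sr,
      log_bf ~ soil_corg,
      pf ~ cn_leaf + shoot_mass,
      log_ompr ~ log_bf + pf
    ),
    correlated = list(c("log_bf", "pf"))
  )
}

#' Assemble the SEM analysis table from a dataset and its indices
#'
#' Joins plot covariates with community metrics and adds the transformed
#' analysis columns used by the SEM and mixed-model functions: `log_sr`
#' (log sown richness), `log_bf`, `log_ompr` (log trophic abundances, `NA`
#' where the abundance is 0), alongside the untransformed metrics.
#'
#' @param dataset A `nema_dataset` from [generate_dataset()], or a list with
#'   `covariates`, `counts`, `samples` tibbles.
#' @param indices Optional precomputed [compute_indices()] table.
#' @param annotations,weights Passed to [compute_indices()] when `indices`
#'   is not supplied.
#' @return One row per plot with design, covariate and metric columns.
#' @export
sem_data <- function(dataset, indices = NULL,
                     annotations = default_annotations(),
                     weights = default_guild_weights()) {
  if (is.null(indices)) {
    indices <- compute_indices(dataset$counts, dataset$samples,
                               annotations, weights,
                               covariates = dataset$covariates)
  }
  safe_log <- function(x) ifelse(!is.na(x) & x > 0, log(x), NA_real_)
  dataset$covariates %>%
    left_join(select(indices, -dplyr::any_of("root_mass")), by = "plot_id") %>%
    mutate(
      log_sr = log(.data$sown_richness),
      log_bf = safe_log(.data$bf),
      log_ompr = safe_log(.data$ompr)
    )
}
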