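#' Response transformation ledger
#'
#' Variance-stabilising transformations applied before mixed-model and SEM
#' analysis. Natural log for the abundances of bacterial feeders, fungal
#' feeders and omnivores+predators, the predator-prey ratio and the c-p 1+2
#' and c-p 4 class abundances; square root for fungal-feeder genus richness
#' and the c-p 3 and c-p 5 class abundances; identity otherwise (total
#' abundance, plant feeders, Shannon diversity, channel ratio, the guild
#' indices, ...). Sown species richness always enters models as
#' `log(sown_richness)` and is handled in the model formula, not here.
#' The ledger is a tibble and can be replaced wholesale.
#'
#' @return Tibble with columns `response`, `transform`
#'   (`"log"`, `"sqrt"` or `"identity"`).
#' @export
default_transforms <- function() {
  tibble(
    response = c("bf", "ff", "ompr", "predator_prey", "cp12", "cp4",
                 "ff_rich", "cp3", "cp5"),
    transform = c(rep("log", 6), rep("sqrt", 3))
  )
}

#' Apply the transformation ledger to a response
#'
#' @param values Numeric vector.
#' @param response Response name looked up in the ledger; unlisted names get
#'   the identity.
#' @param transforms Ledger tibble (see [default_transforms()]).
#' @param labels Optional labels (e.g. plot ids) used in error messages.
#' @return Transformed numeric vector.
#' @examples
#' transform_response(100, "bf") # log(100)
#' transform_response(9, "ff_rich") # 3
#' transform_response(9, "pf") # unchanged
#' @export
transform_response <- function(values, response,
                               transforms = default_transforms(),
                               labels = NULL) {
  tag <- transforms$transform[match(response, transforms$response)]
  if (is.na(tag)) tag <- "identity"
  if (is.null(labels)) labels <- as.character(seq_along(values))
  switch(
    tag,
    identity = values,
    sqrt = {
      if (any(values < 0, na.rm = TRUE)) {
        abort(paste0("negative value under sqrt transform for '", response,
                     "' at: ",
                     paste(labels[which(values < 0)], collapse = ", ")),
              class = "nemacomm_transform_error")
      }
      sqrt(values)
    },
    log = {
      bad <- which(values <= 0)
      if (length(bad) > 0) {
        abort(paste0("nonpositive value under log transform for '", response,
                     "' at: ", paste(labels[bad], collapse = ", ")),
              class = "nemacomm_transform_error")
      }
      log(values)
    },
    abort(paste0("unknown transform tag: ", tag), class = "nemacomm_transform_error")
  )
}

fit_lmm_pair <- function(data, resp_col, fixed_term) {
  null_f <- as.formula(paste(resp_col, "~ 1 + (1 | block) + (1 | mixture_id)"))
  full_f <- as.formula(paste(resp_col, "~", fixed_term,
                             "+ (1 | block) + (1 | mixture_id)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  quiet_lmer <- function(f) {
    withCallingHandlers(
      suppressMessages(lme4::lmer(f, data = data, REML = FALSE, control = ctrl)),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  m0 <- quiet_lmer(null_f)
  m1 <- quiet_lmer(full_f)
  list(null = m0, full = m1)
}

#' Likelihood-ratio test of a plant species-richness effect
#'
#' Fits a null linear mixed model with crossed random intercepts for block
#' and mixture identity (the specific plant species combination; for
#' monocultures, the species itself), and a full model adding sown species
#' richness (log-linear) or realized richness as a fixed effect. Both models
#' are fit by maximum likelihood (REML likelihoods are not comparable across
#' fixed-effect structures); `chi2 = 2 (l_full - l_null)` with 1 df. The
#' response is transformed per the ledger first. Singular random-effect fits
#' are flagged, not suppressed.
#'
#' @param data Tibble with the response column plus `block`, `mixture_id`,
#'   `sown_richness` and (for `predictor = "realized"`) `realized_richness`.
#' @param response Name of the response column.
#' @param predictor `"sown"` (enters as `log(sown_richness)`) or
#'   `"realized"` (untransformed by default).
#' @param transforms Transformation ledger.
#' @param realized_log Enter realized richness on the log scale too.
#' @return One-row tibble: `response`, `predictor`, `df`, `chi2`, `p`,
#'   `singular`.
#' @export
lrt_richness <- function(data, response, predictor = c("sown", "realized"),
                         transforms = default_transforms(),
                         realized_log = FALSE) {
  predictor <- match.arg(predictor)
  stopifnot(all(c("block", "mixture_id", "sown_richness") %in% names(data)),
            response %in% names(data))
  d <- data
  d$.resp <- transform_response(d[[response]], response, transforms,
                                labels = d$plot_id)
  d <- d[!is.na(d$.resp), , drop = FALSE]
  term <- if (predictor == "sown") {
    "log(sown_richness)"
  } else if (realized_log) {
    "log(realized_richness)"
  } else {
    "realized_richness"
  }
  ms <- fit_lmm_pair(d, ".resp", term)
  chi2 <- max(0, 2 * (as.numeric(logLik(ms$full)) - as.numeric(logLik(ms$null))))
  tibble(
    response = response, predictor = predictor, df = 1L, chi2 = chi2,
    p = pchisq(chi2, df = 1, lower.tail = FALSE),
    singular = lme4::isSingular(ms$full) || lme4::isSingular(ms$null)
  )
}

#' Tukey HSD comparison of ordination scores across richness levels
#'
#' All pairwise mean differences of a score (or any value) among categorical
#' groups, with studentized-range-adjusted p-values. Groups with fewer than
#' two observations are excluded with a warning.
#'
#' @param data Tibble containing the value and group columns.
#' @param value Name of the value column (e.g. an NMDS axis).
#' @param group Name of the grouping column (e.g. sown richness).
#' @return Tibble: `contrast`, `estimate`, `conf_low`, `conf_high`, `p_adj`.
#' @export
tukey_groups <- function(data, value, group) {
  d <- tibble(y = data[[value]], g = factor(data[[group]]))
  d <- d[!is.na(d$y), ]
  sizes <- table(d$g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("group(s) with fewer than 2 observations excluded: ",
                paste(small, collapse = ", ")))
    d <- d[!d$g %in% small, ]
    d$g <- droplevels(d$g)
  }
  if (nlevels(d$g) < 2) {
    abort("need at least two groups with 2+ observations",
          class = "nemacomm_input_error")
  }
  tk <- TukeyHSD(aov(y ~ g, data = d))$g
  tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"], conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
}

#' Test the grand mean of D_max against zero
#'
#' Fits a linear model of per-plot D_max on block, sown species richness and
#' mixture identity (all categorical, sum-to-zero coded so the intercept is
#' the grand mean averaged over factor levels) and F-tests the intercept
#' against zero. A significant deviation indicates transgressive
#' overyielding on average across mixtures; a non-significant one suggests
#' the richness effect is carried by particular species (selection effect).
#'
#' @param records Tibble from [dmax_table()] (or with columns `dmax`,
#'   `block`, `sown_richness`, and a mixture identity column `species` or
#'   `mixture_id`).
#' @return One-row tibble: `estimate` (grand mean), `f`, `df1`, `df2`, `p`,
#'   `n`.
#' @export
dmax_deviation_test <- function(records) {
  mix_col <- if ("mixture_id" %in% names(records)) "mixture_id" else "species"
  stopifnot(all(c("dmax", "block", "sown_richness", mix_col) %in% names(records)))
  d <- tibble(
    dmax = records$dmax,
    block = factor(records$block),
    sr = factor(records$sown_richness),
    mixture = factor(records[[mix_col]])
  )
  d <- d[!is.na(d$dmax), ]
  if (nlevels(droplevels(d$mixture)) < 2) {
    abort("need at least two mixtures", class = "nemacomm_input_error")
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  terms <- c(
    if (nlevels(droplevels(d$block)) > 1) "block",
    if (nlevels(droplevels(d$sr)) > 1) "sr",
    "mixture"
  )
  fit <- lm(as.formula(paste("dmax ~", paste(terms, collapse = " + "))), data = d)
  df2 <- fit$df.residual
  if (df2 < 1) {
    abort("saturated design: no residual degrees of freedom",
          class = "nemacomm_input_error")
  }
  sm <- summary(fit)$coefficients
  est <- sm["(Intercept)", "Estimate"]
  tval <- sm["(Intercept)", "t value"]
  f <- tval^2
  # a noise-free design (zero residual variance) makes t 0/0; the F statistic
  # is then 0 for a zero grand mean and unbounded otherwise
  if (!is.finite(f)) f <- if (abs(est) < 1e-12) 0 else Inf
  tibble(
    estimate = est, f = f, df1 = 1L, df2 = df2,
    p = stats::pf(f, 1, df2, lower.tail = FALSE), n = nrow(d)
  )
}
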