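#' Configuration of the synthetic-data generator
#'
#' Bundles every knob of the generator: per-covariate log-linear intercepts,
#' slopes on log sown richness and lognormal noise scales; block-effect SD;
#' the target correlation between soil organic carbon and soil nitrogen;
#' extinction probabilities driving realized < sown richness; baseline
#' trophic-group abundances (per 100 g dry soil) and the signed path
#' coefficients of the causal links among covariates and trophic groups;
#' count-noise parameters (group-level lognormal sigma, negative-binomial
#' dispersion; Poisson is the `nb_size = Inf` limit); and the subsampling
#' arithmetic (identification cap, dry-mass distribution).
#'
#' Defaults reproduce the qualitative structure of a temperate grassland
#' diversity experiment: positive richness effects on shoot mass, root mass
#' and soil carbon, a small negative effect on specific root length, none on
#' leaf C/N; bacterial feeders driven by soil carbon, plant feeders by leaf
#' C/N (+) and shoot mass (-), omnivores+predators by their prey, fungal
#' feeders flat; trophic composition centred on 63.6/12.3/13.0/11.2 percent
#' PF/BF/FF/Om+Pr of a mean total of 1852.4 individuals per 100 g dry soil.
#'
#' @param seed Integer seed fixing the generated dataset bit for bit.
#' @param alpha,beta,sigma Named numeric vectors of log-scale intercepts,
#'   slopes on `log(sown_richness)` and noise SDs for covariates
#'   `shoot`, `root`, `srl`, `cn`, `corg` (and `soil_n` in `alpha`/`sigma`).
#' @param block_sd SD of lognormal block effects on covariates.
#' @param soil_cn_cor Target Pearson correlation between soil organic carbon
#'   and soil nitrogen; the noise correlation is calibrated internally so the
#'   generated columns attain it.
#' @param extinction Named vector of per-species extinction probabilities by
#'   functional group (`legume`, `herb`); grasses never go locally extinct.
#' @param group_base Baseline abundances per 100 g (`pf`, `bf`, `ff`, `ompr`).
#' @param refs Reference covariate values at which the links equal their
#'   baselines (`corg`, `cn`, `shoot`, `bf`, `pf`); the defaults are the
#'   expected covariate means over the 93-plot roster, so the realized
#'   community composition matches `group_base` at the design centre.
#' @param paths Named signed path coefficients: `bf_corg`, `pf_cn`,
#'   `pf_shoot`, `ompr_bf` (on log realized BF), `ompr_pf` (on realized PF).
#' @param group_sigma Lognormal SD of group-level abundance noise.
#' @param nb_size Negative-binomial dispersion of genus counts (must be > 0;
#'   `Inf` gives Poisson).
#' @param nema_block_sd,nema_mixture_sd SDs of block and mixture-identity
#'   random effects on log trophic-group abundance.
#' @param geom_ratio Ratio of the geometric series allocating a group total
#'   over its genera (alphabetical order).
#' @param cap Identification cap: at most this many individuals of the
#'   counted total are identified to genus (default 100).
#' @param dry_mass_mean,dry_mass_sd,dry_mass_min Normal parameters (and lower
#'   truncation, g) of the dried subsample mass.
#' @return A validated list of class `nema_config`.
#' @export
synth_config <- function(
    seed = 1L,
    alpha = c(shoot = log(300), root = log(0.002), srl = log(100),
              cn = log(20), corg = log(20), soil_n = log(2)),
    beta = c(shoot = 0.25, root = 0.15, srl = -0.08, cn = 0, corg = 0.12),
    sigma = c(shoot = 0.35, root = 0.35, srl = 0.2, cn = 0.15, corg = 0.15,
              soil_n = 0.15),
    block_sd = 0.1,
    soil_cn_cor = 0.87,
    extinction = c(legume = 0.3, herb = 0.15),
    group_base = c(pf = 1178.1, bf = 227.8, ff = 240.8, ompr = 207.5),
    refs = c(corg = 23, cn = 20.3, shoot = 410, bf = 227.8, pf = 1178.1),
    paths = c(bf_corg = 0.04, pf_cn = 0.04, pf_shoot = -0.002,
              ompr_bf = 0.4, ompr_pf = 5e-4),
    group_sigma = 0.25,
    nb_size = 5,
    nema_block_sd = 0.1,
    nema_mixture_sd = 0.1,
    geom_ratio = 0.7,
    cap = 100L,
    dry_mass_mean = 22, dry_mass_sd = 1.5, dry_mass_min = 10) {
  cfg <- list(
    seed = as.integer(seed), alpha = alpha, beta = beta, sigma = sigma,
    block_sd = block_sd, soil_cn_cor = soil_cn_cor, extinction = extinction,
    group_base = group_base, refs = refs, paths = paths,
    group_sigma = group_sigma, nb_size = nb_size,
    nema_block_sd = nema_block_sd, nema_mixture_sd = nema_mixture_sd,
    geom_ratio = geom_ratio, cap = as.integer(cap),
    dry_mass_mean = dry_mass_mean, dry_mass_sd = dry_mass_sd,
    dry_mass_min = dry_mass_min
  )
  num <- unlist(cfg[c("alpha", "beta", "sigma", "block_sd", "soil_cn_cor",
                      "extinction", "group_base", "refs", "paths",
                      "group_sigma", "nema_block_sd", "nema_mixture_sd",
                      "geom_ratio")])
  if (anyNA(num) || any(!is.finite(num))) {
    abort("all generator coefficients must be finite", class = "nemacomm_config_error")
  }
  if (!(cfg$nb_size > 0)) {
    abort("nb_size (dispersion) must be positive", class = "nemacomm_config_error")
  }
  if (cfg$cap < 1) {
    abort("subsample cap must be >= 1", class = "nemacomm_config_error")
  }
  structure(cfg, class = "nema_config")
}

#' A configuration with all richness effects and causal paths zeroed
#'
#' Convenience null configuration for type-I-error calibration: covariate
#' slopes on richness and all trophic path coefficients are 0, block and
#' mixture effects and all noise scales keep their defaults.
#'
#' @inheritParams synth_config
#' @param ... Further arguments passed to [synth_config()].
#' @export
null_config <- function(seed = 1L, ...) {
  cfg <- synth_config(seed = seed, ...)
  cfg$beta[] <- 0
  cfg$paths[] <- 0
  cfg
}

#' Generate per-plot covariates over a roster
#'
#' Each covariate v is lognormal around a log-linear richness signal:
#' `v = exp(alpha_v + beta_v * log(sown_richness) + block effect + noise)`.
#' Root length density is derived exactly as `RLD = SRL * root mass * 100`
#' (both trait and density measure the same root length, hence their strong
#' collinearity in real data). Soil nitrogen shares the soil-carbon signal
#' and its noise is correlated so that the generated (C_org, N) columns
#' attain the configured Pearson correlation in expectation. Realized
#' richness thins sown legumes and herbs by the configured extinction
#' probabilities (grasses persist; at least one species always remains).
#'
#' @param cfg A [synth_config()].
#' @param roster Roster tibble with `plot_id`, `block`, `sown_richness`,
#'   `species`, `replicate` ([build_dominance_roster()] or compatible).
#' @param seed Seed for this stage (defaults to `cfg$seed`).
#' @return Tibble with one row per plot: design columns, `mixture_id`,
#'   `realized_richness`, `shoot_mass`, `root_mass`, `srl`, `rld`,
#'   `cn_leaf`, `soil_corg`, `soil_n`.
#' @export
generate_covariates <- function(cfg, roster, seed = cfg$seed) {
  stopifnot(inherits(cfg, "nema_config"))
  set.seed(seed)
  n <- nrow(roster)
  lsr <- log(roster$sown_richness)
  vars <- c("shoot", "root", "srl", "cn")
  block_eff <- matrix(rnorm(4 * (length(vars) + 1), 0, cfg$block_sd),
                      nrow = 4,
                      dimnames = list(NULL, c(vars, "corg")))
  draw <- function(v) {
    exp(cfg$alpha[[v]] + cfg$beta[[v]] * lsr + block_eff[roster$block, v] +
          rnorm(n, 0, cfg$sigma[[v]]))
  }
  shoot <- draw("shoot"); root <- draw("root"); srl <- draw("srl"); cn <- draw("cn")

  # soils: shared signal, noise correlation calibrated to the target
  mu_c <- cfg$alpha[["corg"]] + cfg$beta[["corg"]] * lsr + block_eff[roster$block, "corg"]
  sc <- cfg$sigma[["corg"]]; sn <- cfg$sigma[["soil_n"]]
  v_mu <- var(mu_c) * (n - 1) / n
  rho0 <- if (sc > 0 && sn > 0) {
    (cfg$soil_cn_cor * sqrt((v_mu + sc^2) * (v_mu + sn^2)) - v_mu) / (sc * sn)
  } else 0
  rho0 <- min(1, max(-1, rho0))
  e1 <- rnorm(n); e2 <- rho0 * e1 + sqrt(1 - rho0^2) * rnorm(n)
  corg <- exp(mu_c + sc * e1)
  soil_n <- exp(cfg$alpha[["soil_n"]] + (mu_c - cfg$alpha[["corg"]]) + sn * e2)

  # realized richness: thin legumes/herbs among sown target species
  sp <- dominance_species()
  ext_p <- setNames(rep(0, nrow(sp)), sp$code)
  ext_p[sp$code[sp$functional_group == "legume"]] <- cfg$extinction[["legume"]]
  ext_p[sp$code[sp$functional_group == "herb"]] <- cfg$extinction[["herb"]]
  targets <- sp$code[sp$target]
  realized <- vapply(roster$species, function(s) {
    codes <- intersect(strsplit(s, ";")[[1]], targets)
    surv <- sum(runif(length(codes)) >= ext_p[codes])
    max(1L, as.integer(surv))
  }, integer(1), USE.NAMES = FALSE)

  roster %>%
    mutate(
      mixture_id = .data$species,
      realized_richness = realized,
      shoot_mass = shoot, root_mass = root, srl = srl,
      rld = srl * root * 100,
      cn_leaf = cn, soil_corg = corg, soil_n = soil_n
    )
}

#' Expected trophic-group abundances under the configured links
#'
#' The noise-free expected abundances per 100 g implied by a plot's
#' covariates: `BF = bf0 * exp(g (C_org - ref))`,
#' `PF = pf0 * exp(d1 (C/N - ref) + d2 (shoot - ref))`, `FF = ff0`.
#' Omnivores+predators depend on *realized* prey abundances and are
#' therefore not a pure function of the covariates; their link is
#' `OmPr = ompr0 * exp(e1 (log BF - log bf0) + e2 (PF - pf0))`.
#'
#' @inheritParams generate_covariates
#' @param measurements Tibble of plot covariates ([generate_covariates()]).
#' @return Tibble with `plot_id` (if present), `bf`, `pf`, `ff`.
#' @export
expected_group_abundance <- function(cfg, measurements) {
  p <- cfg$paths; r <- cfg$refs; b <- cfg$group_base
  out <- tibble(
    bf = b[["bf"]] * exp(p[["bf_corg"]] * (measurements$soil_corg - r[["corg"]])),
    pf = b[["pf"]] * exp(p[["pf_cn"]] * (measurements$cn_leaf - r[["cn"]]) +
                           p[["pf_shoot"]] * (measurements$shoot_mass - r[["shoot"]])),
    ff = rep(b[["ff"]], nrow(measurements))
  )
  if ("plot_id" %in% names(measurements)) {
    out <- dplyr::bind_cols(tibble(plot_id = measurements$plot_id), out)
  }
  out
}

# geometric allocation of a group total over genera (alphabetical order)
geom_props <- function(k, ratio) {
  w <- ratio^(seq_len(k) - 1)
  w / sum(w)
}

rnb <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = size)
}

#' Generate one nematode sample for a plot
#'
#' Draws a dried subsample mass, negative-binomial genus counts whose
#' expectations follow the configured trophic links and a geometric
#' within-group evenness profile, and identifies a subsample of at most
#' `cfg$cap` individuals by a multivariate hypergeometric draw from the
#' counted animals. Omnivore+predator expectations are driven by the
#' *realized* (count-derived) bacterial- and plant-feeder abundances of the
#' same sample, as prey availability would.
#'
#' @inheritParams expected_group_abundance
#' @param measurements One-row tibble of plot covariates.
#' @param annotations Annotation tibble defining the genus pool.
#' @param offsets Named numeric log-scale offsets (`pf`, `bf`, `ff`, `ompr`)
#'   carrying block/mixture random effects; zero by default.
#' @return A list of class `nema_sample`: `dry_mass`, `counted_total`, and
#'   `identified`, a named integer vector of genus counts with
#'   `sum(identified) = min(counted_total, cap)`.
#' @export
generate_nematode_sample <- function(cfg, measurements,
                                     annotations = default_annotations(),
                                     offsets = c(pf = 0, bf = 0, ff = 0, ompr = 0)) {
  stopifnot(inherits(cfg, "nema_config"), nrow(measurements) == 1)
  sample_one(cfg, measurements, genus_pool(annotations), offsets)
}

# validated genus pool split by trophic group, for repeated sampling
genus_pool <- function(annotations) {
  ann <- validate_annotations(annotations)
  pool <- split(sort(ann$genus), ann$trophic[order(ann$genus)])
  need <- c("PF", "BF", "FF")
  if (!all(need %in% names(pool)) || !any(c("Om", "Pr") %in% names(pool))) {
    miss <- c(setdiff(need, names(pool)),
              if (!any(c("Om", "Pr") %in% names(pool))) "Om/Pr")
    abort(paste0("annotation table lacks genera for group(s): ",
                 paste(miss, collapse = ", ")),
          class = "nemacomm_annotation_gap")
  }
  pool
}

sample_one <- function(cfg, measurements, pool, offsets) {
  dry <- max(cfg$dry_mass_min, rnorm(1, cfg$dry_mass_mean, cfg$dry_mass_sd))
  exp_ab <- expected_group_abundance(cfg, measurements)

  draw_group <- function(genera, mu100, off) {
    lam <- mu100 * exp(off + rnorm(1, 0, cfg$group_sigma)) *
      geom_props(length(genera), cfg$geom_ratio) * dry / 100
    setNames(rnb(length(genera), lam, cfg$nb_size), genera)
  }
  bf_counts <- draw_group(pool$BF, exp_ab$bf, offsets[["bf"]])
  pf_counts <- draw_group(pool$PF, exp_ab$pf, offsets[["pf"]])
  ff_counts <- draw_group(pool$FF, exp_ab$ff, offsets[["ff"]])

  bf_real <- sum(bf_counts) * 100 / dry
  pf_real <- sum(pf_counts) * 100 / dry
  p <- cfg$paths; r <- cfg$refs
  ompr_mu <- cfg$group_base[["ompr"]] *
    exp(p[["ompr_bf"]] * (log(max(bf_real, 1)) - log(r[["bf"]])) +
          p[["ompr_pf"]] * (pf_real - r[["pf"]]))
  ompr_genera <- sort(c(pool$Om, pool$Pr))
  ompr_counts <- draw_group(ompr_genera, ompr_mu, offsets[["ompr"]])

  counts <- c(bf_counts, pf_counts, ff_counts, ompr_counts)
  counted_total <- sum(counts)
  n_ident <- min(counted_total, cfg$cap)
  identified <- if (counted_total == 0) {
    integer(0)
  } else if (counted_total <= cfg$cap) {
    counts[counts > 0]
  } else {
    drawn <- sample(rep.int(seq_along(counts), counts), n_ident)
    tab <- tabulate(drawn, nbins = length(counts))
    setNames(tab, names(counts))[tab > 0]
  }
  structure(
    list(dry_mass = dry, counted_total = as.integer(counted_total),
         identified = identified),
    class = "nema_sample"
  )
}

#' Generate a complete synthetic dataset over a roster
#'
#' End-to-end wrapper: covariates, block/mixture random effects on trophic
#' abundances, and one nematode sample per plot. Mirroring the field
#' campaign, root measurements are missing on the second monoculture
#' replicate of every species (`root_mass` and `rld` set `NA`), so analyses
#' needing roots run on 86 of the 93 plots.
#'
#' @inheritParams generate_covariates
#' @param annotations Annotation tibble defining the genus pool.
#' @return A list of class `nema_dataset` with tibbles `roster`,
#'   `covariates` (incl. `mixture_id`, `realized_richness`, root-missing
#'   `NA`s), `counts` (long: `plot_id`, `genus`, `identified_count`) and
#'   `samples` (`plot_id`, `dry_mass`, `counted_total`).
#' @examples
#' \donttest{
#' ds <- generate_dataset(synth_config(seed = 42))
#' nrow(ds$covariates) # 93
#' }
#' @export
generate_dataset <- function(cfg, roster = build_dominance_roster(),
                             annotations = default_annotations()) {
  stopifnot(inherits(cfg, "nema_config"))
  cov <- generate_covariates(cfg, roster, seed = cfg$seed)

  set.seed(cfg$seed %% 2147480000L + 1L)
  groups <- c("pf", "bf", "ff", "ompr")
  block_re <- matrix(rnorm(4 * 4, 0, cfg$nema_block_sd), nrow = 4,
                     dimnames = list(NULL, groups))
  mixtures <- unique(cov$mixture_id)
  mix_re <- matrix(rnorm(length(mixtures) * 4, 0, cfg$nema_mixture_sd),
                   nrow = length(mixtures), dimnames = list(mixtures, groups))

  pool <- genus_pool(annotations)
  cov_rows <- cov[, c("plot_id", "soil_corg", "cn_leaf", "shoot_mass")]
  samples <- vector("list", nrow(cov))
  for (i in seq_len(nrow(cov))) {
    off <- block_re[cov$block[i], ] + mix_re[cov$mixture_id[i], ]
    samples[[i]] <- sample_one(cfg, cov_rows[i, ], pool, offsets = off)
  }

  counts <- purrr::map2_dfr(cov$plot_id, samples, function(pid, s) {
    if (length(s$identified) == 0) return(tibble())
    tibble(plot_id = pid, genus = names(s$identified),
           identified_count = as.integer(s$identified))
  })
  sample_tab <- tibble(
    plot_id = cov$plot_id,
    dry_mass = vapply(samples, `[[`, numeric(1), "dry_mass"),
    counted_total = vapply(samples, `[[`, integer(1), "counted_total")
  )

  root_missing <- cov$sown_richness == 1 & cov$replicate == 2
  cov$root_mass[root_missing] <- NA_real_
  cov$rld[root_missing] <- NA_real_

  structure(
    list(roster = roster, covariates = cov, counts = counts,
         samples = sample_tab),
    class = "nema_dataset"
  )
}
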