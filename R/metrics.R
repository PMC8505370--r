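#' Total nematode abundance per 100 g dry soil
#'
#' All animals in a soil subsample are counted; the count is scaled by the
#' dry mass of the remaining soil to individuals per 100 g dry soil.
#'
#' @param counted_total Nonnegative integer vector: all animals counted.
#' @param dry_mass Positive numeric vector: dry soil mass in grams.
#' @return Numeric vector, individuals per 100 g dry soil.
#' @examples
#' abundance_per_100g(400, 25) # 1600
#' @export
abundance_per_100g <- function(counted_total, dry_mass) {
  if (any(dry_mass <= 0)) {
    abort("dry_mass must be positive", class = "nemacomm_domain_error")
  }
  counted_total * 100 / dry_mass
}

#' Genus-level community profiles from identified subsamples
#'
#' Only up to a fixed cap (typically 100) of the counted animals per sample
#' are identified to genus. The per-genus abundance is the identified share
#' allocated over the total abundance per 100 g dry soil:
#' `abundance(g) = identified(g) / sum(identified) * counted_total * 100 / dry_mass`.
#'
#' @param counts Long tibble with columns `plot_id`, `genus`,
#'   `identified_count`.
#' @param samples Tibble with columns `plot_id`, `dry_mass`, `counted_total`.
#' @return A tibble with columns `plot_id`, `genus`, `abundance` (per 100 g
#'   dry soil). Plots with `counted_total = 0` yield no rows. The per-plot
#'   totals are available via [compute_indices()] or by summing.
#' @export
genus_profiles <- function(counts, samples) {
  stopifnot(all(c("plot_id", "genus", "identified_count") %in% names(counts)),
            all(c("plot_id", "dry_mass", "counted_total") %in% names(samples)))
  joined <- left_join(counts, samples, by = "plot_id")
  if (anyNA(joined$counted_total)) {
    abort("counts contain plot_id values absent from samples",
          class = "nemacomm_validation_error")
  }
  bad <- joined %>%
    group_by(.data$plot_id) %>%
    summarise(ident = sum(.data$identified_count), total = .data$counted_total[1]) %>%
    filter(.data$ident > 0 & .data$total == 0)
  if (nrow(bad) > 0) {
    abort(
      paste0("identified counts with counted_total = 0 for plot(s): ",
             paste(bad$plot_id, collapse = ", ")),
      class = "nemacomm_inconsistency_error"
    )
  }
  joined %>%
    group_by(.data$plot_id) %>%
    mutate(abundance = .data$identified_count / sum(.data$identified_count) *
             abundance_per_100g(.data$counted_total, .data$dry_mass)) %>%
    ungroup() %>%
    filter(.data$counted_total > 0) %>%
    select("plot_id", "genus", "abundance")
}

#' Genus richness and Shannon diversity of a community profile
#'
#' Richness is the number of genera with positive abundance; Shannon
#' diversity is \eqn{H' = -\sum q_g \ln q_g} with \eqn{q_g} the relative
#' abundances (natural log, nats). An empty profile has richness 0 and
#' `NA` diversity (undefined, never coerced to zero).
#'
#' @param profiles Long profile tibble from [genus_profiles()].
#' @return Tibble with `plot_id`, `genus_richness`, `shannon`.
#' @export
diversity_metrics <- function(profiles) {
  profiles %>%
    group_by(.data$plot_id) %>%
    summarise(
      genus_richness = sum(.data$abundance > 0),
      shannon = shannon_index(.data$abundance)
    )
}

shannon_index <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0) return(NA_real_)
  q <- x / sum(x)
  -sum(q * log(q))
}

#' Trophic-group abundances and genus richness
#'
#' Sums per-100 g abundances and counts genera within each trophic group
#' (PF, BF, FF, Pr, Om); predators and omnivores are also reported combined
#' (`ompr`) because of their similar life-history strategies.
#'
#' @inheritParams diversity_metrics
#' @param annotations Annotation tibble; every profiled genus must be covered.
#' @return Tibble with one row per plot: `pf`, `bf`, `ff`, `pr`, `om`, `ompr`
#'   abundances and `pf_rich`, `bf_rich`, `ff_rich`, `pr_rich`, `om_rich`,
#'   `ompr_rich` genus counts.
#' @export
trophic_summary <- function(profiles, annotations = default_annotations()) {
  ann <- annotate_genera(unique(profiles$genus), annotations)
  prof <- left_join(profiles, ann, by = "genus")
  out <- prof %>%
    group_by(.data$plot_id, .data$trophic) %>%
    summarise(ab = sum(.data$abundance), rich = sum(.data$abundance > 0),
              .groups = "drop")
  grid <- tidyr::expand_grid(
    plot_id = unique(profiles$plot_id),
    trophic = trophic_levels
  )
  out <- left_join(grid, out, by = c("plot_id", "trophic")) %>%
    mutate(
      ab = ifelse(is.na(.data$ab), 0, .data$ab),
      rich = ifelse(is.na(.data$rich), 0L, .data$rich)
    )
  wide <- out %>%
    tidyr::pivot_wider(
      names_from = "trophic", values_from = c("ab", "rich"),
      names_glue = "{tolower(trophic)}_{.value}"
    )
  names(wide) <- sub("_ab$", "", names(wide))
  wide %>% mutate(
    ompr = .data$om + .data$pr,
    ompr_rich = .data$om_rich + .data$pr_rich
  )
}

#' Trophic-group ratios
#'
#' Three ratios summarise food-web topology: the predator-prey ratio
#' `(Pr + Om) / PF` (capacity for top-down control of plant feeders), the
#' channel ratio `FF / (FF + BF)` (fungal- vs bacterial-based energy
#' channel), and the grazing-pressure ratio `log(PF / root mass)` (herbivore
#' load per unit root). Undefined ratios (zero denominators, nonpositive
#' root mass) propagate as `NA`, never as 0.
#'
#' @param trophic Tibble from [trophic_summary()].
#' @param root_mass Optional numeric vector (g root per cm^3 soil) aligned
#'   with the rows of `trophic`, or the name of a column in `trophic`.
#' @param log_base Base of the grazing-pressure log; default natural log.
#' @return `trophic` with columns `predator_prey`, `channel`,
#'   `grazing_pressure` added.
#' @export
trophic_ratios <- function(trophic, root_mass = NULL, log_base = exp(1)) {
  if (is.character(root_mass) && length(root_mass) == 1) {
    root_mass <- trophic[[root_mass]]
  }
  if (is.null(root_mass)) root_mass <- rep(NA_real_, nrow(trophic))
  trophic %>% mutate(
    predator_prey = ifelse(.data$pf > 0, (.data$pr + .data$om) / .data$pf, NA_real_),
    channel = ifelse(.data$ff + .data$bf > 0,
                     .data$ff / (.data$ff + .data$bf), NA_real_),
    grazing_pressure = ifelse(
      .data$pf > 0 & !is.na(.env$root_mass) & .env$root_mass > 0,
      log(.data$pf / .env$root_mass, base = .env$log_base), NA_real_
    )
  )
}

#' Colonizer-persister class abundances
#'
#' Abundance totals in the c-p classes, with classes 1 and 2 pooled as
#' classic r-strategists. Plant feeders are excluded: they respond to
#' resource availability, not to the disturbance gradient the scale encodes.
#'
#' @inheritParams trophic_summary
#' @return Tibble with `plot_id`, `cp12`, `cp3`, `cp4`, `cp5`.
#' @export
cp_class_abundances <- function(profiles, annotations = default_annotations()) {
  ann <- annotate_genera(unique(profiles$genus), annotations)
  base <- tibble(plot_id = unique(profiles$plot_id))
  out <- left_join(profiles, ann, by = "genus") %>%
    filter(.data$trophic != "PF") %>%
    mutate(class = ifelse(.data$cp <= 2, "cp12", paste0("cp", .data$cp))) %>%
    group_by(.data$plot_id, .data$class) %>%
    summarise(ab = sum(.data$abundance), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "class", values_from = "ab", values_fill = 0)
  out <- left_join(base, out, by = "plot_id")
  for (cl in c("cp12", "cp3", "cp4", "cp5")) {
    if (!cl %in% names(out)) out[[cl]] <- 0
    out[[cl]][is.na(out[[cl]])] <- 0
  }
  select(out, "plot_id", "cp12", "cp3", "cp4", "cp5")
}

#' Maturity Index
#'
#' The c-p weighted mean of free-living (non-plant-feeding) genus relative
#' abundances: \eqn{MI = \sum v_g q_g} with \eqn{v_g} the c-p class. Between
#' 1 (enriched/disturbed, colonizer-dominated) and 5 (stable,
#' persister-dominated). By default the relative abundances are taken within
#' the free-living taxa only; `within_nonpf = FALSE` divides by total
#' community abundance instead.
#'
#' @inheritParams trophic_summary
#' @param within_nonpf Use relative abundance within non-plant-feeders
#'   (default) rather than within the whole community.
#' @return Tibble with `plot_id`, `mi` (`NA` where no free-living individuals).
#' @export
maturity_index <- function(profiles, annotations = default_annotations(),
                           within_nonpf = TRUE) {
  ann <- annotate_genera(unique(profiles$genus), annotations)
  prof <- left_join(profiles, ann, by = "genus")
  prof %>%
    group_by(.data$plot_id) %>%
    summarise(mi = {
      tot <- if (within_nonpf) sum(.data$abundance[.data$trophic != "PF"])
             else sum(.data$abundance)
      num <- sum((.data$cp * .data$abundance)[.data$trophic != "PF"])
      if (tot > 0) num / tot else NA_real_
    })
}

#' Enrichment and Structure indices
#'
#' Functional-guild weighted food-web indices on a 0-100 scale. With
#' weighted abundance sums e (enrichment guilds), b (basal guilds) and s
#' (structure guilds): `EI = 100 e / (e + b)` measures the nutrient
#' enrichment status; `SI = 100 s / (s + b)` the structural complexity of
#' the food web. Guild membership and weights come from a configurable
#' [guild weight table][load_guild_weights()].
#'
#' @inheritParams trophic_summary
#' @param weights Guild weight tibble (default [default_guild_weights()]).
#' @return Tibble with `plot_id`, `ei`, `si` (`NA` where the denominator is 0).
#' @export
enrichment_structure_indices <- function(profiles,
                                         annotations = default_annotations(),
                                         weights = default_guild_weights()) {
  weights <- validate_guild_weights(weights)
  ann <- annotate_genera(unique(profiles$genus), annotations)
  prof <- left_join(profiles, ann, by = "genus")
  comp_sum <- function(df, comp) {
    w <- weights[weights$component == comp, ]
    idx <- match(df$guild, w$guild)
    sum(ifelse(is.na(idx), 0, w$weight[idx]) * df$abundance)
  }
  prof %>%
    group_by(.data$plot_id) %>%
    summarise(
      ei = {
        e <- comp_sum(dplyr::pick(dplyr::everything()), "enrichment")
        b <- comp_sum(dplyr::pick(dplyr::everything()), "basal")
        if (e + b > 0) 100 * e / (e + b) else NA_real_
      },
      si = {
        s <- comp_sum(dplyr::pick(dplyr::everything()), "structure")
        b <- comp_sum(dplyr::pick(dplyr::everything()), "basal")
        if (s + b > 0) 100 * s / (s + b) else NA_real_
      }
    )
}

#' Community-weighted mean of a species trait
#'
#' \eqn{CWM = \sum p_i t_i} with \eqn{p_i} species biomass proportions
#' (summing to 1) and \eqn{t_i} species trait values (e.g. leaf C/N).
#'
#' @param p Numeric vector of biomass proportions (nonnegative, sum 1).
#' @param t Numeric vector of trait values, same length.
#' @param tol Tolerance on `sum(p) == 1`.
#' @return The community-weighted mean (scalar).
#' @examples
#' community_weighted_mean(c(0.25, 0.75), c(12, 20)) # 18
#' @export
community_weighted_mean <- function(p, t, tol = 1e-8) {
  if (length(p) != length(t)) {
    abort("p and t must have equal length", class = "nemacomm_input_error")
  }
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    abort("biomass proportions must be nonnegative and sum to 1",
          class = "nemacomm_input_error")
  }
  sum(p * t)
}

#' Transgressive overyielding statistic D_max
#'
#' Relative deviation of a mixture's value from its best constituent
#' monoculture: \eqn{D_{max} = (O_T - M) / M}, where the benchmark M is the
#' highest monoculture value for variables expected to increase with
#' richness (`direction = "max"`) and the lowest for variables expected to
#' decrease (`direction = "min"`; e.g. channel or grazing-pressure ratio).
#' A positive (resp. negative) deviation beyond the best monoculture
#' indicates complementarity rather than a selection effect.
#'
#' @param o_t Mixture value (scalar).
#' @param mono_values Values of the constituent-species monocultures.
#' @param direction `"max"` or `"min"` benchmark.
#' @return Tibble with `o_t`, `benchmark`, `dmax` (`dmax` is `NA` when the
#'   benchmark is 0).
#' @examples
#' dmax(15, c(10, 8))$dmax # 0.5
#' @export
dmax <- function(o_t, mono_values, direction = c("max", "min")) {
  direction <- match.arg(direction)
  mono_values <- mono_values[!is.na(mono_values)]
  if (length(mono_values) == 0) {
    abort("mono_values must contain at least one non-missing value",
          class = "nemacomm_input_error")
  }
  bench <- if (direction == "max") max(mono_values) else min(mono_values)
  tibble(
    o_t = o_t, benchmark = bench,
    dmax = if (bench != 0) (o_t - bench) / bench else NA_real_
  )
}

#' D_max for every mixture plot of a roster
#'
#' For each plot with sown richness > 1, benchmarks its value against the
#' monoculture plots of its constituent target species.
#'
#' @param values Tibble with `plot_id` and a `value` column.
#' @param roster Roster tibble ([build_dominance_roster()]).
#' @param direction Benchmark direction, see [dmax()].
#' @return Tibble with `plot_id`, `sown_richness`, `species`, `block`,
#'   `o_t`, `benchmark`, `dmax` for mixture plots whose constituent species
#'   have at least one monoculture value.
#' @export
dmax_table <- function(values, roster, direction = c("max", "min")) {
  direction <- match.arg(direction)
  stopifnot(all(c("plot_id", "value") %in% names(values)))
  rs <- roster_species(roster)
  mono <- rs %>%
    filter(.data$sown_richness == 1) %>%
    left_join(values, by = "plot_id") %>%
    select("code", mono_value = "value")
  mix <- roster %>%
    filter(.data$sown_richness > 1) %>%
    left_join(values, by = "plot_id") %>%
    filter(!is.na(.data$value))
  purrr::map_dfr(seq_len(nrow(mix)), function(i) {
    codes <- strsplit(mix$species[i], ";")[[1]]
    mvals <- mono$mono_value[mono$code %in% codes]
    mvals <- mvals[!is.na(mvals)]
    if (length(mvals) == 0) return(tibble())
    dplyr::bind_cols(
      mix[i, c("plot_id", "block", "sown_richness", "species")],
      dmax(mix$value[i], mvals, direction)
    )
  })
}

#' All per-plot community metrics in one table
#'
#' Runs the full metric engine: per-100 g profile, diversity, trophic
#' abundances/richness, trophic ratios, c-p class abundances, Maturity,
#' Enrichment and Structure indices.
#'
#' @inheritParams genus_profiles
#' @inheritParams enrichment_structure_indices
#' @param covariates Optional tibble with `plot_id` and `root_mass` used for
#'   the grazing-pressure ratio (left `NA` otherwise).
#' @return One row per plot with all metric columns.
#' @export
compute_indices <- function(counts, samples,
                            annotations = default_annotations(),
                            weights = default_guild_weights(),
                            covariates = NULL) {
  profiles <- genus_profiles(counts, samples)
  totals <- samples %>%
    mutate(total_per_100g = abundance_per_100g(.data$counted_total, .data$dry_mass)) %>%
    select("plot_id", "total_per_100g")
  out <- totals %>%
    left_join(diversity_metrics(profiles), by = "plot_id") %>%
    left_join(trophic_summary(profiles, annotations), by = "plot_id") %>%
    left_join(cp_class_abundances(profiles, annotations), by = "plot_id") %>%
    left_join(maturity_index(profiles, annotations), by = "plot_id") %>%
    left_join(enrichment_structure_indices(profiles, annotations, weights),
              by = "plot_id")
  zero_fill <- c("genus_richness", "pf", "bf", "ff", "pr", "om", "ompr",
                 "pf_rich", "bf_rich", "ff_rich", "pr_rich", "om_rich",
                 "ompr_rich", "cp12", "cp3", "cp4", "cp5")
  for (cl in zero_fill) {
    if (cl %in% names(out)) out[[cl]][is.na(out[[cl]]) & out$total_per_100g == 0] <- 0
  }
  root <- NULL
  if (!is.null(covariates) && "root_mass" %in% names(covariates)) {
    out <- left_join(out, select(covariates, "plot_id", "root_mass"), by = "plot_id")
    root <- "root_mass"
  }
  trophic_ratios(out, root_mass = root)
}
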