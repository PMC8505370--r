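#' The nine dominance-experiment species
#'
#' The design uses nine potentially dominant Central European grassland
#' species: five grasses, two legumes and two herbs. Two of them
#' (*Phleum pratense* and *Anthriscus sylvestris*) were nearly extinct at
#' sampling and are not *target* species: they occur in mixtures but carry no
#' monocultures and do not count towards realized richness.
#'
#' @return A tibble with columns `code` (two-letter id used in plot ids and
#'   the `species` column of the roster), `species` (binomial),
#'   `functional_group` (grass/legume/herb) and `target` (logical).
#' @export
dominance_species <- function() {
  tibble(
    code = c("Ae", "Ap", "Dg", "Pp", "Pt", "Gp", "As", "Tp", "Tr"),
    species = c(
      "Arrhenatherum elatius", "Alopecurus pratensis", "Dactylis glomerata",
      "Phleum pratense", "Poa trivialis", "Geranium pratense",
      "Anthriscus sylvestris", "Trifolium pratense", "Trifolium repens"
    ),
    functional_group = c(rep("grass", 5), "herb", "herb", "legume", "legume"),
    target = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
}

comp_key <- function(codes) paste(sort(codes), collapse = ";")

# The 12 lines of the affine plane AG(2,3) over the lexicographically sorted
# nine species codes: rows, columns and both diagonal directions of a 3x3
# grid. Every species lies on 4 lines and every pair of species on exactly
# one, so the complements (six-species sets) hit each species 8 times.
ag23_lines <- function(items) {
  stopifnot(length(items) == 9)
  m <- matrix(items, nrow = 3, byrow = TRUE)
  lines <- list()
  for (i in 1:3) lines[[length(lines) + 1]] <- m[i, ]
  for (j in 1:3) lines[[length(lines) + 1]] <- m[, j]
  for (c0 in 0:2) {
    lines[[length(lines) + 1]] <-
      vapply(0:2, function(i) m[i + 1, ((i + c0) %% 3) + 1], items[1])
  }
  for (c0 in 0:2) {
    lines[[length(lines) + 1]] <-
      vapply(0:2, function(i) m[i + 1, ((c0 - i) %% 3) + 1], items[1])
  }
  lines
}

#' Reconstruct the 93-plot dominance-experiment roster
#'
#' Deterministically rebuilds the sampled plot roster from the published
#' selection rules: two monocultures for each of the seven target species;
#' all two-species combinations of the targets in two replicates except
#' single replicates for *T. pratense* and *T. repens* with each of
#' *A. elatius*, *A. pratensis* and *D. glomerata* and for the
#' *T. pratense* x *T. repens* pair; single-replicate pairs of each target
#' with *A. sylvestris* and *P. pratense* except none for *G. pratense* with
#' either, none for *T. repens* x *A. sylvestris*, and a second replicate for
#' *T. pratense* x *A. sylvestris*; 24 six-species plots in which every
#' species occurs 16 times; and 8 nine-species plots. Totals per richness
#' level: 14 / 47 / 24 / 8.
#'
#' The exact six-species compositions are not published; they are generated
#' as the complements of the 12 lines of a resolvable triple design over the
#' nine species (each composition twice), which reproduces every published
#' per-species occurrence margin. Blocks are assigned by cycling blocks 1-4
#' within each richness level while keeping replicates of identical
#' compositions in different blocks wherever arithmetic allows.
#'
#' @return A tibble (one row per plot) with columns `plot_id`, `block`
#'   (integer 1..4), `sown_richness` (1, 2, 6 or 9), `species`
#'   (semicolon-joined sorted species codes, see [dominance_species()]) and
#'   `replicate`.
#' @examples
#' r <- build_dominance_roster()
#' nrow(r) # 93
#' dplyr::count(r, sown_richness)
#' @export
build_dominance_roster <- function() {
  sp <- dominance_species()
  targets <- sort(sp$code[sp$target])
  comps <- list() # list of (codes, n_rep)

  add <- function(codes, n_rep) {
    comps[[length(comps) + 1]] <<- list(codes = sort(codes), n_rep = n_rep)
  }

  # monocultures: two replicates per target
  for (t in targets) add(t, 2)

  # target x target pairs
  single_rep <- c("Ae;Tp", "Ap;Tp", "Dg;Tp", "Ae;Tr", "Ap;Tr", "Dg;Tr", "Tp;Tr")
  pair_idx <- combn(targets, 2)
  for (i in seq_len(ncol(pair_idx))) {
    pair <- pair_idx[, i]
    add(pair, if (comp_key(pair) %in% single_rep) 1L else 2L)
  }

  # pairs with the non-target species
  for (t in setdiff(targets, "Gp")) {
    if (t != "Tr") add(c(t, "As"), if (t == "Tp") 2L else 1L)
    add(c(t, "Pp"), 1L)
  }

  # six-species plots: complements of the 12 triple-design lines, twice each
  for (line in ag23_lines(sort(sp$code))) {
    add(setdiff(sort(sp$code), line), 2L)
  }

  # nine-species plots: eight replicates of the full mixture
  add(sort(sp$code), 8L)

  plots <- purrr::map_dfr(comps, function(cm) {
    tibble(
      species = comp_key(cm$codes),
      sown_richness = length(cm$codes),
      replicate = seq_len(cm$n_rep)
    )
  })
  plots <- arrange(plots, .data$sown_richness, .data$species, .data$replicate)

  # block assignment: within each richness level, greedily place each plot in
  # the least-filled block not yet holding its composition (ties -> lowest id)
  plots$block <- NA_integer_
  for (k in unique(plots$sown_richness)) {
    rows <- which(plots$sown_richness == k)
    level_count <- integer(4)
    comp_count <- list()
    for (r in rows) {
      key <- plots$species[r]
      used <- comp_count[[key]]
      if (is.null(used)) used <- integer(4)
      score <- used * 1000L + level_count * 10L + 1:4
      b <- which.min(score)
      plots$block[r] <- b
      level_count[b] <- level_count[b] + 1L
      used[b] <- used[b] + 1L
      comp_count[[key]] <- used
    }
  }

  plots$plot_id <- sprintf(
    "SR%d_%s_r%d", plots$sown_richness,
    gsub(";", "", plots$species), plots$replicate
  )
  select(plots, "plot_id", "block", "sown_richness", "species", "replicate")
}

#' Long plot-by-species view of a roster
#'
#' @param roster A roster tibble from [build_dominance_roster()].
#' @return A tibble with one row per (plot, species code) pair.
#' @export
roster_species <- function(roster) {
  tidyr::separate_rows(
    select(roster, "plot_id", "block", "sown_richness", "species", "replicate"),
    "species", sep = ";"
  ) %>% rename(code = "species")
}

#' Summarise a roster into design margins
#'
#' Reproduces the published design-summary margins: the number of plots per
#' sown richness level and, for every species, how often it occurs in plots
#' of each richness level.
#'
#' @param roster A roster tibble from [build_dominance_roster()].
#' @return A list with two tibbles: `plots` (`sown_richness`, `n_plots`) and
#'   `occurrences` (`code`, `sown_richness`, `n`).
#' @export
summarize_roster <- function(roster) {
  plots <- count(roster, .data$sown_richness, name = "n_plots")
  occ <- roster_species(roster) %>%
    count(.data$code, .data$sown_richness, name = "n")
  list(plots = plots, occurrences = occ)
}
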