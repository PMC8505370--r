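test_that("abundance extrapolates counts to 100 g dry soil", {
  expect_equal(abundance_per_100g(400, 25), 1600)
  expect_equal(abundance_per_100g(0, 20), 0)
  expect_equal(abundance_per_100g(123, 100), 123)
  expect_error(abundance_per_100g(10, 0), class = "nemacomm_domain_error")
})

test_that("genus profiles allocate the identified shares over the total", {
  counts <- tibble::tibble(plot_id = "p1", genus = c("A", "B"),
                           identified_count = c(60L, 40L))
  samples <- tibble::tibble(plot_id = "p1", dry_mass = 25, counted_total = 500L)
  prof <- genus_profiles(counts, samples) # total per 100 g = 2000
  expect_equal(setNames(prof$abundance, prof$genus), c(A = 1200, B = 800))

  # everything identified (counted below the cap): direct scaling
  samples2 <- tibble::tibble(plot_id = "p1", dry_mass = 20, counted_total = 100L)
  counts2 <- tibble::tibble(plot_id = "p1", genus = c("A", "B"),
                            identified_count = c(70L, 30L))
  prof2 <- genus_profiles(counts2, samples2)
  expect_equal(prof2$abundance, c(70, 30) * 100 / 20)

  # a single-genus sample carries the whole total
  prof3 <- genus_profiles(
    tibble::tibble(plot_id = "p1", genus = "A", identified_count = 10L),
    tibble::tibble(plot_id = "p1", dry_mass = 10, counted_total = 80L)
  )
  expect_equal(prof3$abundance, 800)

  expect_error(
    genus_profiles(counts, dplyr::mutate(samples, counted_total = 0L)),
    class = "nemacomm_inconsistency_error"
  )
})

test_that("diversity metrics match direct summation", {
  prof <- tibble::tibble(plot_id = "p1", genus = c("A", "B", "C"),
                         abundance = c(50, 30, 20))
  dm <- diversity_metrics(prof)
  expect_equal(dm$genus_richness, 3)
  expect_equal(dm$shannon, -sum(c(.5, .3, .2) * log(c(.5, .3, .2))))
  expect_equal(round(dm$shannon, 4), 1.0297)

  uni <- tibble::tibble(plot_id = "u", genus = letters[1:4], abundance = rep(5, 4))
  expect_equal(diversity_metrics(uni)$shannon, log(4))

  single <- tibble::tibble(plot_id = "s", genus = "a", abundance = 3)
  expect_equal(diversity_metrics(single)$shannon, 0)
})

test_that("trophic summaries, ratios and c-p classes follow the annotations", {
  ann <- tiny_annotations()
  prof <- tibble::tibble(
    plot_id = "p1",
    genus = c("Helicotylenchus", "Plectus", "Aphelenchus"),
    abundance = c(100, 50, 50)
  )
  ts <- trophic_summary(prof, ann)
  expect_equal(ts$pf, 100); expect_equal(ts$bf, 50); expect_equal(ts$ff, 50)
  expect_equal(ts$bf_rich, 1L)

  tr <- trophic_ratios(
    tibble::tibble(pf = c(60, 100), bf = c(150, 0), ff = c(50, 0),
                   pr = c(20, 0), om = c(10, 0)),
    root_mass = c(NA, 0.01)
  )
  expect_equal(tr$channel[1], 0.25)
  expect_equal(tr$predator_prey[1], 0.5)
  expect_equal(round(tr$grazing_pressure[2], 4), 9.2103)
  expect_true(is.na(tr$channel[2]))       # FF + BF = 0
  expect_true(is.na(tr$grazing_pressure[1])) # no root mass

  profile <- tibble::tibble(
    plot_id = "p1",
    genus = c("Protorhabditis", "Plectus", "Prodesmodora", "Clarkus",
              "Prodorylaimus", "Helicotylenchus"),
    abundance = c(10, 20, 5, 3, 2, 50)
  )
  cp <- cp_class_abundances(profile, ann)
  expect_equal(unlist(cp[, c("cp12", "cp3", "cp4", "cp5")]),
               c(cp12 = 30, cp3 = 5, cp4 = 3, cp5 = 2))
  mi <- maturity_index(profile, ann)
  expect_equal(mi$mi, (10 * 1 + 20 * 2 + 5 * 3 + 3 * 4 + 2 * 5) / 40)
  expect_equal(mi$mi, 2.175)

  all_pf <- tibble::tibble(plot_id = "p", genus = c("Helicotylenchus", "Lelenchus"),
                           abundance = c(5, 5))
  expect_equal(sum(unlist(cp_class_abundances(all_pf, ann)[, -1])), 0)
  expect_true(is.na(maturity_index(all_pf, ann)$mi))
  # constant-class communities pin the index to the class value
  all2 <- tibble::tibble(plot_id = "p", genus = c("Plectus", "Aphelenchus"),
                         abundance = c(1, 9))
  expect_equal(maturity_index(all2, ann)$mi, 2)
})

test_that("enrichment and structure indices evaluate the weighted quotients", {
  ann <- tiny_annotations()
  w <- default_guild_weights()
  bf1 <- tibble::tibble(plot_id = "a", genus = "Protorhabditis", abundance = 7)
  es <- enrichment_structure_indices(bf1, ann, w)
  expect_equal(es$ei, 100) # no basal component present
  bf2 <- tibble::tibble(plot_id = "a", genus = "Plectus", abundance = 7)
  es2 <- enrichment_structure_indices(bf2, ann, w)
  expect_equal(es2$ei, 0); expect_equal(es2$si, 0)
  mix <- tibble::tibble(
    plot_id = "a",
    genus = c("Protorhabditis", "Plectus", "Bacillonema"),
    abundance = c(10, 10, 10)
  ) # weights 3.2 (enrichment), 0.8 (basal), 5.0 (structure)
  es3 <- enrichment_structure_indices(mix, ann, w)
  expect_equal(es3$ei, 80)
  expect_equal(es3$si, 100 * 50 / 58)
  expect_equal(round(es3$si, 2), 86.21)
})

test_that("community-weighted means are biomass-weighted dot products", {
  expect_equal(community_weighted_mean(c(0.5, 0.5), c(20, 30)), 25)
  expect_equal(community_weighted_mean(1, 17), 17)
  expect_equal(community_weighted_mean(c(0.25, 0.75), c(12, 20)), 18)
  expect_error(community_weighted_mean(c(0.5, 0.2), c(1, 2)),
               class = "nemacomm_input_error")
  expect_error(community_weighted_mean(c(0.5, 0.5), 1),
               class = "nemacomm_input_error")
})

test_that("D_max benchmarks mixtures against their best monoculture", {
  expect_equal(dmax(10, c(10, 4))$dmax, 0)
  expect_equal(dmax(15, c(10, 8))$dmax, 0.5)
  expect_equal(dmax(4, c(10, 5), direction = "min")$dmax, -0.2)
  expect_true(is.na(dmax(3, c(0, 0))$dmax))
  expect_error(dmax(3, numeric(0)), class = "nemacomm_input_error")

  # over a roster: benchmark from constituent monocultures only
  roster <- build_dominance_roster()
  vals <- tibble::tibble(plot_id = roster$plot_id,
                         value = seq_len(nrow(roster)))
  dt <- dmax_table(vals, roster)
  expect_true(all(dt$sown_richness > 1))
  one_mix <- dt[1, ]
  codes <- strsplit(one_mix$species, ";")[[1]]
  monos <- roster_species(roster) %>%
    dplyr::filter(sown_richness == 1, code %in% codes) %>%
    dplyr::left_join(vals, by = "plot_id")
  expect_equal(one_mix$benchmark, max(monos$value))
})

test_that("the index engine agrees with the naive-loop oracle", {
  ann <- tiny_annotations()
  w <- default_guild_weights()
  profs <- random_profiles(60, ann, seed = 42)
  counts <- profs %>%
    dplyr::mutate(identified_count = as.integer(ceiling(abundance))) %>%
    dplyr::select(plot_id, genus, identified_count)
  samples <- counts %>%
    dplyr::group_by(plot_id) %>%
    dplyr::summarise(counted_total = sum(identified_count)) %>%
    dplyr::mutate(dry_mass = 100) # identity scale: abundance = counts
  idx <- compute_indices(counts, samples, ann, w)
  for (i in seq_len(nrow(idx))) {
    pid <- idx$plot_id[i]
    sub <- counts[counts$plot_id == pid, ]
    ab <- setNames(as.numeric(sub$identified_count), sub$genus)
    o <- oracle_index_set(ab, ann, w)
    expect_rel_equal(idx$total_per_100g[i], o$total)
    expect_rel_equal(idx$genus_richness[i], o$genus_richness)
    expect_rel_equal(idx$shannon[i], o$shannon)
    for (col in c("pf", "bf", "ff", "pr", "om", "ompr", "predator_prey",
                  "channel", "cp12", "cp3", "cp4", "cp5", "mi", "ei", "si")) {
      expect_rel_equal(idx[[col]][i], o[[col]])
    }
  }
})

test_that("ratio and index metrics are invariant to abundance rescaling", {
  ann <- tiny_annotations()
  w <- default_guild_weights()
  profs <- random_profiles(10, ann, seed = 7)
  scaled <- dplyr::mutate(profs, abundance = abundance * 37.5)
  inv_cols <- c("shannon", "channel", "predator_prey", "mi", "ei", "si")
  a <- dplyr::bind_cols(
    diversity_metrics(profs),
    trophic_ratios(trophic_summary(profs, ann))[inv_cols[2:3]],
    maturity_index(profs, ann)["mi"],
    enrichment_structure_indices(profs, ann, w)[c("ei", "si")]
  )
  b <- dplyr::bind_cols(
    diversity_metrics(scaled),
    trophic_ratios(trophic_summary(scaled, ann))[inv_cols[2:3]],
    maturity_index(scaled, ann)["mi"],
    enrichment_structure_indices(scaled, ann, w)[c("ei", "si")]
  )
  expect_equal(a[inv_cols], b[inv_cols], tolerance = 1e-12)
})

test_that("merging identically annotated genera preserves trophic metrics", {
  ann <- tiny_annotations()
  # Plectus and a clone share BF2; merge the clone into Plectus
  ann2 <- rbind(ann, tibble::tibble(genus = "Plectoides", trophic = "BF", cp = 2L))
  prof_split <- tibble::tibble(
    plot_id = "p", genus = c("Plectus", "Plectoides", "Clarkus"),
    abundance = c(30, 20, 10)
  )
  prof_merged <- tibble::tibble(
    plot_id = "p", genus = c("Plectus", "Clarkus"), abundance = c(50, 10)
  )
  w <- default_guild_weights()
  for (fn in list(
    function(p, a) trophic_summary(p, a)[c("pf", "bf", "ff", "pr", "om")],
    function(p, a) cp_class_abundances(p, a)[, -1],
    function(p, a) maturity_index(p, a)["mi"],
    function(p, a) enrichment_structure_indices(p, a, w)[c("ei", "si")]
  )) {
    expect_equal(fn(prof_split, ann2), fn(prof_merged, ann2), tolerance = 1e-12)
  }
  # merging can only decrease richness and diversity
  expect_gt(diversity_metrics(prof_split)$genus_richness,
            diversity_metrics(prof_merged)$genus_richness)
  expect_gte(diversity_metrics(prof_split)$shannon,
             diversity_metrics(prof_merged)$shannon)
})
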