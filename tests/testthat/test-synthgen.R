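test_that("the same seed reproduces the whole dataset bit for bit", {
  cfg <- synth_config(seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
})

test_that("configuration validation catches impossible settings", {
  expect_error(synth_config(paths = c(bf_corg = NaN, pf_cn = 0, pf_shoot = 0,
                                      ompr_bf = 0, ompr_pf = 0)),
               class = "nemacomm_config_error")
  expect_error(synth_config(nb_size = 0), class = "nemacomm_config_error")
  expect_error(synth_config(cap = 0), class = "nemacomm_config_error")
})

test_that("a degenerate noise-free generator is constant, then monotone", {
  roster <- build_dominance_roster()
  base <- synth_config(seed = 3, block_sd = 0)
  base$sigma[] <- 0
  flat <- base; flat$beta[] <- 0
  cov_flat <- generate_covariates(flat, roster)
  for (v in c("shoot_mass", "root_mass", "srl", "cn_leaf", "soil_corg", "soil_n")) {
    expect_equal(length(unique(cov_flat[[v]])), 1)
  }
  # positive slope, no noise: shoot mass strictly increases with richness
  cov_inc <- generate_covariates(base, roster)
  agg <- tapply(cov_inc$shoot_mass, cov_inc$sown_richness, unique)
  expect_true(all(diff(agg[order(as.numeric(names(agg)))]) > 0))
})

test_that("soil carbon and nitrogen attain the configured correlation", {
  cfg <- synth_config(seed = 21)
  roster_big <- replicated_roster(11)[1:1000, ] # 1000 plots
  cv <- generate_covariates(cfg, roster_big)
  expect_lt(abs(cor(cv$soil_corg, cv$soil_n) - cfg$soil_cn_cor), 0.05)
})

test_that("identification is capped at 100 individuals, else exhaustive", {
  ann <- default_annotations()
  roster <- build_dominance_roster()[1, ]
  cfg <- synth_config(seed = 5)
  m <- generate_covariates(cfg, roster)
  set.seed(11)
  s <- generate_nematode_sample(cfg, m, ann)
  expect_gt(s$counted_total, cfg$cap) # defaults count ~400 per sample
  expect_equal(sum(s$identified), cfg$cap)

  sparse <- synth_config(seed = 5,
                         group_base = c(pf = 4, bf = 2, ff = 2, ompr = 2),
                         refs = c(corg = 20, cn = 20, shoot = 300, bf = 2, pf = 4))
  set.seed(11)
  s2 <- generate_nematode_sample(sparse, m, ann)
  expect_lt(s2$counted_total, sparse$cap)
  expect_equal(sum(s2$identified), s2$counted_total)
  expect_true(all(names(s$identified) %in% ann$genus))
})

test_that("the bacterial-feeder link has the configured log-linear slope", {
  cfg <- synth_config(seed = 1)
  g <- cfg$paths[["bf_corg"]]
  m <- tibble::tibble(soil_corg = c(20, 21), cn_leaf = 20, shoot_mass = 300)
  ex <- expected_group_abundance(cfg, m)
  expect_equal(ex$bf[2] / ex$bf[1], exp(g))
  expect_equal(ex$ff[1], ex$ff[2]) # fungal feeders are flat
})

test_that("datasets carry the root-missing pattern and sane realized richness", {
  ds <- generate_dataset(synth_config(seed = 13))
  expect_equal(nrow(ds$covariates), 93)
  expect_equal(sum(!is.na(ds$covariates$root_mass)), 86)
  miss <- ds$covariates[is.na(ds$covariates$root_mass), ]
  expect_true(all(miss$sown_richness == 1 & miss$replicate == 2))
  expect_true(all(ds$covariates$realized_richness >= 1))
  expect_true(all(ds$covariates$realized_richness <=
                    pmin(ds$covariates$sown_richness, 7)))
  # grasses never go extinct: grass-only plots keep all sown targets
  targets <- dominance_species()$code[dominance_species()$target]
  grasses <- dominance_species()$code[dominance_species()$functional_group == "grass"]
  rs <- roster_species(ds$roster) %>%
    dplyr::group_by(plot_id) %>%
    dplyr::summarise(n_target = sum(code %in% targets),
                     all_grass = all(code %in% grasses))
  joined <- dplyr::left_join(ds$covariates, rs, by = "plot_id")
  g <- joined[joined$all_grass, ]
  expect_equal(g$realized_richness, g$n_target)
})

test_that("plots and samples line up and dry masses respect truncation", {
  ds <- generate_dataset(synth_config(seed = 29))
  expect_setequal(ds$samples$plot_id, ds$covariates$plot_id)
  expect_true(all(ds$counts$plot_id %in% ds$samples$plot_id))
  expect_true(all(ds$samples$dry_mass >= 10))
  per_plot <- ds$counts %>%
    dplyr::group_by(plot_id) %>%
    dplyr::summarise(ident = sum(identified_count)) %>%
    dplyr::left_join(ds$samples, by = "plot_id")
  expect_true(all(per_plot$ident == pmin(per_plot$counted_total, 100L)))
})
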