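# Independent naive-loop oracles for the metric engine, plus small fixtures.
# These deliberately avoid every package code path they check.

tiny_annotations <- function() {
  tibble::tribble(
    ~genus,        ~trophic, ~cp,
    "Protorhabditis", "BF",  1L,
    "Plectus",        "BF",  2L,
    "Prodesmodora",   "BF",  3L,
    "Alaimus",        "BF",  4L,
    "Bacillonema",    "BF",  5L, # synthetic BF5 genus for weight coverage
    "Aphelenchus",    "FF",  2L,
    "Diphtherophora", "FF",  3L,
    "Helicotylenchus","PF",  3L,
    "Lelenchus",      "PF",  2L,
    "Clarkus",        "Pr",  4L,
    "Prodorylaimus",  "Om",  5L
  )
}

# one random long profile table over the given annotation genera
random_profiles <- function(n_plots, annotations = tiny_annotations(),
                            seed = 1, max_genera = nrow(annotations)) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_plots), function(i) {
    k <- sample(2:max_genera, 1)
    gs <- sample(annotations$genus, k)
    tibble::tibble(
      plot_id = sprintf("p%03d", i),
      genus = gs,
      abundance = round(stats::rlnorm(k, log(50), 1), 4)
    )
  })
}

# naive loop computation of every per-plot metric from a named abundance
# vector (per 100 g), an annotation table and a guild weight table
oracle_index_set <- function(ab, ann, weights, root_mass = NA) {
  ab <- ab[ab > 0]
  total <- 0
  for (v in ab) total <- total + v
  rich <- length(ab)
  shan <- NA_real_
  if (total > 0) {
    shan <- 0
    for (v in ab) {
      q <- v / total
      shan <- shan - q * log(q)
    }
  }
  look <- function(g, col) {
    i <- which(tolower(ann$genus) == tolower(g))
    ann[[col]][i]
  }
  groups <- c(PF = 0, BF = 0, FF = 0, Pr = 0, Om = 0)
  grich <- c(PF = 0, BF = 0, FF = 0, Pr = 0, Om = 0)
  for (g in names(ab)) {
    tr <- look(g, "trophic")
    groups[tr] <- groups[tr] + ab[[g]]
    grich[tr] <- grich[tr] + 1
  }
  pp <- if (groups[["PF"]] > 0) {
    (groups[["Pr"]] + groups[["Om"]]) / groups[["PF"]]
  } else NA_real_
  ch <- if (groups[["FF"]] + groups[["BF"]] > 0) {
    groups[["FF"]] / (groups[["FF"]] + groups[["BF"]])
  } else NA_real_
  gr <- if (groups[["PF"]] > 0 && !is.na(root_mass) && root_mass > 0) {
    log(groups[["PF"]] / root_mass)
  } else NA_real_
  cp <- c(cp12 = 0, cp3 = 0, cp4 = 0, cp5 = 0)
  mi_num <- 0; mi_den <- 0
  e <- 0; b <- 0; s <- 0
  for (g in names(ab)) {
    tr <- look(g, "trophic"); v <- look(g, "cp")
    if (tr == "PF") next
    cls <- if (v <= 2) "cp12" else paste0("cp", v)
    cp[cls] <- cp[cls] + ab[[g]]
    mi_num <- mi_num + v * ab[[g]]
    mi_den <- mi_den + ab[[g]]
    gu <- paste0(tr, v)
    for (r in seq_len(nrow(weights))) {
      if (weights$guild[r] == gu) {
        if (weights$component[r] == "enrichment") e <- e + weights$weight[r] * ab[[g]]
        if (weights$component[r] == "basal") b <- b + weights$weight[r] * ab[[g]]
        if (weights$component[r] == "structure") s <- s + weights$weight[r] * ab[[g]]
      }
    }
  }
  list(
    total = total, genus_richness = rich, shannon = shan,
    pf = groups[["PF"]], bf = groups[["BF"]], ff = groups[["FF"]],
    pr = groups[["Pr"]], om = groups[["Om"]],
    ompr = groups[["Pr"]] + groups[["Om"]],
    pf_rich = grich[["PF"]], bf_rich = grich[["BF"]], ff_rich = grich[["FF"]],
    predator_prey = pp, channel = ch, grazing_pressure = gr,
    cp12 = cp[["cp12"]], cp3 = cp[["cp3"]], cp4 = cp[["cp4"]], cp5 = cp[["cp5"]],
    mi = if (mi_den > 0) mi_num / mi_den else NA_real_,
    ei = if (e + b > 0) 100 * e / (e + b) else NA_real_,
    si = if (s + b > 0) 100 * s / (s + b) else NA_real_
  )
}

# compare a package value against the oracle with relative tolerance
expect_rel_equal <- function(x, y, tol = 1e-12) {
  if (is.na(x) && is.na(y)) return(invisible(TRUE))
  expect_false(is.na(x) != is.na(y))
  denom <- max(abs(y), 1)
  expect_lt(abs(x - y) / denom, tol)
}

# a fast roster stand-in: replicate the dominance roster with fresh ids
replicated_roster <- function(times) {
  r <- build_dominance_roster()
  purrr::map_dfr(seq_len(times), function(i) {
    dplyr::mutate(r, plot_id = paste0(plot_id, "_c", i))
  })
}
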