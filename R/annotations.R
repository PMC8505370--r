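#' Genus annotations: trophic groups and colonizer-persister classes
#'
#' Every faunal index in this package is built on a reference table assigning
#' each nematode genus a trophic group -- plant feeder (`PF`), bacterial feeder
#' (`BF`), fungal feeder (`FF`), predator (`Pr`), omnivore (`Om`) -- and a
#' colonizer-persister (c-p) life-history class from 1 (fast, disturbance
#' tolerant) to 5 (slow, sensitive). `load_annotation_table()` reads and
#' validates such a table from a delimited text file;
#' [default_annotations()] returns the 51-genus table shipped with the package.
#'
#' Genus names are matched case-insensitively after whitespace trimming
#' throughout the package, because field tables vary in capitalisation.
#'
#' @param path Path to a delimited text file with columns `genus`, `trophic`
#'   and `cp` (extra columns are kept). Field delimiter is auto-detected by
#'   [readr::read_delim()].
#' @return A tibble with columns `genus` (character), `trophic` (character,
#'   one of PF/BF/FF/Pr/Om) and `cp` (integer in 1..5), plus any extra columns.
#' @examples
#' ann <- default_annotations()
#' dplyr::filter(ann, genus == "Filenchus")
#' @export
load_annotation_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path), class = "nemacomm_format_error")
  }
  tab <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  validate_annotations(as_tibble(tab))
}

.nema_cache <- new.env(parent = emptyenv())

#' @rdname load_annotation_table
#' @export
default_annotations <- function() {
  if (is.null(.nema_cache$annotations)) {
    .nema_cache$annotations <- load_annotation_table(
      system.file("extdata", "genus_annotations.tsv", package = "nemacomm",
                  mustWork = TRUE)
    )
  }
  .nema_cache$annotations
}

#' Write an annotation table back to disk
#'
#' Tab-separated; a round trip through [load_annotation_table()] reproduces
#' the table exactly.
#'
#' @param annotations An annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  annotations <- validate_annotations(annotations)
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

trophic_levels <- c("PF", "BF", "FF", "Pr", "Om")

validate_annotations <- function(tab) {
  needed <- c("genus", "trophic", "cp")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(
      paste0("annotation table lacks column(s): ", paste(missing_cols, collapse = ", ")),
      class = "nemacomm_format_error"
    )
  }
  tab$genus <- trimws(tab$genus)
  dup <- unique(tab$genus[duplicated(tolower(tab$genus))])
  if (length(dup) > 0) {
    abort(
      paste0("duplicate genus name(s) in annotation table: ", paste(dup, collapse = ", ")),
      class = "nemacomm_validation_error"
    )
  }
  bad_troph <- unique(tab$trophic[!tab$trophic %in% trophic_levels])
  if (length(bad_troph) > 0) {
    abort(
      paste0("unknown trophic group(s): ", paste(bad_troph, collapse = ", "),
             " (expected PF, BF, FF, Pr, Om)"),
      class = "nemacomm_validation_error"
    )
  }
  cp <- tab$cp
  if (!is.numeric(cp) || any(is.na(cp)) || any(cp != as.integer(cp)) ||
      any(cp < 1) || any(cp > 5)) {
    bad <- tab$genus[is.na(cp) | !cp %in% 1:5]
    abort(
      paste0("c-p class must be an integer in 1..5; offending genus/genera: ",
             paste(bad, collapse = ", ")),
      class = "nemacomm_validation_error"
    )
  }
  tab$cp <- as.integer(tab$cp)
  tab
}

#' Functional guild code of an annotated genus
#'
#' The guild is the trophic abbreviation concatenated with the c-p digit,
#' e.g. a colonizing bacterial feeder is `"BF1"`, a persister omnivore `"Om5"`.
#' Guilds key the weight table used by the Enrichment and Structure indices.
#'
#' @param trophic Character vector of trophic codes (PF/BF/FF/Pr/Om).
#' @param cp Integer vector of c-p classes (1..5), recycled against `trophic`.
#' @return Character vector of guild codes.
#' @examples
#' guild_code("BF", 1) # "BF1"
#' @export
guild_code <- function(trophic, cp) {
  stopifnot(all(trophic %in% trophic_levels), all(cp %in% 1:5))
  paste0(trophic, as.integer(cp))
}

#' Check annotation coverage of a set of observed genera
#'
#' Lists genera present in a count table or community profile but absent from
#' the annotation table (case-insensitive match). An empty result means full
#' coverage; index functions refuse profiles with unannotated genera.
#'
#' @param annotations An annotation tibble (see [load_annotation_table()]).
#' @param genera Character vector of genus names, or a data frame with a
#'   `genus` column.
#' @return A tibble with column `genus` listing the unannotated genera
#'   (zero rows iff coverage is complete).
#' @export
validate_annotation_table <- function(annotations, genera) {
  annotations <- validate_annotations(annotations)
  if (is.data.frame(genera)) genera <- genera$genus
  genera <- unique(trimws(as.character(genera)))
  missing <- genera[!tolower(genera) %in% tolower(annotations$genus)]
  tibble(genus = missing)
}

# Join observed genus names onto the annotation table (case-insensitive);
# errors listing any unannotated genus.
annotate_genera <- function(genera, annotations) {
  annotations <- validate_annotations(annotations)
  missing <- validate_annotation_table(annotations, genera)
  if (nrow(missing) > 0) {
    abort(
      paste0("unannotated genus/genera: ", paste(missing$genus, collapse = ", ")),
      class = "nemacomm_annotation_gap"
    )
  }
  idx <- match(tolower(trimws(genera)), tolower(annotations$genus))
  tibble(
    genus = genera,
    trophic = annotations$trophic[idx],
    cp = annotations$cp[idx],
    guild = guild_code(annotations$trophic[idx], annotations$cp[idx])
  )
}

#' Guild weight tables for the Enrichment and Structure indices
#'
#' The Enrichment Index (EI) and Structure Index (SI) weight functional guilds
#' (trophic group x c-p class) as members of an *enrichment*, *basal* or
#' *structure* food-web component. The default table follows the classical
#' faunal-analysis weighting: enrichment = BF1 (3.2) and FF2 (0.8); basal =
#' BF2 and FF2 (0.8 each; FF2 contributes to both enrichment and basal);
#' structure = all BF/FF/Om guilds with c-p >= 3 and Pr guilds with c-p >= 2,
#' weighted 0.8 / 1.8 / 3.2 / 5.0 for c-p 2 / 3 / 4 / 5. Plant-feeder guilds
#' are excluded. The table is an input, not a constant: substitute any
#' published weighting by pointing `load_guild_weights()` at your own file.
#'
#' @param path Delimited text file with columns `guild`, `component`
#'   (`enrichment`, `basal`, `structure` or `excluded`) and `weight`
#'   (nonnegative).
#' @return A tibble with columns `guild`, `component`, `weight`.
#' @export
load_guild_weights <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("guild weight file not found: ", path), class = "nemacomm_format_error")
  }
  tab <- as_tibble(readr::read_delim(path, show_col_types = FALSE, progress = FALSE))
  validate_guild_weights(tab)
}

#' @rdname load_guild_weights
#' @export
default_guild_weights <- function() {
  if (is.null(.nema_cache$weights)) {
    .nema_cache$weights <- load_guild_weights(
      system.file("extdata", "guild_weights.tsv", package = "nemacomm",
                  mustWork = TRUE)
    )
  }
  .nema_cache$weights
}

#' @rdname load_guild_weights
#' @param weights A guild weight tibble to validate.
#' @export
validate_guild_weights <- function(weights) {
  needed <- c("guild", "component", "weight")
  missing_cols <- setdiff(needed, names(weights))
  if (length(missing_cols) > 0) {
    abort(
      paste0("guild weight table lacks column(s): ", paste(missing_cols, collapse = ", ")),
      class = "nemacomm_format_error"
    )
  }
  ok_comp <- c("enrichment", "basal", "structure", "excluded")
  if (!all(weights$component %in% ok_comp)) {
    abort("guild weight component must be enrichment, basal, structure or excluded",
          class = "nemacomm_validation_error")
  }
  if (any(weights$weight < 0)) {
    abort("guild weights must be nonnegative", class = "nemacomm_validation_error")
  }
  if (anyDuplicated(weights[, c("guild", "component")])) {
    abort("duplicate (guild, component) entries in weight table",
          class = "nemacomm_validation_error")
  }
  # every free-living guild must resolve; PF guilds must be excluded
  free_guilds <- as.vector(outer(c("BF", "FF", "Om", "Pr"), 1:5, paste0))
  uncovered <- setdiff(free_guilds, weights$guild)
  if (length(uncovered) > 0) {
    abort(
      paste0("guild(s) without a component assignment: ", paste(uncovered, collapse = ", ")),
      class = "nemacomm_validation_error"
    )
  }
  pf <- weights[startsWith(weights$guild, "PF"), ]
  if (nrow(pf) > 0 && !all(pf$component == "excluded")) {
    abort("plant-feeder guilds must have component = excluded",
          class = "nemacomm_validation_error")
  }
  weights
}
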