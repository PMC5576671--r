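# Survey data model: belt-transect underwater visual census of seagrass fish,
# plus quadrat-based seagrass cover. Long-format tables, one row per observed
# fish / per cover quadrat.

SEASONS <- c("SR", "LR", "D")
MANAGEMENT_LEVELS <- c("MPA", "open")
AGE_CLASSES <- c("juvenile", "subadult", "adult")

#' Describe a transect survey design
#'
#' A design lists the surveyed sites, their management level (marine protected
#' area vs open-access), how many replicate belt transects each site received
#' per season, and the ordered set of seasons. The default mirrors a common
#' East African monsoon design: four sites (two MPA, two open-access) with
#' 10/7/10/10 transects of 25 x 4 m (100 m^2), revisited in three seasons
#' (SR = short rains, LR = long rains, D = dry), i.e. (10+10+10+7) x 3 = 111
#' transect records in total.
#'
#' @param sites character vector of site labels.
#' @param management management level per site, each `"MPA"` or `"open"`.
#' @param transects_per_site integer vector, transects surveyed per site in
#'   each season.
#' @param seasons ordered character vector of season codes; the order is the
#'   chronological order used by trajectory metrics.
#' @param area_m2 area of one belt transect in square metres.
#' @param quadrats_per_transect number of cover quadrats per transect.
#' @return An object of class `"survey_design"`.
#' @examples
#' d <- survey_design()
#' sum(d$sites$transects) * length(d$seasons) # 111
#' @export
survey_design <- function(sites = c("MPA1", "MPA2", "OA1", "OA2"),
                          management = c("MPA", "MPA", "open", "open"),
                          transects_per_site = c(10L, 7L, 10L, 10L),
                          seasons = SEASONS,
                          area_m2 = 100,
                          quadrats_per_transect = 6L) {
  stopifnot(length(sites) == length(management),
            length(sites) == length(transects_per_site),
            all(management %in% MANAGEMENT_LEVELS),
            !anyDuplicated(sites),
            area_m2 > 0, quadrats_per_transect >= 1)
  structure(list(
    sites = data.frame(site = as.character(sites),
                       management = as.character(management),
                       transects = as.integer(transects_per_site),
                       stringsAsFactors = FALSE),
    seasons = as.character(seasons),
    area_m2 = area_m2,
    quadrats_per_transect = as.integer(quadrats_per_transect)
  ), class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design:", nrow(x$sites), "sites,", length(x$seasons),
      "seasons,", sum(x$sites$transects) * length(x$seasons),
      "transect records\n")
  print(x$sites, row.names = FALSE)
  cat("Seasons:", paste(x$seasons, collapse = " -> "),
      "| transect area:", x$area_m2, "m^2 |", x$quadrats_per_transect,
      "cover quadrats per transect\n")
  invisible(x)
}

#' Bundle fish and cover tables into a survey object
#'
#' @param fish data.frame with columns `site, management, season, transect,
#'   species, family, functional_group, length_cm` (one row per fish).
#' @param cover data.frame with columns `site, management, season, transect,
#'   quadrat, cover_pct` (one row per quadrat).
#' @param design a [survey_design()].
#' @param species_table optional data.frame with columns `species, family,
#'   functional_group, lmax_cm` and optionally `cut1_cm, cut2_cm`, used to
#'   build age-class rules.
#' @return An object of class `"seagrass_survey"`.
#' @export
seagrass_survey <- function(fish, cover, design = survey_design(),
                            species_table = NULL) {
  need_fish <- c("site", "management", "season", "transect", "species",
                 "family", "functional_group", "length_cm")
  need_cov <- c("site", "management", "season", "transect", "quadrat",
                "cover_pct")
  miss <- setdiff(need_fish, names(fish))
  if (length(miss)) stop("fish table lacks columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(need_cov, names(cover))
  if (length(miss)) stop("cover table lacks columns: ", paste(miss, collapse = ", "))
  structure(list(fish = as.data.frame(fish), cover = as.data.frame(cover),
                 design = design, species_table = species_table),
            class = "seagrass_survey")
}

#' @export
print.seagrass_survey <- function(x, ...) {
  cat("Seagrass fish survey:", nrow(x$fish), "fish observations,",
      length(unique(x$fish$species)), "taxa,",
      nrow(unique(x$cover[c("site", "season", "transect")])),
      "transect records\n")
  invisible(x)
}

# Roster of transect records present in the survey (from the cover table,
# which has a fixed number of rows per transect, so empty transects with no
# fish are still represented).
transect_roster <- function(survey) {
  r <- unique(survey$cover[c("site", "management", "season", "transect")])
  r <- r[order(r$site, match(r$season, survey$design$seasons), r$transect), ]
  rownames(r) <- NULL
  r
}

#' Age-class rules from a species table
#'
#' Builds per-species length cut-points separating juveniles, subadults and
#' adults. Where explicit `cut1_cm`/`cut2_cm` columns are present they are
#' used; otherwise cut-points default to one third and two thirds of the
#' species' maximum length (`lmax_cm`), a standard fraction-of-maximum-length
#' staging when published stage tables are unavailable.
#'
#' @param species_table data.frame with columns `species`, `lmax_cm` and
#'   optionally `cut1_cm`, `cut2_cm`.
#' @return data.frame with columns `species, cut1_cm, cut2_cm`.
#' @export
age_class_rules <- function(species_table) {
  stopifnot(is.data.frame(species_table), "species" %in% names(species_table))
  n <- nrow(species_table)
  cut1 <- if ("cut1_cm" %in% names(species_table)) species_table$cut1_cm else rep(NA_real_, n)
  cut2 <- if ("cut2_cm" %in% names(species_table)) species_table$cut2_cm else rep(NA_real_, n)
  if ("lmax_cm" %in% names(species_table)) {
    lmax <- species_table$lmax_cm
    cut1 <- ifelse(is.na(cut1), lmax / 3, cut1)
    cut2 <- ifelse(is.na(cut2), 2 * lmax / 3, cut2)
  }
  if (anyNA(cut1) || anyNA(cut2))
    stop("species table must supply lmax_cm or explicit cut points for every species")
  bad <- !(cut1 > 0 & cut2 > cut1)
  if (any(bad))
    stop("invalid cut points (need 0 < cut1 < cut2) for: ",
         paste(species_table$species[bad], collapse = ", "))
  data.frame(species = as.character(species_table$species),
             cut1_cm = cut1, cut2_cm = cut2, stringsAsFactors = FALSE)
}

#' Assign fish to age classes by length
#'
#' Lengths are staged into three classes with half-open intervals:
#' `[0, cut1)` is juvenile, `[cut1, cut2)` is subadult and `[cut2, Inf)` is
#' adult, so a length exactly on a cut-point belongs to the upper class.
#'
#' @param length_cm numeric vector of body lengths (cm).
#' @param species character vector of species labels (recycled if length 1);
#'   may be `NULL` when `default_cuts` is supplied.
#' @param rules data.frame from [age_class_rules()].
#' @param default_cuts optional length-2 numeric `(cut1, cut2)` used for
#'   species absent from `rules` (or for all fish when `rules` is `NULL`).
#' @return factor with levels `juvenile, subadult, adult`.
#' @examples
#' assign_age_class(c(5, 10, 25), default_cuts = c(10, 20))
#' @export
assign_age_class <- function(length_cm, species = NULL, rules = NULL,
                             default_cuts = NULL) {
  stopifnot(is.numeric(length_cm), all(length_cm > 0))
  n <- length(length_cm)
  if (is.null(rules)) {
    if (is.null(default_cuts))
      stop("either 'rules' or 'default_cuts' must be supplied")
    c1 <- rep(default_cuts[1], n); c2 <- rep(default_cuts[2], n)
  } else {
    if (is.null(species)) stop("'species' required when using per-species rules")
    species <- rep_len(as.character(species), n)
    idx <- match(species, rules$species)
    if (anyNA(idx) && is.null(default_cuts)) {
      missing_sp <- unique(species[is.na(idx)])
      stop("no age-class rule for species: ", paste(missing_sp, collapse = ", "))
    }
    c1 <- rules$cut1_cm[idx]; c2 <- rules$cut2_cm[idx]
    if (!is.null(default_cuts)) {
      c1[is.na(c1)] <- default_cuts[1]; c2[is.na(c2)] <- default_cuts[2]
    }
  }
  stopifnot(all(c1 > 0), all(c2 > c1))
  cls <- ifelse(length_cm < c1, "juvenile",
                ifelse(length_cm < c2, "subadult", "adult"))
  factor(cls, levels = AGE_CLASSES)
}

#' Validate a survey against its design
#'
#' Checks the long-format tables for schema violations (unknown season or
#' management labels, cover values outside \[0, 100\], non-positive lengths,
#' wrong quadrat counts, duplicated quadrat indices) and tabulates transect
#' counts per site and season against the design. Validation never throws:
#' it returns a report whose `violations` table is empty for a clean survey.
#'
#' @param survey a [seagrass_survey()].
#' @param design a [survey_design()]; defaults to the survey's own.
#' @return list of class `"survey_validation"` with elements `violations`
#'   (data.frame: table, field, message), `transect_counts`, `n_transects`
#'   and `valid`.
#' @export
validate_survey <- function(survey, design = survey$design) {
  v <- list()
  add <- function(tab, field, message)
    v[[length(v) + 1]] <<- data.frame(table = tab, field = field,
                                      message = message, stringsAsFactors = FALSE)
  fish <- survey$fish; cover <- survey$cover

  for (tab_name in c("fish", "cover")) {
    tab <- survey[[tab_name]]
    bad <- setdiff(unique(tab$season), design$seasons)
    if (length(bad)) add(tab_name, "season", paste("unknown season label:", paste(bad, collapse = ", ")))
    bad <- setdiff(unique(tab$management), MANAGEMENT_LEVELS)
    if (length(bad)) add(tab_name, "management", paste("unknown management label:", paste(bad, collapse = ", ")))
    bad <- setdiff(unique(tab$site), design$sites$site)
    if (length(bad)) add(tab_name, "site", paste("site not in design:", paste(bad, collapse = ", ")))
    mm <- unique(tab[c("site", "management")])
    mm$expected <- design$sites$management[match(mm$site, design$sites$site)]
    bad <- mm$site[!is.na(mm$expected) & mm$management != mm$expected]
    if (length(bad)) add(tab_name, "management", paste("management disagrees with design for site:", paste(bad, collapse = ", ")))
  }
  if (any(fish$length_cm <= 0))
    add("fish", "length_cm", paste(sum(fish$length_cm <= 0), "non-positive lengths"))
  if (any(fish$length_cm %% 5 != 0))
    add("fish", "length_cm", paste(sum(fish$length_cm %% 5 != 0), "lengths not recorded to the nearest 5 cm"))
  if (any(is.na(fish$species) | fish$species == ""))
    add("fish", "species", "empty species labels")
  out_of_range <- cover$cover_pct < 0 | cover$cover_pct > 100
  if (any(out_of_range))
    add("cover", "cover_pct", paste(sum(out_of_range), "cover values outside [0, 100]"))

  key <- interaction(cover$site, cover$season, cover$transect, drop = TRUE)
  nq <- table(key)
  if (any(nq != design$quadrats_per_transect))
    add("cover", "quadrat", paste(sum(nq != design$quadrats_per_transect),
        "transects without exactly", design$quadrats_per_transect, "quadrats"))
  dup <- tapply(cover$quadrat, key, function(q) anyDuplicated(q) > 0)
  if (any(dup))
    add("cover", "quadrat", paste(sum(dup), "transects with duplicated quadrat indices"))

  roster <- transect_roster(survey)
  counts <- as.data.frame(table(site = roster$site, season = roster$season),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n_transects"
  counts$expected <- design$sites$transects[match(counts$site, design$sites$site)]
  off <- counts[!is.na(counts$expected) & counts$n_transects != counts$expected, ]
  if (nrow(off))
    add("cover", "transect", paste("transect count differs from design in",
                                   nrow(off), "site x season cells"))
  # duplicate transect ids are detected as duplicated (site, season, transect)
  # rows carrying conflicting quadrat sets; the quadrat checks above flag them.

  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(table = character(), field = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(list(violations = violations, transect_counts = counts,
                 n_transects = nrow(roster), valid = nrow(violations) == 0L),
            class = "survey_validation")
}

#' @export
print.survey_validation <- function(x, ...) {
  cat("Survey validation:", x$n_transects, "transect records;",
      nrow(x$violations), "violations\n")
  if (nrow(x$violations)) print(x$violations, row.names = FALSE)
  invisible(x)
}

#' Mean seagrass cover of a transect
#'
#' Quadrat subsamples along a transect are averaged before any analysis.
#'
#' @param cover_pct numeric vector of quadrat percent covers in \[0, 100\].
#' @return the arithmetic mean cover (percent).
#' @export
mean_cover <- function(cover_pct) {
  if (length(cover_pct) == 0) stop("no quadrat cover values supplied")
  stopifnot(all(cover_pct >= 0 & cover_pct <= 100))
  mean(cover_pct)
}

#' Per-transect mean cover table
#'
#' @param survey a [seagrass_survey()].
#' @return data.frame with one row per transect: site, management, season,
#'   transect, mean_cover_pct.
#' @export
transect_cover <- function(survey) {
  cov <- survey$cover
  agg <- stats::aggregate(cover_pct ~ site + management + season + transect,
                          data = cov, FUN = mean_cover)
  names(agg)[names(agg) == "cover_pct"] <- "mean_cover_pct"
  agg <- agg[order(agg$site, match(agg$season, survey$design$seasons),
                   agg$transect), ]
  rownames(agg) <- NULL
  agg
}

#' Aggregate survey observations into a density table
#'
#' Builds the species-by-sample matrix the multivariate analyses run on.
#' At transect level each sample is one transect and values are densities per
#' 100 m^2 (count divided by area/100, so with the default 25 x 4 m transect
#' density equals the raw count). At site level each sample is one
#' site x season cell, aggregating the transect values by `sum` (as used for
#' community-structure analyses) or `mean` (as used for synchrony analyses).
#' The species set is the union over the whole survey, so tables filtered to
#' one age class keep all-zero columns and stay conformable.
#'
#' @param survey a [seagrass_survey()].
#' @param level `"transect"` or `"site"`.
#' @param aggregation `"sum"` or `"mean"` (site level only).
#' @param age_class optional: one of `"juvenile"`, `"subadult"`, `"adult"` to
#'   restrict to one age class.
#' @param rules age-class rules (see [age_class_rules()]); required when
#'   `age_class` is given unless the survey carries a species table.
#' @return object of class `"density_table"`: list with `values` (numeric
#'   matrix, samples x species), `samples` (data.frame of grouping labels),
#'   `species`, `level`, `aggregation`.
#' @export
aggregate_density <- function(survey, level = c("transect", "site"),
                              aggregation = c("sum", "mean"),
                              age_class = NULL, rules = NULL) {
  level <- match.arg(level); aggregation <- match.arg(aggregation)
  fish <- survey$fish
  if (nrow(fish) == 0) stop("survey contains no fish observations")
  species <- sort(unique(fish$species))
  if (!is.null(age_class)) {
    if (!age_class %in% AGE_CLASSES)
      stop("unknown age class: ", age_class)
    if (is.null(rules)) {
      if (is.null(survey$species_table))
        stop("age-class rules required to filter by age class")
      rules <- age_class_rules(survey$species_table)
    }
    cls <- assign_age_class(fish$length_cm, fish$species, rules)
    fish <- fish[cls == age_class, , drop = FALSE]
  }

  roster <- transect_roster(survey)
  roster$sample <- paste(roster$site, roster$season, roster$transect, sep = ".")
  values <- matrix(0, nrow(roster), length(species),
                   dimnames = list(roster$sample, species))
  if (nrow(fish)) {
    key <- paste(fish$site, fish$season, fish$transect, sep = ".")
    tab <- table(factor(key, levels = roster$sample),
                 factor(fish$species, levels = species))
    values <- values + unclass(tab)
  }
  values <- values / (survey$design$area_m2 / 100)  # density per 100 m^2

  if (level == "site") {
    cell <- paste(roster$site, roster$season, sep = ".")
    agg <- rowsum(values, cell)
    if (aggregation == "mean") agg <- agg / as.vector(table(cell)[rownames(agg)])
    cells <- unique(roster[c("site", "management", "season")])
    cells$sample <- paste(cells$site, cells$season, sep = ".")
    cells <- cells[order(cells$site, match(cells$season, survey$design$seasons)), ]
    values <- agg[cells$sample, , drop = FALSE]
    samples <- cells
  } else {
    samples <- roster
  }
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, species = species,
                 level = level, aggregation = aggregation,
                 age_class = age_class %||% "all"),
            class = "density_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.density_table <- function(x, ...) {
  cat("Density table (", x$level, " level, ", x$aggregation, "; age class: ",
      x$age_class, "): ", nrow(x$values), " samples x ", ncol(x$values),
      " species\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.density_table <- function(x, ...) x$values

#' Read a survey from CSV files
#'
#' @param fish_csv,cover_csv paths to the long-format fish and cover tables.
#' @param species_csv optional path to the species table
#'   (`species,family,functional_group,lmax_cm[,cut1_cm,cut2_cm]`).
#' @param design a [survey_design()].
#' @return a [seagrass_survey()].
#' @export
read_survey <- function(fish_csv, cover_csv, species_csv = NULL,
                        design = survey_design()) {
  fish <- utils::read.csv(fish_csv, stringsAsFactors = FALSE)
  cover <- utils::read.csv(cover_csv, stringsAsFactors = FALSE)
  sp <- if (!is.null(species_csv)) utils::read.csv(species_csv, stringsAsFactors = FALSE)
  seagrass_survey(fish, cover, design, species_table = sp)
}

#' Write a survey to CSV files
#'
#' @param survey a [seagrass_survey()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_survey <- function(survey, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fish = file.path(dir, "fish.csv"),
             cover = file.path(dir, "cover.csv"))
  utils::write.csv(survey$fish, paths["fish"], row.names = FALSE)
  utils::write.csv(survey$cover, paths["cover"], row.names = FALSE)
  if (!is.null(survey$species_table)) {
    paths <- c(paths, species = file.path(dir, "species.csv"))
    utils::write.csv(survey$species_table, paths["species"], row.names = FALSE)
  }
  invisible(paths)
}
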