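# Shared fixtures: a tiny hand-built survey and constructors for the small
# synthetic configurations the tests reuse.

# two sites (one MPA, one open), two transects each, two seasons, two species
tiny_survey <- function() {
  design <- survey_design(sites = c("A", "B"), management = c("MPA", "open"),
                          transects_per_site = c(2L, 2L),
                          seasons = c("SR", "LR"))
  grid <- expand.grid(site = c("A", "B"), season = c("SR", "LR"),
                      transect = c("T01", "T02"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$management <- ifelse(grid$site == "A", "MPA", "open")
  cover <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    data.frame(grid[i, c("site", "management", "season", "transect")],
               quadrat = 1:6, cover_pct = c(40, 50, 60, 50, 40, 60),
               row.names = NULL)))
  fish <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    n1 <- 2 + (i %% 3); n2 <- 1 + (i %% 2)
    data.frame(grid[i, c("site", "management", "season", "transect")],
               species = rep(c("spA", "spB"), c(n1, n2)),
               family = rep(c("famA", "famB"), c(n1, n2)),
               functional_group = "herbivore",
               length_cm = rep(c(10, 25), c(n1, n2)), row.names = NULL)
  }))
  species_table <- data.frame(species = c("spA", "spB"),
                              family = c("famA", "famB"),
                              functional_group = "herbivore",
                              lmax_cm = c(30, 45), stringsAsFactors = FALSE)
  seagrass_survey(fish, cover, design, species_table = species_table)
}

# small fast generator configuration for simulation-heavy tests
small_config <- function(...) {
  generator_config(n_species = 8L, n_families = 4L, ...)
}

# hand-built site-level mean density table (for synchrony tests)
make_site_table <- function(values, site, management, season) {
  structure(list(values = values,
                 samples = data.frame(site = site, management = management,
                                      season = season,
                                      sample = paste(site, season, sep = "."),
                                      stringsAsFactors = FALSE),
                 species = colnames(values), level = "site",
                 aggregation = "mean", age_class = "all"),
            class = "density_table")
}

# brute-force Bray-Curtis between two abundance vectors
bc_pair <- function(x, y) {
  denom <- sum(x + y)
  if (denom == 0) return(0)
  sum(abs(x - y)) / denom
}
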