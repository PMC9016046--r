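# in-code fixtures shared across test files

toy_species <- function() {
  data.frame(species_code = c("AA", "BB", "CC"),
             conifer = c(TRUE, FALSE, TRUE),
             seral_class = c("late", "early", "rare"),
             stringsAsFactors = FALSE)
}

toy_plots <- function(n = 2) {
  data.frame(plot_id = sprintf("p%02d", seq_len(n)),
             x_m = (seq_len(n) - 1) * 200, y_m = 0,
             elevation_m = 1000 + 100 * seq_len(n),
             aspect_class = "N", zone = "strict",
             sand_pct = 45, clay_pct = 20, soil_depth_cm = 30,
             soil_type = "rendzina", pnv_dominants = "AA",
             disturbed_p1 = FALSE, disturbed_p2 = FALSE,
             stringsAsFactors = FALSE)
}

toy_trees <- function() {
  data.frame(plot_id = c("p01", "p01", "p02"),
             census_id = c(1984, 1984, 1984),
             species_code = c("AA", "BB", "AA"),
             dbh_cm = c(20, 30, 15),
             age_years = c(60, 80, 40),
             expansion_factor = 20,
             stringsAsFactors = FALSE)
}

toy_dataset <- function(trees = toy_trees(), plots = toy_plots(),
                        species = toy_species(),
                        census_years = c(1984, 1996)) {
  inventory_dataset(trees, plots, species, census_years)
}

# random tree table for property tests: n trees on one plot-census
random_trees <- function(n, species = toy_species()) {
  data.frame(plot_id = "p01", census_id = 1984,
             species_code = sample(species$species_code, n, replace = TRUE),
             dbh_cm = runif(n, 6, 80),
             age_years = sample(10:200, n, replace = TRUE),
             expansion_factor = runif(n, 5, 40),
             stringsAsFactors = FALSE)
}

# indicator table built directly from per-plot values, for change tests
manual_indicator_table <- function(values_by_census) {
  # values_by_census: list census_id -> named list/vector per indicator,
  # recycled across plots; plots inferred from the first element
  rows <- list()
  for (cid in names(values_by_census)) {
    v <- values_by_census[[cid]]
    df <- data.frame(plot_id = v$plot_id, census_id = as.numeric(cid))
    for (nm in indicator_names()) df[[nm]] <- v[[nm]]
    rows[[cid]] <- df
  }
  do.call(rbind, rows)
}
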