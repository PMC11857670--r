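# Fixtures are built in code at test time; nothing binary ships with the
# package. Sizes here are deliberately small for the unit tests; the
# acceptance suite builds the full-size recovery landscape itself.

# a small stack of independent smoothed fields (all continuous)
small_stack <- function(side = 30, n_layers = 3, seed = 1, corr_length = 3) {
  g <- grid_spec(side, side, 30)
  specs <- lapply(seq_len(n_layers), function(i)
    list(name = paste0("l", i), generator = "gaussian_field",
         corr_length = corr_length))
  generate_landscape(landscape_spec(g, specs, seed = seed))
}

# a compact landscape + concentrated virtual species with dominant layer
# "dem"; strong enough that all three learners discriminate well
small_species_fixture <- function(side = 50, n_presence = 120, seed = 3) {
  g <- grid_spec(side, side, 30)
  spec <- landscape_spec(g, list(
    list(name = "dem", generator = "gaussian_field", corr_length = 5),
    list(name = "evi", generator = "gaussian_field", corr_length = 4),
    list(name = "noise1", generator = "gaussian_field", corr_length = 3)
  ), seed = seed)
  st <- generate_landscape(spec)
  vs <- virtual_species(
    list(dem = list(type = "gaussian", center = 1.2, width = 0.5, weight = 9),
         evi = list(type = "linear", weight = 0.8)),
    intercept = -5)
  occ <- add_pseudo_absences(
    sample_virtual_occurrences(vs, st, n_presence, seed = seed + 1),
    st, seed = seed + 2)
  list(stack = st, vs = vs, occ = occ)
}

# the full-size recovery landscape used by the acceptance criteria:
# 200 x 200 grid, four autocorrelated layers, virtual species with one
# dominant layer (dem, narrow unimodal niche) and a weak secondary (evi)
recovery_landscape <- function() {
  g <- grid_spec(200, 200, 30)
  generate_landscape(landscape_spec(g, list(
    list(name = "dem", generator = "gaussian_field", corr_length = 8),
    list(name = "evi", generator = "gaussian_field", corr_length = 6),
    list(name = "bio14", generator = "gaussian_field", corr_length = 6),
    list(name = "road", generator = "gaussian_field", corr_length = 5)
  ), seed = 11))
}

recovery_species <- function() {
  virtual_species(
    list(dem = list(type = "gaussian", center = 1.2, width = 0.5, weight = 9),
         evi = list(type = "linear", weight = 0.8)),
    intercept = -5)
}

# seven-species categorical statuses (the published species set; blanks in
# the source table mean non-protected / NE / not-listed)
seven_species_status <- function() {
  data.frame(
    species = c("Macaca mulatta", "Muntiacus nigripes", "Sus scrofa",
                "Paradoxurus hermaphroditus", "Melogale moschata",
                "Atherurus macrourus", "Dremomys pyrrhomerus"),
    national_level = c("II", "II", "", "II", "", "", ""),
    redlist = c("LC", "VU", "LC", "EN", "NT", "LC", "NT"),
    cites = c("II", "", "", "III", "", "", ""),
    stringsAsFactors = FALSE)
}

# stack whose cells hold prescribed per-layer vectors (for exact screening
# arithmetic); vectors are laid out row-major on a 1 x n grid
vector_stack <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  g <- grid_spec(1, n, 1)
  env_stack(lapply(names(cols), function(nm)
    env_layer(nm, matrix(cols[[nm]], 1, n), g, "continuous")))
}
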