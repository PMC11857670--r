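## Conservation-value scoring and the weighted multi-species suitability
## overlay. Each species is scored on three ordinal scales — national
## protection level, Red List status, CITES appendix — the three scores are
## averaged into a conservation value I, and the per-species overlay weight
## is I normalised over the species set.

# the three scoring scales
.GRADE_SCORES <- c(I = 1, II = 0.5, III = 0.3, "non-protected" = 0.1)
.REDLIST_SCORES <- c(CR = 1, EN = 0.8, VU = 0.6, NT = 0.4, LC = 0.2, NE = 0.1)
.CITES_SCORES <- c(I = 1, II = 0.6, III = 0.3, "not-listed" = 0.1)

#' Score a species' conservation status on the three scales
#'
#' @param national_level `"I"`, `"II"`, `"III"` or `"non-protected"`.
#' @param redlist `"CR"`, `"EN"`, `"VU"`, `"NT"`, `"LC"` or `"NE"`.
#' @param cites `"I"`, `"II"`, `"III"` or `"not-listed"`.
#' @return named numeric vector `(I_grade, I_endangered, I_CITES)`.
#' @export
score_status <- function(national_level, redlist, cites) {
  lookup <- function(tab, key, what) {
    if (!key %in% names(tab))
      stop(sprintf("unknown %s category '%s' (expected one of %s)",
                   what, key, paste(names(tab), collapse = ", ")))
    unname(tab[key])
  }
  c(I_grade = lookup(.GRADE_SCORES, national_level, "national protection"),
    I_endangered = lookup(.REDLIST_SCORES, redlist, "Red List"),
    I_CITES = lookup(.CITES_SCORES, cites, "CITES"))
}

#' Conservation value: mean of the three component scores
#'
#' @param components numeric vector of the three scores from [score_status()].
#' @return the conservation value I in \[0.1, 1\].
#' @export
conservation_value <- function(components) {
  stopifnot(length(components) == 3, all(is.finite(components)))
  mean(components)
}

#' Normalised overlay weights from conservation values
#'
#' `P_i = I_i / sum_j I_j` over the species set; the weights sum to 1.
#' Internal arithmetic is unrounded; use `round_weights()` for the 3-decimal
#' half-up presentation convention.
#'
#' @param values positive numeric vector of conservation values (named by
#'   species if available).
#' @return numeric vector of weights summing to 1.
#' @export
species_weights <- function(values) {
  values <- unlist(values)
  if (length(values) < 1 || any(!is.finite(values)) || any(values <= 0))
    stop("conservation values must be positive")
  values / sum(values)
}

#' Report-time rounding of weights (3 decimals, half-up)
#' @param w numeric weights.
#' @param digits decimals (default 3).
#' @return rounded weights.
#' @export
round_weights <- function(w, digits = 3) round_half_up(w, digits)

#' Conservation scores and weights for a species status table
#'
#' @param status data frame with columns `species`, `national_level`,
#'   `redlist`, `cites` (or a CSV path to one). Blank/NA entries mean
#'   non-protected / NE / not-listed respectively.
#' @return data frame with the three component scores, the conservation
#'   value `I`, and the normalised weight `weight` per species.
#' @export
conservation_table <- function(status) {
  if (is.character(status)) status <- utils::read.csv(status, stringsAsFactors = FALSE)
  need <- c("species", "national_level", "redlist", "cites")
  if (!all(need %in% names(status)))
    stop("status table must have columns ", paste(need, collapse = ","))
  blank_to <- function(x, def) ifelse(is.na(x) | !nzchar(trimws(x)), def, trimws(x))
  status$national_level <- blank_to(status$national_level, "non-protected")
  status$redlist <- blank_to(status$redlist, "NE")
  status$cites <- blank_to(status$cites, "not-listed")
  comp <- t(mapply(score_status, status$national_level, status$redlist, status$cites))
  I <- apply(comp, 1, conservation_value)
  data.frame(species = status$species,
             I_grade = comp[, "I_grade"], I_endangered = comp[, "I_endangered"],
             I_CITES = comp[, "I_CITES"], I = I,
             weight = species_weights(I), row.names = NULL)
}

#' Weighted multi-species suitability overlay
#'
#' Per-cell weighted sum of aligned single-species suitability maps; a cell
#' is valid only where every map has data (undefined suitability cannot
#' contribute). With weights from [species_weights()] the output stays in
#' \[0, 1\] and is bounded per-cell by the input maps.
#'
#' @param maps list of suitability [env_layer()] objects on one grid.
#' @param weights numeric weights (same length, summing to 1).
#' @return an [env_layer()] named `"multispecies_suitability"`.
#' @export
stack_multispecies <- function(maps, weights) {
  stopifnot(length(maps) == length(weights), length(maps) >= 1)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  grid <- maps[[1]]$grid
  for (m in maps[-1])
    if (!grids_aligned(m$grid, grid)) stop("suitability maps are misaligned")
  vals <- Reduce(`+`, Map(function(m, w) {
    v <- m$values
    v[is.na(v)] <- NA          # NA propagates through the sum
    w * v
  }, maps, weights))
  env_layer("multispecies_suitability", vals, grid, "continuous")
}
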