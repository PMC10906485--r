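# --- fixed vocabularies ------------------------------------------------

habitat_strata <- list(
  complex = c("understory", "mid_high"),
  open    = c("aerial", "open_water"),
  horizon = c("ground", "water_surface", "canopy")
)

light_keyword_table <- list(
  low = c("forest_understory", "mangrove", "dense_shrubland", "heathland",
          "dense_habitat"),
  high = c("desert", "grassland", "savannah", "farmland", "steppe", "meadow",
           "pelagic_ocean", "open_antarctic_island", "flat_beach", "dune",
           "mudflat"),
  medium = c("forest_edge", "secondary_forest", "scrub_forest", "semi_open")
)

far_maneuvers <- c("aerial_chase", "pursuit_diving", "scavenging", "sallying")
near_maneuvers <- c("gleaning", "pecking", "dabbling", "kicking_scratching",
                    "probing")

#' Default mapping from raw EltonTraits diet categories to analysis
#' categories
#'
#' The ten raw diet-score categories are aggregated into the three analysis
#' categories (plants, invertebrates, vertebrates including scavenged prey),
#' and separately into mobile vs immobile prey (scavenged prey counts as
#' immobile). The mapping is a plain list so it can be edited and passed to
#' [aggregate_diet()] and [classify_prey_mobility()].
#'
#' @format list with elements `plants`, `invertebrates`,
#'   `vertebrates_scavenged`, `vertebrates_live`, `scavenged`.
#' @export
elton_diet_map <- list(
  plants = c("fruit", "nect", "seed", "planto"),
  invertebrates = c("inv"),
  vertebrates_scavenged = c("vend", "vect", "vfish", "vunk", "scav"),
  vertebrates_live = c("vend", "vect", "vfish", "vunk"),
  scavenged = c("scav")
)

normalize_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ /'-]+", "_", x)
  gsub("_+", "_", x)
}

# --- unit conversion and record selection ------------------------------

#' Convert an acuity value to cycles per degree
#'
#' Acuity is expressed throughout in cycles per degree (cpd): the number of
#' black/white grating pairs resolvable per degree of visual angle. One
#' grating cycle spans two minimum angles of resolution (MAR), so with MAR
#' in arcminutes cpd = 60 / (2 * MAR) = 30 / MAR, and with MAR in degrees
#' cpd = 0.5 / MAR. Cycles per radian convert by the 180/pi degrees per
#' radian.
#'
#' @param value positive acuity value(s).
#' @param unit one of `"cpd"`, `"mar_arcmin"`, `"mar_deg"`,
#'   `"cycles_per_radian"`.
#' @return acuity in cycles per degree.
#' @export
to_cpd <- function(value, unit = c("cpd", "mar_arcmin", "mar_deg",
                                   "cycles_per_radian")) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("acuity values must be positive")
  }
  unit <- match.arg(unit)
  switch(unit,
         cpd = value,
         mar_arcmin = 30 / value,
         mar_deg = 0.5 / value,
         cycles_per_radian = value * pi / 180)
}

#' Select one acuity record per species
#'
#' Applies the database record-selection rules: anatomical (RGC-density)
#' estimates are preferred over behavioral ones when both exist; among
#' records of the preferred method the most recent source year wins; ties
#' are broken by the highest reported acuity.
#'
#' @param candidates data.frame of candidate records for one species, with
#'   columns `species`, `method` (`"RGC"` or `"behavioral"`),
#'   `source_year`, `acuity_cpd`.
#' @return the single selected row.
#' @export
select_record <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0L) stop("no candidate records")
  if (length(unique(normalize_label(candidates$species))) > 1L) {
    stop("candidate records span multiple species")
  }
  if (nrow(candidates) == 1L) return(candidates)
  pool <- if (any(candidates$method == "RGC")) {
    candidates[candidates$method == "RGC", , drop = FALSE]
  } else {
    candidates
  }
  pool <- pool[pool$source_year == max(pool$source_year), , drop = FALSE]
  pool[which.max(pool$acuity_cpd), , drop = FALSE]
}

# --- classifiers -------------------------------------------------------

#' Classify habitat spatial complexity
#'
#' Sums the foraging-stratum percentages into three broad habitat classes
#' -- spatially complex (understory + mid-high vegetation), open (aerial +
#' open water) and horizon-dominated (ground + water surface + canopy) --
#' and assigns the species to the first class whose sum strictly exceeds
#' the threshold (70% by default; at most one class can exceed it when the
#' strata total <= 100). Species with no sum above the threshold are
#' habitat generalists.
#'
#' @param habitat_pct named numeric vector of percentages with names among
#'   `understory`, `mid_high`, `aerial`, `open_water`, `ground`,
#'   `water_surface`, `canopy` (missing strata count as 0).
#' @param threshold percentage threshold (default 70; strict inequality).
#' @return one of `"complex"`, `"open"`, `"horizon"`, `"generalist"`.
#' @export
classify_habitat <- function(habitat_pct, threshold = 70) {
  strata <- unlist(habitat_strata, use.names = FALSE)
  pct <- stats::setNames(rep(0, length(strata)), strata)
  nm <- normalize_token(names(habitat_pct))
  unknown <- setdiff(nm, strata)
  if (length(unknown)) {
    stop("unknown habitat strata: ", paste(unknown, collapse = ", "))
  }
  pct[nm] <- as.numeric(habitat_pct)
  if (any(pct < 0) || any(pct > 100)) stop("percentages must lie in [0, 100]")
  if (sum(pct) > 100 + 1e-6) {
    stop(sprintf("habitat strata sum to %.2f%% (> 100%%)", sum(pct)))
  }
  sums <- vapply(habitat_strata, function(s) sum(pct[s]), numeric(1))
  hit <- which(sums > threshold)
  if (length(hit)) names(sums)[hit[1L]] else "generalist"
}

#' Classify habitat light level
#'
#' Nocturnal species (and ecological equivalents such as deep-diving
#' foragers flagged nocturnal upstream) are classified as low-light
#' regardless of habitat. Otherwise habitat descriptor keywords are matched
#' against fixed low/medium/high keyword tables and the majority class over
#' the matched keywords wins, with ties resolved to medium. Species with no
#' matching keyword fail loudly rather than defaulting, since light
#' assignment is otherwise a manual call.
#'
#' @param habitat_keywords character vector of habitat descriptors
#'   (case/space/hyphen-insensitive).
#' @param nocturnal logical flag.
#' @return one of `"low"`, `"medium"`, `"high"`.
#' @export
classify_light <- function(habitat_keywords, nocturnal = FALSE) {
  if (isTRUE(nocturnal)) return("low")
  kw <- normalize_token(habitat_keywords)
  votes <- c(low = 0L, medium = 0L, high = 0L)
  for (class in names(light_keyword_table)) {
    votes[class] <- sum(kw %in% light_keyword_table[[class]])
  }
  if (sum(votes) == 0L) {
    stop("unclassified light level: no keyword matched (",
         paste(habitat_keywords, collapse = ", "), ") and not nocturnal")
  }
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) "medium" else top
}

#' Aggregate raw diet scores into the three analysis categories
#'
#' @param raw_scores named numeric vector of raw diet-category percentage
#'   scores (EltonTraits-style names, case-insensitive).
#' @param map aggregation mapping, default [elton_diet_map].
#' @return named numeric vector with elements `plants`, `invertebrates`,
#'   `vertebrates_scavenged`.
#' @export
aggregate_diet <- function(raw_scores, map = elton_diet_map) {
  nm <- normalize_token(names(raw_scores))
  x <- stats::setNames(as.numeric(raw_scores), nm)
  if (any(x < 0)) stop("diet scores must be non-negative")
  vapply(c("plants", "invertebrates", "vertebrates_scavenged"),
         function(cat) sum(x[intersect(map[[cat]], nm)]), numeric(1))
}

#' Classify dominant diet
#'
#' The analysis category (plants, invertebrates, or vertebrates including
#' scavenged prey) scoring at least 50% of the diet wins; species with no
#' category reaching 50%, or with a 50/50 tie, are omnivores.
#'
#' @param diet_pct named numeric vector with elements `plants`,
#'   `invertebrates`, `vertebrates_scavenged` (percentages), or raw scores
#'   to be aggregated via [aggregate_diet()].
#' @param threshold dominance threshold (default 50; `>=`).
#' @return one of `"plants"`, `"invertebrates"`, `"vertebrates_scavenged"`,
#'   `"omnivore"`.
#' @export
classify_diet <- function(diet_pct, threshold = 50) {
  cats <- c("plants", "invertebrates", "vertebrates_scavenged")
  nm <- normalize_token(names(diet_pct))
  if (!all(nm %in% cats)) diet_pct <- aggregate_diet(diet_pct)
  else diet_pct <- stats::setNames(as.numeric(diet_pct), nm)[
    intersect(cats, nm)]
  if (any(diet_pct < 0)) stop("diet scores must be non-negative")
  winners <- names(diet_pct)[diet_pct >= threshold]
  if (length(winners) == 1L) winners else "omnivore"
}

#' Classify primary prey mobility
#'
#' Mobile prey are live vertebrates and invertebrates; immobile prey are
#' plant matter of all kinds plus scavenged prey. The species is classified
#' by which side holds the larger share of its raw diet scores; an exact
#' tie is an error flagged for a manual call.
#'
#' @param raw_scores named numeric vector of raw diet-category scores.
#' @param map aggregation mapping, default [elton_diet_map].
#' @return `"mobile"` or `"immobile"`.
#' @export
classify_prey_mobility <- function(raw_scores, map = elton_diet_map) {
  nm <- normalize_token(names(raw_scores))
  x <- stats::setNames(as.numeric(raw_scores), nm)
  if (any(x < 0)) stop("diet scores must be non-negative")
  if (sum(x) == 0) stop("all diet scores are zero")
  mobile <- sum(x[intersect(c(map$invertebrates, map$vertebrates_live), nm)])
  immobile <- sum(x[intersect(c(map$plants, map$scavenged), nm)])
  if (mobile == immobile) {
    stop("mobile and immobile prey scores tie exactly; manual call required")
  }
  if (mobile > immobile) "mobile" else "immobile"
}

#' Classify foraging mode (far- vs near-sighted maneuvers)
#'
#' Distance maneuvers (resolving prey from afar) are aerial chase, pursuit
#' diving, scavenging and sallying; close-up maneuvers are gleaning,
#' pecking, dabbling, kicking/scratching and probing. The species' primary
#' maneuver is taken to be the first listed; the mode is `"far"` if that
#' maneuver is a distance maneuver, else `"near"`.
#'
#' @param maneuvers character vector of maneuver tokens, primary first.
#' @return `"far"` or `"near"`.
#' @export
classify_foraging <- function(maneuvers) {
  if (length(maneuvers) == 0L) stop("no foraging maneuvers given")
  tok <- normalize_token(maneuvers)
  known <- c(far_maneuvers, near_maneuvers)
  unknown <- setdiff(tok, known)
  if (length(unknown)) {
    stop("unknown foraging maneuver token(s): ",
         paste(unknown, collapse = ", "))
  }
  if (tok[1L] %in% far_maneuvers) "far" else "near"
}

#' Build an ecology profile for one species
#'
#' Applies all five classifiers to one species' raw trait fields.
#'
#' @param habitat_pct see [classify_habitat()].
#' @param habitat_keywords,nocturnal see [classify_light()].
#' @param diet_raw raw diet scores; see [classify_diet()] and
#'   [classify_prey_mobility()].
#' @param maneuvers see [classify_foraging()].
#' @param habitat_threshold,diet_threshold rule thresholds (defaults 70, 50).
#' @return list with `habitat_class`, `light_class`, `diet_class`,
#'   `prey_mobility`, `foraging_mode`.
#' @export
ecology_profile <- function(habitat_pct, habitat_keywords, nocturnal,
                            diet_raw, maneuvers,
                            habitat_threshold = 70, diet_threshold = 50) {
  list(
    habitat_class = classify_habitat(habitat_pct, habitat_threshold),
    light_class = classify_light(habitat_keywords, nocturnal),
    diet_class = classify_diet(diet_raw, diet_threshold),
    prey_mobility = classify_prey_mobility(diet_raw),
    foraging_mode = classify_foraging(maneuvers)
  )
}
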