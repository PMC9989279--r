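#' Specification of a synthetic longitudinal cohort
#'
#' The generator emulates the statistical shape of an early-disease
#' observational cohort: a few hundred patients followed over up to five
#' annual visits, eight normalized clinical features in `[0, 1]`, a latent
#' archetype (disease-state cluster) per patient, per-medication-type annual
#' drift of the motor score, and geometric visit dropout thinning later
#' years.
#'
#' Default drifts are expressed in normalized score units (absolute points /
#' score range 80) and mirror the ordering reported for the eight regimens
#' (combination therapy with dopamine agonists slowest, "other" fastest);
#' they make sign- and order-recovery tests meaningful without claiming to
#' reproduce any gated-cohort value.
#'
#' @param n_patients number of patients (default 480).
#' @param n_years maximal number of annual visits (default 5).
#' @param n_archetypes latent disease-state clusters (default 9: a baseline
#'   state plus one single-axis-dominant phenotype per feature).
#' @param drift named numeric vector, `"0"`..`"7"` -> annual normalized
#'   score change.
#' @param noise_sd visit-level feature and increment noise SD (default 0.015
#'   normalized, i.e. ~1.2 absolute points on a range of 80).
#' @param between_sd patient-level SD around the archetype centre (default
#'   0.015): patients form a narrow severity spectrum within a phenotype
#'   rather than copies of its centre.
#' @param type_probs probability of each medication type 0--7.
#' @param retention per-year probability that a patient returns (default
#'   0.75, reproducing the decaying visit counts of real cohorts).
#' @param age_range years spanned by the normalized age axis (default 50,
#'   so one study year advances normalized age by 0.02).
#' @param seed RNG seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 480, n_years = 5, n_archetypes = 9,
                        drift = default_drift(), noise_sd = 0.015,
                        between_sd = 0.015,
                        type_probs = default_type_probs(), retention = 0.75,
                        age_range = 50, seed = 1L) {
  if (n_patients < 1) abort("n_patients must be >= 1",
                            "progmapper_config_error")
  if (noise_sd < 0) abort("noise_sd must be >= 0", "progmapper_config_error")
  type_probs <- type_probs / sum(type_probs)
  if (length(type_probs) != 8)
    abort("type_probs must have 8 entries", "progmapper_config_error")
  drift <- setNames(as.numeric(drift), as.character(0:7))
  structure(list(n_patients = as.integer(n_patients),
                 n_years = as.integer(n_years),
                 n_archetypes = as.integer(n_archetypes),
                 drift = drift, noise_sd = noise_sd, between_sd = between_sd,
                 type_probs = type_probs, retention = retention,
                 age_range = age_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default per-type annual drifts (normalized score units)
#'
#' Absolute-point growths of roughly 2.2, 2.2, 2.5, 3.4, 2.2, 0.3, 0.9 and
#' 1.9 per year on a score range of 80, i.e. ordering
#' type 5 < 6 < 7 < 0 = 1 = 4 < 2 < 3.
#'
#' @return named numeric vector `"0"`..`"7"`.
#' @export
default_drift <- function() {
  setNames(c(2.2, 2.2, 2.5, 3.4, 2.2, 0.3, 0.9, 1.9) / 80, as.character(0:7))
}

#' Default medication-type distribution
#'
#' Early-cohort-like mix: un-medicated most common, mono-therapies next,
#' triple combinations rare.
#'
#' @return probability vector of length 8.
#' @export
default_type_probs <- function() {
  c(0.30, 0.20, 0.12, 0.06, 0.08, 0.12, 0.06, 0.06)
}

synthetic_features <- c("age", "updrs3", "np1apat", "np1fatg", "np1anxs",
                        "moca", "scopa", "symptom")

# Archetype centres: a baseline disease state plus single-axis-dominant
# phenotypes (feature j elevated from 0.25 to 0.70) -- e.g. a motor-dominant,
# an apathy-dominant, a late-onset state.  With at most 9 archetypes every
# feature axis separates some phenotype pair, so each signal feature is
# topologically load-bearing; extra archetypes (>9) get random centres.
archetype_centres <- function(n_archetypes) {
  base <- rep(0.25, 8)
  rows <- list(base)
  for (j in seq_len(min(n_archetypes - 1L, 8L))) {
    v <- base; v[j] <- 0.70
    rows[[j + 1L]] <- v
  }
  extra <- n_archetypes - length(rows)
  if (extra > 0)
    for (k in seq_len(extra)) rows[[length(rows) + 1L]] <- runif(8, 0.15, 0.85)
  centres <- do.call(rbind, rows)
  colnames(centres) <- synthetic_features
  centres
}

#' Generate a synthetic longitudinal cohort
#'
#' Each patient draws a latent archetype (a Gaussian centre in the 8-D
#' normalized feature space) and a medication type; the baseline motor score
#' comes from the archetype, and every subsequent year adds the type's drift
#' plus noise while age advances by one year on the normalized axis.
#' Non-filter features re-jitter around the archetype centre, so visits
#' cluster by archetype.  Later visits are thinned geometrically.  All
#' values are clipped to `[0, 1]` (with a warning when drift actually pushes
#' scores out of range); output is deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return A normalized [visit_table()] with features
#'   `age, updrs3, np1apat, np1fatg, np1anxs, moca, scopa, symptom`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    centres <- archetype_centres(spec$n_archetypes)
    rows <- vector("list", spec$n_patients)
    clipped <- FALSE
    for (pt in seq_len(spec$n_patients)) {
      arch <- sample.int(spec$n_archetypes, 1)
      med <- sample(0:7, 1, prob = spec$type_probs)
      n_vis <- 1L
      while (n_vis < spec$n_years && runif(1) < spec$retention)
        n_vis <- n_vis + 1L
      # the patient is a Gaussian draw around the archetype centre: a
      # narrow severity spectrum, not a copy of the centre.  Baseline age
      # follows the archetype too (phenotypes correlate with onset age).
      centre_pt <- centres[arch, ] + rnorm(8, 0, spec$between_sd)
      age0 <- centre_pt[["age"]]
      updrs0 <- centre_pt[["updrs3"]] + rnorm(1, 0, spec$noise_sd)
      updrs <- updrs0 + c(0, cumsum(spec$drift[[as.character(med)]] +
                                      rnorm(n_vis - 1, 0, spec$noise_sd)))
      if (any(updrs < 0 | updrs > 1)) clipped <- TRUE
      other <- matrix(rep(centre_pt[c("np1apat", "np1fatg", "np1anxs",
                                      "moca", "scopa", "symptom")],
                          each = n_vis),
                      nrow = n_vis) +
        matrix(rnorm(n_vis * 6, 0, spec$noise_sd), nrow = n_vis)
      df <- data.frame(
        patient_id = sprintf("P%04d", pt),
        year = seq_len(n_vis) - 1L,
        med_type = med,
        age = pmin(pmax(age0 + (seq_len(n_vis) - 1L) / spec$age_range, 0), 1),
        updrs3 = pmin(pmax(updrs, 0), 1))
      colnames(other) <- c("np1apat", "np1fatg", "np1anxs", "moca", "scopa",
                           "symptom")
      rows[[pt]] <- cbind(df, pmin(pmax(other, 0), 1))
    }
    if (clipped)
      warning("drift pushed some scores outside [0, 1]; values were clipped")
    visit_table(do.call(rbind, rows), synthetic_features, normalized = TRUE)
  })
}

#' Append a pure-noise feature to a visit table
#'
#' Adds one i.i.d. uniform `[0, 1]` feature, independent of everything else;
#' the canonical negative control for the feature-elimination procedure.
#'
#' @param table a [visit_table()].
#' @param seed RNG seed.
#' @param name name of the new feature.
#' @return the widened [visit_table()].
#' @export
generate_noise_feature <- function(table, seed = 1L, name = "noise") {
  stopifnot(inherits(table, "visit_table"))
  if (nrow(table$data) == 0) abort("table is empty", "progmapper_config_error")
  if (name %in% names(table$data))
    abort(sprintf("feature '%s' already exists", name),
          "progmapper_config_error")
  df <- table$data
  df[[name]] <- with_seed(seed, runif(nrow(df)))
  visit_table(df, c(table$feature_names, name), normalized = table$normalized)
}

#' Serialize a cohort spec as JSON
#'
#' @param spec a [cohort_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  doc <- unclass(spec)
  doc$drift <- as.list(doc$drift)  # keep type labels through JSON
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
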