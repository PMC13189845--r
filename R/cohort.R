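#' Configuration for synthetic multi-site cohorts
#'
#' Defines the tissue-signature pool and composition rules used by
#' [make_cohort()]. Positive (malignant) lesions always contain the
#' "malignant triad" signature (high T1, high T2, low ADC) at a volume
#' fraction of at least `triad_fraction_range[1]`; negative (benign) lesions
#' are composed of degenerative signatures: a low-ADC-without-high-T1
#' hyaline class and/or a high-T2 cystic class, plus viable stroma.
#'
#' @param sd Within-habitat noise SD shared by all signatures.
#' @param site_shifts Named list of per-site additive channel shifts
#'   `c(t1, t2, adc)`, modelling scanner/site effects.
#' @param triad_fraction_range Range of the triad volume fraction in
#'   positive lesions (min >= 0.3).
#' @param triad_fraction_negative Probability that a negative lesion carries
#'   a triad subregion (default 0).
#' @param hyaline_fraction_range Range of the hyaline volume fraction in
#'   negative multi-region lesions.
#' @param cystic_prob Probability that a lesion carries a cystic subregion.
#' @param hemorrhage_prob Probability that a lesion instead carries a
#'   hemorrhagic focus (high T1 without restricted diffusion — the benign
#'   "red degeneration" mimic that confounds whole-lesion intensity
#'   features). At most one of the two degenerative extras is present, so
#'   lesions have 1-3 subregions.
#' @param cystic_fraction_range Range of the cystic/hemorrhagic volume
#'   fraction.
#' @param neg_single_region_prob Probability that a negative lesion is a
#'   single homogeneous stromal region.
#' @param signature_jitter Per-channel SD `c(t1, t2, adc)` of the
#'   between-patient variation of signature means. This is what makes the
#'   classes overlap: each patient's tissue deviates from the class
#'   prototype, as real lesions do, so no model attains a perfect AUC.
#' @param lesion_radius_range_mm Range of lesion radii (sampled uniformly).
#' @param grid_shape,spacing_mm Grid for every phantom.
#' @param bias_amplitude Bias-field magnitude for every phantom.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(sd = 0.15,
                          site_shifts = list(
                            site_A = c(0, 0, 0),
                            site_B = c(0.10, -0.05, 0.03),
                            site_C = c(0.25, 0.15, 0.08)
                          ),
                          triad_fraction_range = c(0.3, 0.5),
                          triad_fraction_negative = 0,
                          hyaline_fraction_range = c(0.25, 0.45),
                          cystic_prob = 0.45,
                          hemorrhage_prob = 0.45,
                          cystic_fraction_range = c(0.15, 0.35),
                          neg_single_region_prob = 0.15,
                          signature_jitter = c(0.30, 0.30, 0.09),
                          lesion_radius_range_mm = c(7, 9),
                          grid_shape = c(32L, 32L, 32L),
                          spacing_mm = c(1, 1, 1),
                          bias_amplitude = 0.1) {
  stopifnot(triad_fraction_range[1] >= 0.3)
  # "hyaline" here is the benign low-ADC mimic: hypercellular/degenerate
  # leiomyoma tissue with restricted diffusion but without the triad's
  # T1/T2 hyperintensity
  pool <- list(
    stroma     = habitat_signature("stroma",     1.6, 1.2, 1.35, sd = sd),
    cystic     = habitat_signature("cystic",     0.9, 2.9, 1.60, sd = sd),
    hyaline    = habitat_signature("hyaline",    2.1, 2.0, 0.90, sd = sd),
    hemorrhage = habitat_signature("hemorrhage", 3.0, 1.3, 1.30, sd = sd),
    triad      = habitat_signature("triad",      2.7, 2.6, 0.82, sd = sd)
  )
  structure(
    list(signature_pool = pool, site_shifts = site_shifts,
         triad_fraction_range = triad_fraction_range,
         triad_fraction_negative = triad_fraction_negative,
         hyaline_fraction_range = hyaline_fraction_range,
         cystic_prob = cystic_prob,
         hemorrhage_prob = hemorrhage_prob,
         cystic_fraction_range = cystic_fraction_range,
         neg_single_region_prob = neg_single_region_prob,
         signature_jitter = signature_jitter,
         lesion_radius_range_mm = lesion_radius_range_mm,
         grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
         bias_amplitude = bias_amplitude),
    class = "cohort_config"
  )
}

# Sample one lesion composition (signatures + fractions) for a class.
# Every lesion has 1-3 contiguous subregions: a class-defining component
# (triad for malignant, hyaline for most benign), optionally ONE extra
# degenerative component (cystic or hemorrhagic), and viable stroma.
sample_composition <- function(config, positive) {
  pool <- config$signature_pool
  runif1 <- function(r) runif(1, r[1], r[2])
  extra <- {
    u <- runif(1)
    if (u < config$cystic_prob) "cystic"
    else if (u < config$cystic_prob + config$hemorrhage_prob) "hemorrhage"
    else NULL
  }
  if (positive) {
    sigs <- list(pool$triad)
    fr <- runif1(config$triad_fraction_range)
  } else {
    if (runif(1) < config$neg_single_region_prob) {
      return(list(signatures = list(pool$stroma), fractions = 1))
    }
    has_triad <- runif(1) < config$triad_fraction_negative
    if (has_triad) { # rare mimic: triad tissue in a benign lesion
      sigs <- list(pool$hyaline, pool$triad)
      fr <- c(runif(1, 0.2, 0.3), runif(1, 0.2, 0.25))
      extra <- NULL # keep at most 3 subregions
    } else {
      sigs <- list(pool$hyaline)
      fr <- runif1(config$hyaline_fraction_range)
    }
  }
  if (!is.null(extra)) {
    sigs <- c(sigs, list(pool[[extra]]))
    fr <- c(fr, runif1(config$cystic_fraction_range))
  }
  sigs <- c(sigs, list(pool$stroma))
  fr <- c(fr, 1 - sum(fr))
  list(signatures = sigs, fractions = fr)
}

#' Generate a multi-site synthetic cohort
#'
#' Simulates a cohort of lesion phantoms across sites, with a forced number
#' of positive (malignant) cases per site of `round(positive_fraction * n)`.
#' Each site applies its configured channel shift; lesion size and
#' composition vary per patient under the rules in [cohort_config()].
#'
#' @param n_per_site Named integer vector of patients per site; names must
#'   be sites present in `config$site_shifts`.
#' @param positive_fraction Fraction of positive cases per site, in (0, 1).
#' @param config A [cohort_config()].
#' @param seed Integer seed; the cohort is a pure function of it.
#' @return List with `manifest` (tibble: patient_id, site, label) and
#'   `phantoms` (named list of [make_phantom()] outputs).
#' @examples
#' coh <- make_cohort(c(site_A = 2, site_B = 2, site_C = 2), seed = 1)
#' coh$manifest
#' @export
make_cohort <- function(n_per_site = c(site_A = 12, site_B = 12, site_C = 16),
                        positive_fraction = 0.45,
                        config = cohort_config(),
                        seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop("positive_fraction must be in (0, 1)")
  }
  if (is.null(names(n_per_site))) {
    names(n_per_site) <- names(config$site_shifts)[seq_along(n_per_site)]
  }
  if (any(n_per_site < 1)) stop("need at least one patient per site")
  if (!all(names(n_per_site) %in% names(config$site_shifts))) {
    stop("every site needs a shift in config$site_shifts")
  }

  with_seed(seed, {
    rows <- list(); phantoms <- list(); pid <- 0L
    for (site in names(n_per_site)) {
      n <- n_per_site[[site]]
      n_pos <- round(positive_fraction * n)
      is_pos <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
      for (p in seq_len(n)) {
        pid <- pid + 1L
        id <- sprintf("P%03d", pid)
        comp <- sample_composition(config, is_pos[p])
        # between-patient biological variability around the class prototypes
        jit <- config$signature_jitter
        comp$signatures <- lapply(comp$signatures, function(s) {
          habitat_signature(s$name,
                            s$mean_t1 + rnorm(1, 0, jit[1]),
                            s$mean_t2 + rnorm(1, 0, jit[2]),
                            s$mean_adc + rnorm(1, 0, jit[3]),
                            sd = s$sd)
        })
        radius <- runif(1, config$lesion_radius_range_mm[1],
                        config$lesion_radius_range_mm[2])
        spec <- phantom_spec(
          grid_shape = config$grid_shape, spacing_mm = config$spacing_mm,
          lesion_radius_mm = radius,
          signatures = comp$signatures, volume_fractions = comp$fractions,
          class_label = if (is_pos[p]) "positive" else "negative",
          site_id = site, site_shift = config$site_shifts[[site]],
          bias_amplitude = config$bias_amplitude,
          seed = sample.int(2147483646L, 1)
        )
        phantoms[[id]] <- c(make_phantom(spec), list(spec = spec))
        rows[[id]] <- tibble::tibble(
          patient_id = id, site = site,
          label = if (is_pos[p]) "positive" else "negative"
        )
      }
    }
    list(manifest = dplyr::bind_rows(rows), phantoms = phantoms)
  })
}
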