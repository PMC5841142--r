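# Multi-subject, multi-visit synthetic cohorts. Hemizygote splenium
# heterogeneity follows an age profile peaking in the 5-10 year band
# (gaussian bump over a baseline), controls are flat in age; all other
# regions take their group defaults.

#' Cohort specification
#'
#' @param n_subjects_per_group subjects per group.
#' @param groups subset of `control`, `hemizygote`, `CALD`,
#'   `self-arrested`.
#' @param visits_per_subject number of visits; visit ages are spread over
#'   the follow-up window.
#' @param age_range age range (years) for the first visit.
#' @param followup_years window over which repeat visits are spread.
#' @param phantom one of `"wm"` (single white-matter compartment plus
#'   thalamus, used for whole-WM group comparisons) or `"regional"` (the
#'   nine-region survey plus thalamus).
#' @param block region block size passed to [block_labels()].
#' @param noise_sigma,snr noise specification as in [phantom_spec()].
#' @param zone_params lesion-zone parameters used for CALD /
#'   self-arrested subjects.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_group = 10,
                        groups = c("control", "hemizygote"),
                        visits_per_subject = 1,
                        age_range = c(4, 16), followup_years = 10,
                        phantom = c("wm", "regional"),
                        block = c(4, 3, 2), noise_sigma = 0, snr = NULL,
                        zone_params = default_zone_params()) {
  allowed <- c("control", "hemizygote", "CALD", "self-arrested")
  if (length(groups) == 0) stopf("groups must be non-empty")
  bad <- setdiff(groups, allowed)
  if (length(bad) > 0) stopf("unknown groups: %s", paste(bad, collapse = ", "))
  if (n_subjects_per_group < 1) stopf("n_subjects_per_group must be >= 1")
  if (visits_per_subject < 1) stopf("visits_per_subject must be >= 1")
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 groups = groups,
                 visits_per_subject = as.integer(visits_per_subject),
                 age_range = age_range, followup_years = followup_years,
                 phantom = match.arg(phantom), block = block,
                 noise_sigma = noise_sigma, snr = snr,
                 zone_params = zone_params),
            class = "cohort_spec")
}

#' Age profile of hemizygote splenium transit-time heterogeneity
#'
#' Gaussian bump over a baseline, peaking at 7 years: elevated
#' heterogeneity during the developmental window of highest conversion
#' risk, declining towards adulthood. Controls are flat at their group
#' default.
#'
#' @param age age in years (vectorised).
#' @param group subject group.
#' @param base,amp,centre,width profile parameters (seconds / years).
#' @return Splenium CTH in seconds.
#' @export
splenium_age_profile <- function(age, group = "hemizygote", base = 1.3,
                                 amp = 2.9, centre = 7, width = 5) {
  if (group != "hemizygote") return(rep(2.43, length(age)))
  base + amp * exp(-((age - centre) / width)^2)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws subject ages, builds one phantom per subject-visit, and returns
#' the phantoms together with a tidy ground-truth record table (one row
#' per subject, visit, region and map). Deterministic given
#' `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param acq an [acquisition_params()].
#' @param aif an [aif_model()].
#' @param seed RNG seed.
#' @param simulate_signal generate the 4D signal series (set `FALSE` for
#'   ground-truth-only studies, which is much faster).
#' @return An object of class `dsc_cohort`: list with `subjects` (each
#'   holding id, group, ages and per-visit phantoms) and `truth_records`
#'   (data frame: subject_id, age, group, visit, region, map, value).
#' @export
make_cohort <- function(spec = cohort_spec(), acq = acquisition_params(),
                        aif = aif_model(), seed = 1,
                        simulate_signal = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- list()
  records <- list()
  sid <- 0L
  with_seed(seed, {
    for (grp in spec$groups) {
      for (i in seq_len(spec$n_subjects_per_group)) {
        sid <- sid + 1L
        id <- sprintf("S%03d", sid)
        age0 <- stats::runif(1, spec$age_range[1], spec$age_range[2])
        ages <- if (spec$visits_per_subject == 1) age0 else
          age0 + seq(0, spec$followup_years, length.out = spec$visits_per_subject)
        visits <- list()
        for (v in seq_len(spec$visits_per_subject)) {
          pseed <- sample.int(.Machine$integer.max, 1)
          ph <- subject_phantom(spec, grp, ages[v], acq, aif, pseed,
                                simulate_signal)
          visits[[v]] <- ph
          rec <- truth_region_records(ph, id, ages[v], grp, v)
          records[[length(records) + 1L]] <- rec
        }
        subjects[[id]] <- list(id = id, group = grp, ages = ages,
                               visits = visits)
      }
    }
  })
  structure(list(subjects = subjects,
                 truth_records = do.call(rbind, records),
                 spec = spec),
            class = "dsc_cohort")
}

# One subject-visit phantom. Hemizygote regional phantoms get their
# splenium CTH (and MTT at fixed RTH) from the age profile.
subject_phantom <- function(spec, group, age, acq, aif, seed, simulate_signal) {
  grp_param <- if (group %in% c("control")) "control" else "hemizygote"
  if (spec$phantom == "wm") {
    params <- default_wm_params(grp_param)
    labels <- block_labels(2, block = spec$block, ncol = 2)
  } else {
    params <- default_region_params(grp_param)
    if (group == "hemizygote") {
      cth_age <- splenium_age_profile(age, group)
      spl <- params[["1"]]
      rth <- spl$cth / spl$mtt
      params[["1"]] <- region_params(cbf = spl$cbf, mtt = cth_age / rth,
                                     cth = cth_age, k_app = spl$k_app,
                                     cbf_sd = spl$cbf_sd,
                                     mtt_sd = 0.08 * cth_age / rth,
                                     cth_sd = spl$cth_sd,
                                     k_app_sd = spl$k_app_sd)
      attr(params, "region_names") <- stats::setNames(c(REGION_ORDER, "THA"),
                                                      as.character(1:10))
    }
    labels <- block_labels(10, block = spec$block, ncol = 4)
  }
  if (group %in% c("CALD", "self-arrested")) {
    zp <- spec$zone_params
    if (group == "self-arrested") {
      # non-progressing cases: perilesional tissue near-normal
      zp$D_conv <- zp$D_non
      zp$C_enh <- zp$C_non
    }
    return(make_lesion_phantom(zp, acq = acq, aif = aif, seed = seed,
                               noise_sigma = spec$noise_sigma, snr = spec$snr))
  }
  if (!simulate_signal) {
    spec_ph <- phantom_spec(labels, params, noise_sigma = 0, seed = seed)
    return(truth_only_phantom(spec_ph, acq, aif))
  }
  spec_ph <- phantom_spec(labels, params, noise_sigma = spec$noise_sigma,
                          snr = spec$snr, seed = seed)
  make_region_phantom(spec_ph, acq, aif, with_oxygen = FALSE)
}

# Ground truth draws without signal simulation (fast path).
truth_only_phantom <- function(spec, acq, aif) {
  labs3d <- spec$region_labels
  dims <- dim(labs3d)
  empty <- array(NA_real_, dims)
  maps <- list(cbf = empty, mtt = empty, cth = empty, k_app = empty)
  with_seed(spec$seed, {
    labs <- sort(unique(as.vector(labs3d))); labs <- labs[labs > 0]
    for (lb in labs) {
      rp <- spec$region_params[[as.character(lb)]]
      vox <- which(labs3d == lb)
      tr <- draw_truth(rp, length(vox))
      maps$cbf[vox] <- tr$cbf; maps$mtt[vox] <- tr$mtt
      maps$cth[vox] <- tr$cth; maps$k_app[vox] <- tr$k_app
    }
  })
  truth <- perfusion_maps(maps$cbf, maps$mtt, maps$cth, maps$k_app)
  structure(list(signal = NULL, truth = truth, labels = labs3d,
                 region_names = attr(spec$region_params, "region_names"),
                 aif = NULL, time = frame_times(acq), acq = acq,
                 noise_sigma = 0, spec = spec),
            class = "dsc_phantom")
}

# Tidy ground-truth records per region for the cohort table.
truth_region_records <- function(ph, id, age, group, visit) {
  if (inherits(ph, "lesion_phantom")) {
    zones <- ph$zones
    rows <- list()
    for (nm in names(zones)) {
      if (!any(zones[[nm]])) next
      for (map in c("cth", "k_app")) {
        st <- roi_mean(ph$baseline$truth[[map]], zones[[nm]], label = nm)
        rows[[length(rows) + 1L]] <-
          data.frame(subject_id = id, age = age, group = group,
                     visit = visit, region = nm, map = map,
                     value = st$mean)
      }
    }
    return(do.call(rbind, rows))
  }
  labs <- sort(unique(as.vector(ph$labels))); labs <- labs[labs > 0]
  rows <- list()
  for (lb in labs) {
    nm <- if (!is.null(ph$region_names)) ph$region_names[[as.character(lb)]]
          else as.character(lb)
    m <- ph$labels == lb
    for (map in c("cbf", "mtt", "cth", "k_app")) {
      st <- roi_mean(ph$truth[[map]], m, label = nm)
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = id, age = age, group = group, visit = visit,
                   region = nm, map = map, value = st$mean)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.dsc_cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, function(s) s$group, ""))
  cat("Synthetic DSC cohort:",
      paste(sprintf("%s n=%d", names(tab), as.integer(tab)), collapse = ", "),
      sprintf("(%d visits/subject)\n", x$spec$visits_per_subject))
  invisible(x)
}
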