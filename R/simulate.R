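# Synthetic study generator.  Defaults emulate a 12-volunteer crossover
# of 2/5/10 mg/cm^2 areal doses with a 4-h occluded uptake, 6-h
# clearance, up to 20 tapes per 5-cm^2 site grouped [2, 6, 6, 6], mean
# per-strip SC removal 0.0245 mg/cm^2 (20 strips ~ 0.49 mg/cm^2 ~ 4.9 um
# at density 1), LOQ censoring at 0.032 ug/mL in 2 mL extracts, and a
# chromameter blanching response with ~75% responders.

#' Per-subject generative parameters
#'
#' @param partition_scale surface concentration K*C_v (ng/cm^3): vehicle
#'   concentration times the SC/vehicle partition coefficient.
#' @param diffusivity_ratio D/L^2 (1/h), the characteristic diffusional
#'   rate of the subject's SC barrier.
#' @param sc_thickness SC thickness L (um).
#' @param k_true first-order SC elimination rate constant (1/h).
#' @param strip_mass_mean mean SC mass removed per tape (mg/cm^2).
#' @param responder whether the subject mounts a vascular response.
#' @param blanching_scale subject-specific blanching amplitude
#'   (a* units).
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(partition_scale, diffusivity_ratio,
                           sc_thickness, k_true, strip_mass_mean,
                           responder = TRUE, blanching_scale = 2) {
  stopifnot(partition_scale > 0, diffusivity_ratio > 0,
            sc_thickness > 0, k_true > 0, strip_mass_mean > 0,
            is.logical(responder), blanching_scale >= 0)
  structure(list(partition_scale = partition_scale,
                 diffusivity_ratio = diffusivity_ratio,
                 sc_thickness = sc_thickness, k_true = k_true,
                 strip_mass_mean = strip_mass_mean,
                 responder = responder,
                 blanching_scale = blanching_scale),
            class = "subject_params")
}

#' Simulation configuration
#'
#' Population-level defaults of the synthetic study.  Inter-subject
#' variability is lognormal on `partition_scale`, `diffusivity_ratio`,
#' `k_true`, `strip_mass_mean` and `blanching_scale`; SC thickness is
#' drawn uniformly within `sc_thickness_range`.  The uptake amplitude
#' saturates with dose as `dose / (dose + dose50)`.
#'
#' @param n_subjects number of volunteers.
#' @param doses areal doses of formulation (mg/cm^2).
#' @param uptake_h,clearance_h uptake duration and clearance delay (h).
#' @param area stripped template area per site (cm^2).
#' @param grouping tapes pooled per assay group, surface first.
#' @param partition_scale,dl2,k_mean,strip_mass_mean population medians
#'   of the corresponding [subject_params()] fields.
#' @param dose50 dose (mg/cm^2) at half-maximal uptake amplitude.
#' @param sc_thickness_range uniform range of SC thickness L (um).
#' @param cv_between inter-subject lognormal coefficient of variation.
#' @param cv_strip within-site per-strip SC-mass CV (lognormal).
#' @param cv_analytical analytical (assay) CV on group drug masses.
#' @param responder_prob probability a subject is a blanching responder.
#' @param blanching_scale median blanching amplitude (a* units).
#' @param blanching_q50 SC load (ng/cm^2) at half-maximal blanching.
#' @param blanching_tpeak time to peak of the response template (h).
#' @param chroma_noise_sd measurement SD of a single a* reading.
#' @param chroma_baseline mean baseline a* value.
#' @param times chromameter sampling times (h post-removal).
#' @param tewl_baseline pre-stripping TEWL (g m^-2 h^-1).
#' @param drug_fraction drug mass fraction of the formulation (w/w).
#' @param seed integer seed; mandatory, every run is reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12L, doses = c(2, 5, 10),
                       uptake_h = 4, clearance_h = 6, area = 5,
                       grouping = c(2L, 6L, 6L, 6L),
                       partition_scale = 3.1e5, dl2 = 0.1,
                       dose50 = 2, sc_thickness_range = c(8, 20),
                       k_mean = 0.065, strip_mass_mean = 0.0245,
                       cv_between = 0.3, cv_strip = 0.15,
                       cv_analytical = 0.10, responder_prob = 0.75,
                       blanching_scale = 2, blanching_q50 = 30,
                       blanching_tpeak = 8, chroma_noise_sd = 0.5,
                       chroma_baseline = 9,
                       times = c(2, 4, 6, 20, 22),
                       tewl_baseline = 10, drug_fraction = 0.00122,
                       seed) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory: every synthetic study is reproducible")
  stopifnot(n_subjects >= 1, all(doses > 0), uptake_h > 0,
            clearance_h > 0, area > 0, all(grouping >= 1),
            cv_between >= 0, cv_strip >= 0, cv_analytical >= 0,
            responder_prob >= 0, responder_prob <= 1,
            length(sc_thickness_range) == 2,
            sc_thickness_range[1] > 0,
            diff(sc_thickness_range) >= 0)
  structure(list(n_subjects = as.integer(n_subjects), doses = doses,
                 uptake_h = uptake_h, clearance_h = clearance_h,
                 area = area, grouping = as.integer(grouping),
                 partition_scale = partition_scale, dl2 = dl2,
                 dose50 = dose50,
                 sc_thickness_range = sc_thickness_range,
                 k_mean = k_mean, strip_mass_mean = strip_mass_mean,
                 cv_between = cv_between, cv_strip = cv_strip,
                 cv_analytical = cv_analytical,
                 responder_prob = responder_prob,
                 blanching_scale = blanching_scale,
                 blanching_q50 = blanching_q50,
                 blanching_tpeak = blanching_tpeak,
                 chroma_noise_sd = chroma_noise_sd,
                 chroma_baseline = chroma_baseline, times = times,
                 tewl_baseline = tewl_baseline,
                 drug_fraction = drug_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# lognormal with a given median and CV
rlnorm_cv <- function(n, median, cv) {
  if (cv == 0) return(rep(median, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

draw_subject_params <- function(config) {
  r <- config$sc_thickness_range
  subject_params(
    partition_scale = rlnorm_cv(1, config$partition_scale,
                                config$cv_between),
    diffusivity_ratio = rlnorm_cv(1, config$dl2, config$cv_between),
    sc_thickness = runif(1, r[1], r[2]),
    k_true = rlnorm_cv(1, config$k_mean, config$cv_between),
    strip_mass_mean = rlnorm_cv(1, config$strip_mass_mean,
                                config$cv_between),
    responder = runif(1) < config$responder_prob,
    blanching_scale = rlnorm_cv(1, config$blanching_scale,
                                config$cv_between))
}

#' Strip one site of a simulated profile
#'
#' Draws per-tape SC masses (lognormal around the subject's mean, CV
#' `cv_strip`), removes successive depth slabs from the profile, and
#' stops at the first stopping-rule hit.  TEWL after removing a depth
#' `h` of the SC follows the inverse remaining-thickness law
#' `TEWL0 * L / (L - h)`.  The drug on each tape is the integral of the
#' concentration profile over the removed slab.  Consumes the global
#' RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param profile an `sc_sim_profile` (see [uptake_profile()],
#'   [clearance_profile()]).
#' @param params the subject's [subject_params()].
#' @param rule a [stopping_rule()].
#' @param area stripped area (cm^2).
#' @param cv_strip per-strip SC-mass coefficient of variation.
#' @param tewl_baseline pre-stripping TEWL (g m^-2 h^-1).
#' @return a list with `strips` (data frame: `strip_index`,
#'   `sc_mass_mg`, `area_cm2`, `depth_top_um`, `depth_bottom_um`,
#'   `drug_ng`) and `tewl` (trace after each strip, baseline first).
#' @export
strip_site <- function(profile, params, rule = stopping_rule(),
                       area = 5, cv_strip = 0.15, tewl_baseline = 10) {
  stopifnot(inherits(profile, "sc_sim_profile"),
            inherits(rule, "stopping_rule"))
  L <- profile$L_um
  tewl <- tewl_baseline
  depth <- 0
  rows <- vector("list", rule$max_strips)
  for (i in seq_len(rule$max_strips)) {
    m_percm2 <- rlnorm_cv(1, params$strip_mass_mean, cv_strip)
    d_um <- min(10 * m_percm2, L - depth)   # density 1 g/cm^3; cap at L
    m_percm2 <- d_um / 10
    drug <- profile_Q(profile, depth, depth + d_um) * area
    rows[[i]] <- data.frame(strip_index = i,
                            sc_mass_mg = m_percm2 * area,
                            area_cm2 = area,
                            depth_top_um = depth,
                            depth_bottom_um = depth + d_um,
                            drug_ng = drug)
    depth <- depth + d_um
    tewl_i <- if (depth >= L) Inf else tewl_baseline * L / (L - depth)
    tewl <- c(tewl, tewl_i)
    if (tewl_i >= rule$tewl_abs_max ||
        tewl_i >= rule$tewl_fold_max * tewl_baseline) break
  }
  list(strips = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       tewl = tewl)
}

#' Pool strips into assay groups and apply the analytical model
#'
#' Groups tapes surface-first per `grouping` (a trailing short group is
#' kept), sums their true drug masses, perturbs each group mass with
#' multiplicative Gaussian analytical noise (floored at zero), and flags
#' groups whose extract concentration falls below the LOQ as BLQ.
#'
#' @param strips the `strips` data frame from [strip_site()].
#' @param grouping tapes per group, e.g. `c(2, 6, 6, 6)`.
#' @param assay an [assay_config()].
#' @param cv_analytical analytical CV; 0 gives exact slab integrals.
#' @return data frame: `group_id`, `strip_first`, `strip_last`,
#'   `n_strips`, `sc_mass_total_mg`, `area_cm2`, `true_drug_ng`,
#'   `meas_drug_ng` (measured mass before censoring), `drug_mass_ng`
#'   (NA when BLQ), `blq`.
#' @export
assay_groups <- function(strips, grouping = c(2L, 6L, 6L, 6L),
                         assay = assay_config(), cv_analytical = 0.10) {
  stopifnot(inherits(assay, "assay_config"), nrow(strips) >= 1)
  ends <- cumsum(grouping)
  starts <- c(1L, head(ends, -1L) + 1L)
  keep <- starts <= nrow(strips)
  starts <- starts[keep]
  ends <- pmin(ends[keep], nrow(strips))   # last group truncated
  out <- do.call(rbind, lapply(seq_along(starts), function(g) {
    i <- strips$strip_index >= starts[g] & strips$strip_index <= ends[g]
    true_ng <- sum(strips$drug_ng[i])
    meas <- true_ng * (1 + rnorm(1, 0, cv_analytical))
    meas <- max(meas, 0)
    conc_ug_ml <- (meas / 1000) / assay$extraction_volume
    blq <- conc_ug_ml < assay$loq
    data.frame(group_id = sprintf("g%d", g),
               strip_first = starts[g], strip_last = ends[g],
               n_strips = sum(i),
               sc_mass_total_mg = sum(strips$sc_mass_mg[i]),
               area_cm2 = strips$area_cm2[1],
               true_drug_ng = true_ng,
               meas_drug_ng = meas,
               drug_mass_ng = if (blq) NA_real_ else meas,
               blq = blq)
  }))
  rownames(out) <- NULL
  out
}

# unimodal response template, peak 1 at t = tpeak, template(0) = 0
blanch_template <- function(t, tpeak = 8) {
  (t / tpeak) * exp(1 - t / tpeak)
}

#' Simulate chromameter readings for one treated site
#'
#' The treated site's systematic colour change is
#' `-blanching_scale * Q/(Q + q50) * template(t)` (an Emax link on the
#' delivered SC load times a unimodal time template); non-responders
#' have no systematic component.  All four sites share a common slow
#' drift; every reading is made in duplicate with independent Gaussian
#' noise.  Consumes the global RNG stream.
#'
#' @param subject_id,site_id identifiers for the emitted rows.
#' @param q_delivered SC drug load at the end of uptake (ng/cm^2).
#' @param params the subject's [subject_params()].
#' @param config a [sim_config()] (uses the blanching and chromameter
#'   fields and `times`).
#' @return raw chromameter rows (CSV schema of
#'   [read_chromameter_table()], two replicates per reading).
#' @export
simulate_blanching <- function(subject_id, site_id, q_delivered, params,
                               config) {
  times <- config$times
  roles <- c("treated", CONTROL_ROLES)
  base_mean <- rnorm(length(roles), config$chroma_baseline, 0.5)
  names(base_mean) <- roles
  drift <- rnorm(length(times), 0, 0.3)   # shared ambient drift
  link <- q_delivered / (q_delivered + config$blanching_q50)
  effect <- if (params$responder)
    -params$blanching_scale * link * blanch_template(times,
                                                     config$blanching_tpeak)
  else rep(0, length(times))
  rows <- list()
  for (r in roles) {
    mu_t <- c(NA, base_mean[[r]] + drift +
                if (r == "treated") effect else 0)
    tt <- c(NA, times)
    for (j in seq_along(tt)) {
      mu <- if (j == 1) base_mean[[r]] else mu_t[j]
      for (rep_i in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subject_id, site_id = site_id, role = r,
          time_h = tt[j],
          a_star = rnorm(1, mu, config$chroma_noise_sd),
          replicate = rep_i)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a complete tape-strip + blanching study
#'
#' For each subject and dose, one uptake and one clearance SC-sampling
#' site are stripped and assayed, and one blanching site (with three
#' untreated controls) is read over `config$times`.  Per-subject
#' parameter draws use deterministic sub-seeds derived from
#' `config$seed`, so any subject's data are reproducible in isolation.
#'
#' @param config a [sim_config()].
#' @return an object of class `sctape_study`: a list with
#'   \describe{
#'     \item{strip_data}{a `strip_data` object (tapes + assayed groups).}
#'     \item{chroma}{raw duplicate chromameter rows.}
#'     \item{sites}{site metadata: `subject_id`, `site_id`, `dose`,
#'       `phase`, `area_cm2`.}
#'     \item{truth}{per SC site: true full-SC Q (ng/cm^2) at
#'       sampling, the uncensored measured Q over the stripped depth
#'       (`q_meas`), `k_true`, and the subject draws.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L,
                              config$n_subjects)
  strips_all <- list(); groups_all <- list(); chroma_all <- list()
  sites_all <- list(); truth_all <- list()
  rule <- stopping_rule()
  assay <- assay_config()
  for (s in seq_len(config$n_subjects)) {
    set.seed(subject_seeds[s])
    sid <- sprintf("S%02d", s)
    par <- draw_subject_params(config)
    for (d in config$doses) {
      dose_amp <- d / (d + config$dose50)
      par_d <- par
      par_d$partition_scale <- par$partition_scale * dose_amp
      up0 <- sc_sim_profile(par_d, config$uptake_h)
      q_up_true <- profile_Q(up0)
      for (phase in c("uptake", "clearance")) {
        site_id <- sprintf("%s_sc_d%g_%s", sid, d,
                           substr(phase, 1, 2))
        prof <- if (phase == "uptake") up0
                else clearance_profile(up0, config$clearance_h,
                                       par$k_true)
        stripped <- strip_site(prof, par, rule, config$area,
                               config$cv_strip, config$tewl_baseline)
        grp <- assay_groups(stripped$strips, config$grouping, assay,
                            config$cv_analytical)
        st <- stripped$strips
        strips_all[[length(strips_all) + 1L]] <- data.frame(
          subject_id = sid, site_id = site_id,
          strip_index = st$strip_index, sc_mass_mg = st$sc_mass_mg,
          area_cm2 = st$area_cm2,
          group_id = grp$group_id[findInterval(st$strip_index,
                                               grp$strip_first)],
          stringsAsFactors = FALSE)
        groups_all[[length(groups_all) + 1L]] <- cbind(
          data.frame(subject_id = sid, site_id = site_id,
                     stringsAsFactors = FALSE),
          grp[, c("group_id", "strip_first", "strip_last", "n_strips",
                  "sc_mass_total_mg", "area_cm2", "drug_mass_ng",
                  "blq")])
        sites_all[[length(sites_all) + 1L]] <- data.frame(
          subject_id = sid, site_id = site_id, dose = d,
          phase = phase, area_cm2 = config$area,
          stringsAsFactors = FALSE)
        truth_all[[length(truth_all) + 1L]] <- data.frame(
          subject_id = sid, site_id = site_id, dose = d, phase = phase,
          q_true = if (phase == "uptake") q_up_true
                   else q_up_true * exp(-par$k_true * config$clearance_h),
          q_meas = sum(grp$meas_drug_ng) / config$area,
          k_true = par$k_true,
          partition_scale = par$partition_scale,
          diffusivity_ratio = par$diffusivity_ratio,
          sc_thickness = par$sc_thickness,
          responder = par$responder, stringsAsFactors = FALSE)
      }
      sb_site <- sprintf("%s_sb_d%g", sid, d)
      chroma_all[[length(chroma_all) + 1L]] <-
        simulate_blanching(sid, sb_site, q_up_true, par, config)
      sites_all[[length(sites_all) + 1L]] <- data.frame(
        subject_id = sid, site_id = sb_site, dose = d,
        phase = "blanching", area_cm2 = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  strips <- do.call(rbind, strips_all)
  groups <- do.call(rbind, groups_all)
  rownames(strips) <- rownames(groups) <- NULL
  structure(list(
    strip_data = structure(list(strips = strips, groups = groups),
                           class = "strip_data"),
    chroma = do.call(rbind, chroma_all),
    sites = do.call(rbind, sites_all),
    truth = do.call(rbind, truth_all),
    config = config), class = "sctape_study")
}

#' Write all tables of a simulated study
#'
#' Emits `strips.csv`, `chromameter.csv`, `sites.csv` and
#' `ground_truth.csv` under `dir`.
#'
#' @param study an `sctape_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sctape_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_strip_table(study$strip_data, file.path(dir, "strips.csv"))
  write_chromameter_table(study$chroma,
                          file.path(dir, "chromameter.csv"))
  write_plain_csv(study$sites, file.path(dir, "sites.csv"))
  write_plain_csv(study$truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

write_plain_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
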