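# Depth profiles and per-site areal drug loads (Q) from tape-strip data.
#
# Depth coordinate: 0 at the (cleaned) SC surface; each tape removes a
# slab whose thickness follows from its SC mass, the sampled area and
# the SC density.  Group depth intervals are half-open [top, bottom).
# BLQ policy: censored groups contribute 0 to Q by default ("zero"), or
# half the LOQ-equivalent mass ("half-loq"); the censored fraction is
# always reported.

#' SC thickness removed from SC mass
#'
#' `thickness = mass / (area * density)`, returned in micrometres:
#' 0.49 mg over 1 cm^2 at 1 g/cm^3 is 4.9 um.
#'
#' @param sc_mass_mg SC mass (mg).
#' @param area_cm2 sampled area (cm^2).
#' @param density SC density (g/cm^3).
#' @return thickness (um).
#' @export
thickness_from_mass <- function(sc_mass_mg, area_cm2, density = 1) {
  if (any(area_cm2 <= 0)) stop("`area_cm2` must be > 0")
  if (any(density <= 0)) stop("`density` must be > 0")
  if (any(sc_mass_mg < 0)) stop("`sc_mass_mg` must be >= 0")
  10 * sc_mass_mg / (area_cm2 * density)
}

blq_mass_ng <- function(policy, assay) {
  switch(policy,
         zero = 0,
         `half-loq` = assay$loq / 2 * assay$extraction_volume * 1000,
         stop("unknown BLQ policy: ", policy))
}

#' Average drug concentration of pooled tape groups
#'
#' The concentration of each assayed group is the extracted drug mass
#' divided by the pooled SC mass (ng per mg of SC), also expressed
#' volumetrically (ng/cm^3) via the SC density.  Censored (BLQ) groups
#' get the policy value with `censored = TRUE`.
#'
#' @param groups the `groups` data frame of a `strip_data` object.
#' @param assay an [assay_config()].
#' @param blq_policy `"zero"` (default) or `"half-loq"`.
#' @return `groups` with added columns `conc_ng_mg`, `conc_ng_cm3`,
#'   `censored`.
#' @export
group_concentration <- function(groups, assay = assay_config(),
                                blq_policy = c("zero", "half-loq")) {
  blq_policy <- match.arg(blq_policy)
  drug <- ifelse(groups$blq, blq_mass_ng(blq_policy, assay),
                 groups$drug_mass_ng)
  bad <- which(groups$sc_mass_total_mg <= 0 & drug > 0)
  if (length(bad))
    stop("group(s) with zero SC mass but nonzero drug: ",
         paste(groups$group_id[bad], collapse = ", "))
  conc <- ifelse(groups$sc_mass_total_mg > 0,
                 drug / groups$sc_mass_total_mg, 0)
  groups$conc_ng_mg <- conc
  # ng/mg -> ng/cm^3: 1 mg of SC occupies 1e-3/density cm^3
  groups$conc_ng_cm3 <- conc * 1000 * assay$sc_density
  groups$censored <- groups$blq
  groups
}

#' Per-site areal drug load Q
#'
#' `Q = sum(group drug masses) / area` (ng/cm^2).  Censored groups
#' contribute per the BLQ policy; a site whose groups are all censored
#' yields Q per policy with a warning.
#'
#' @param groups the `groups` data frame of a `strip_data` object
#'   (one or more sites).
#' @param assay an [assay_config()].
#' @param blq_policy `"zero"` (default) or `"half-loq"`.
#' @return data frame, one row per site: `subject_id`, `site_id`,
#'   `q_ng_cm2`, `n_groups`, `censored_fraction`.
#' @export
site_Q <- function(groups, assay = assay_config(),
                   blq_policy = c("zero", "half-loq")) {
  blq_policy <- match.arg(blq_policy)
  if (nrow(groups) < 1) stop("need at least one group")
  drug <- ifelse(groups$blq, blq_mass_ng(blq_policy, assay),
                 groups$drug_mass_ng)
  key <- paste(groups$subject_id, groups$site_id, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(groups)), key),
                               function(i) {
    g <- groups[i, ]
    if (all(g$blq))
      warning("site ", g$site_id[1], ": all groups censored (BLQ)",
              call. = FALSE)
    if (length(unique(g$area_cm2)) != 1)
      stop("site ", g$site_id[1], ": inconsistent areas")
    data.frame(subject_id = g$subject_id[1], site_id = g$site_id[1],
               q_ng_cm2 = sum(drug[i]) / g$area_cm2[1],
               n_groups = nrow(g),
               censored_fraction = mean(g$blq),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Concentration-depth profile per site
#'
#' Cumulative depth intervals are built from per-tape thicknesses
#' ([thickness_from_mass()]); each pooled group's average concentration
#' is placed on its half-open interval \[top, bottom) with the midpoint
#' as the single-point depth summary.
#'
#' @param x a `strip_data` object.
#' @param assay an [assay_config()].
#' @param blq_policy `"zero"` (default) or `"half-loq"`.
#' @return data frame, one row per site x group: identifiers, depth
#'   interval (`depth_top_um`, `depth_bottom_um`, `depth_mid_um`),
#'   `conc_ng_mg`, `conc_ng_cm3`, `drug_mass_ng`, `censored`, and the
#'   site totals `total_thickness_um`.
#' @export
depth_profile <- function(x, assay = assay_config(),
                          blq_policy = c("zero", "half-loq")) {
  stopifnot(inherits(x, "strip_data"))
  blq_policy <- match.arg(blq_policy)
  strips <- x$strips
  groups <- group_concentration(x$groups, assay, blq_policy)
  strips$thick_um <- thickness_from_mass(strips$sc_mass_mg,
                                         strips$area_cm2,
                                         assay$sc_density)
  skey <- paste(strips$subject_id, strips$site_id, sep = "\r")
  gkey <- paste(groups$subject_id, groups$site_id, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(groups)), gkey),
                               function(i) {
    g <- groups[i, ]
    g <- g[order(g$strip_first), ]
    st <- strips[skey == paste(g$subject_id[1], g$site_id[1],
                               sep = "\r"), ]
    st <- st[order(st$strip_index), ]
    cum <- cumsum(st$thick_um)
    top_at <- function(idx) if (idx <= 1) 0 else cum[idx - 1]
    tops <- vapply(g$strip_first, top_at, numeric(1))
    bots <- cum[pmin(g$strip_last, nrow(st))]
    data.frame(subject_id = g$subject_id, site_id = g$site_id,
               group_id = g$group_id,
               depth_top_um = tops, depth_bottom_um = bots,
               depth_mid_um = (tops + bots) / 2,
               conc_ng_mg = g$conc_ng_mg, conc_ng_cm3 = g$conc_ng_cm3,
               drug_mass_ng = ifelse(g$blq,
                                     blq_mass_ng(blq_policy, assay),
                                     g$drug_mass_ng),
               censored = g$censored,
               total_thickness_um = cum[length(cum)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
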