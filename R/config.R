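#' Assay configuration
#'
#' Limits of quantification/detection of the drug assay, the extraction
#' volume used for pooled tape groups, and the assumed SC density used to
#' convert SC mass per area into thickness.
#'
#' @param loq limit of quantification (ug/mL). Group extracts whose
#'   concentration falls below this are below the limit of quantification
#'   (BLQ).
#' @param lod limit of detection (ug/mL); must be `< loq`.
#' @param extraction_volume solvent volume per pooled group (mL).
#' @param sc_density SC density (g/cm^3); 1 g/cm^3 is the conventional
#'   assumption for hydrated SC.
#' @return an object of class `assay_config`.
#' @export
assay_config <- function(loq = 0.032, lod = 0.01, extraction_volume = 2,
                         sc_density = 1) {
  stopifnot(is.numeric(loq), loq > 0, is.numeric(lod), lod > 0,
            is.numeric(extraction_volume), extraction_volume > 0,
            is.numeric(sc_density), sc_density > 0)
  if (lod >= loq) stop("`lod` must be smaller than `loq`")
  structure(list(loq = loq, lod = lod,
                 extraction_volume = extraction_volume,
                 sc_density = sc_density),
            class = "assay_config")
}

#' Tape-stripping stopping rule
#'
#' Stripping halts at the first of: absolute TEWL threshold, fold rise
#' over the pre-stripping baseline, or a hard cap on the number of tapes.
#'
#' @param tewl_abs_max absolute transepidermal water loss ceiling
#'   (g m^-2 h^-1).
#' @param tewl_fold_max maximum TEWL as a multiple of baseline.
#' @param max_strips maximum number of tapes per site.
#' @return an object of class `stopping_rule`.
#' @export
stopping_rule <- function(tewl_abs_max = 60, tewl_fold_max = 6,
                          max_strips = 20L) {
  stopifnot(tewl_abs_max > 0, tewl_fold_max > 1, max_strips >= 1)
  structure(list(tewl_abs_max = tewl_abs_max,
                 tewl_fold_max = tewl_fold_max,
                 max_strips = as.integer(max_strips)),
            class = "stopping_rule")
}

#' Site treatment metadata
#'
#' Describes one treated application site: areal dose of formulation,
#' phase (uptake or clearance), uptake duration and the clearance delay
#' between formulation removal and sampling, and the drug mass fraction
#' of the formulation (w/w; 0.00122 for a 0.122% w/w cream).
#'
#' @param subject_id,site_id identifiers.
#' @param dose areal dose of formulation (mg/cm^2).
#' @param phase `"uptake"` or `"clearance"`.
#' @param uptake_duration application time (h).
#' @param clearance_delay delay between removal and stripping for
#'   clearance sites (h).
#' @param drug_fraction drug mass fraction of the formulation.
#' @return an object of class `site_treatment`.
#' @export
site_treatment <- function(subject_id, site_id, dose,
                           phase = c("uptake", "clearance"),
                           uptake_duration = 4, clearance_delay = 6,
                           drug_fraction = 0.00122) {
  phase <- match.arg(phase)
  stopifnot(dose > 0, uptake_duration > 0, drug_fraction > 0)
  if (phase == "clearance" && clearance_delay <= 0)
    stop("`clearance_delay` must be > 0 for clearance sites")
  structure(list(subject_id = as.character(subject_id),
                 site_id = as.character(site_id), dose = dose,
                 phase = phase, uptake_duration = uptake_duration,
                 clearance_delay = clearance_delay,
                 drug_fraction = drug_fraction),
            class = "site_treatment")
}

#' Read / write a flat JSON run configuration
#'
#' The configuration file is a flat JSON object whose keys mirror the
#' arguments of [assay_config()], [stopping_rule()] and [sim_config()],
#' plus the BLQ policy and the AAEC t = 0 anchor flag.  Command-line
#' flags override file values.
#'
#' @param path file path.
#' @return `read_run_config()`: a named list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("config file must contain a JSON object")
  cfg
}

#' @rdname read_run_config
#' @param config named list of configuration values.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
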