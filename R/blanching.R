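# Skin-blanching (vasoconstriction assay) analysis: chromameter a*
# normalisation against three untreated control sites and the signed
# area above the blanching effect curve (AAEC, hours).

#' Normalised blanching response per time point
#'
#' For one treated site with its three controls,
#' `delta_a_t = (a*_T,t - a*_T,0) - mean_n(a*_Cn,t - a*_Cn,0)`:
#' the baseline-corrected treated change minus the mean
#' baseline-corrected control change, so any colour drift common to the
#' four sites cancels exactly.
#'
#' @param x a `chroma_data` object (or data frame with its columns)
#'   holding exactly one site: roles `treated` and `control1..3`, a
#'   baseline row (`time_h = NA`) per role, identical time grids.
#' @return data frame per time: `time_h`, `delta_treated`,
#'   `delta_control`, `delta_a`.
#' @export
delta_a <- function(x) {
  df <- as.data.frame(x)
  site_lbl <- paste(unique(df$subject_id), unique(df$site_id))
  if (length(unique(df$site_id)) != 1)
    stop("`delta_a()` expects a single site; got ",
         length(unique(df$site_id)))
  roles <- c("treated", CONTROL_ROLES)
  missing_roles <- setdiff(roles, unique(df$role))
  if (length(missing_roles))
    stop(site_lbl, ": missing role(s): ",
         paste(missing_roles, collapse = ", "))
  base <- df[is.na(df$time_h), ]
  if (any(!roles %in% base$role))
    stop(site_lbl, ": missing baseline for role(s): ",
         paste(setdiff(roles, base$role), collapse = ", "))
  b <- setNames(base$a_star, base$role)
  obs <- df[!is.na(df$time_h), ]
  times <- sort(unique(obs$time_h))
  per_role <- lapply(roles, function(r) {
    o <- obs[obs$role == r, ]
    if (!setequal(o$time_h, times))
      stop(site_lbl, ": role ", r,
           " does not share the common time grid")
    o$a_star[match(times, o$time_h)] - b[[r]]
  })
  names(per_role) <- roles
  d_ctrl <- (per_role$control1 + per_role$control2 +
               per_role$control3) / 3
  data.frame(time_h = times,
             delta_treated = per_role$treated,
             delta_control = d_ctrl,
             delta_a = per_role$treated - d_ctrl)
}

# signed trapezoidal integral
trapz <- function(x, y) {
  if (is.unsorted(x, strictly = TRUE)) stop("times must be increasing")
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Area above the blanching effect curve (AAEC)
#'
#' Signed trapezoidal integral of `delta_a` over 0--22 h.  Because the
#' normalisation forces the response to zero at baseline, an anchor
#' `delta_a = 0` at `t = 0` (the moment of formulation removal) is
#' prepended by default so the integral genuinely spans from 0 h even
#' though the first reading is at 2 h.  Negative AAEC indicates
#' blanching; a subject/site is a responder when `aaec < 0`.
#'
#' @param delta_a_t normalised response per time ([delta_a()] values).
#' @param times sampling times (h, increasing, all `> 0` and
#'   `<= t_max`).
#' @param anchor prepend the `(0, 0)` anchor point (default `TRUE`).
#' @param t_max end of the integration window (h).
#' @return list of class `aaec_result`: `aaec` (hours, signed),
#'   `responder` (`aaec < 0`), `times`, `delta_a`.
#' @export
aaec <- function(delta_a_t, times, anchor = TRUE, t_max = 22) {
  if (length(delta_a_t) != length(times))
    stop("`delta_a_t` and `times` lengths differ")
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing")
  if (any(times > t_max + 1e-9) || any(times <= 0 & !anchor) ||
      any(times < 0))
    stop("`times` must lie in (0, t_max]")
  tt <- times; yy <- delta_a_t
  if (anchor && tt[1] > 0) { tt <- c(0, tt); yy <- c(0, yy) }
  a <- trapz(tt, yy)
  structure(list(aaec = a, responder = a < 0, times = times,
                 delta_a = delta_a_t),
            class = "aaec_result")
}

#' Per-site AAEC for a whole chromameter table
#'
#' Runs [delta_a()] and [aaec()] on every site of a `chroma_data`
#' object; site metadata (dose) may be merged in for downstream
#' responder tabulation.
#'
#' @param x a `chroma_data` object.
#' @param sites optional site metadata with `subject_id`, `site_id`,
#'   `dose`.
#' @inheritParams aaec
#' @return data frame, one row per site: `subject_id`, `site_id`,
#'   (`dose`,) `aaec`, `responder`.
#' @export
analyze_blanching <- function(x, sites = NULL, anchor = TRUE,
                              t_max = 22) {
  df <- as.data.frame(x)
  key <- paste(df$subject_id, df$site_id, sep = "\r")
  out <- do.call(rbind, lapply(split(df, key), function(site) {
    d <- delta_a(site)
    r <- aaec(d$delta_a, d$time_h, anchor = anchor, t_max = t_max)
    data.frame(subject_id = site$subject_id[1],
               site_id = site$site_id[1],
               aaec = r$aaec, responder = r$responder,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(sites))
    out <- merge(out, sites[, c("subject_id", "site_id", "dose")],
                 by = c("subject_id", "site_id"), sort = FALSE)
  out[order(out$subject_id, out$site_id), ]
}

#' Responder matrix and population subsets
#'
#' Cross-tabulates responders (AAEC < 0) by subject and dose, and
#' derives the two subsets used for power analysis: subjects responding
#' to at least one dose, and "consistent" responders to all doses.
#'
#' @param aaec_df output of [analyze_blanching()] with a `dose` column.
#' @return list: `matrix` (subjects x doses, logical), `counts`
#'   (responders per dose), `any_dose`, `all_doses` (subject ids),
#'   `summaries` (per dose x subset: n, mean, sd of AAEC among
#'   responders in that subset).
#' @export
responder_table <- function(aaec_df) {
  if (!"dose" %in% names(aaec_df))
    stop("`aaec_df` needs a `dose` column (pass `sites` to ",
         "`analyze_blanching()`)")
  subjects <- sort(unique(aaec_df$subject_id))
  doses <- sort(unique(aaec_df$dose))
  m <- matrix(FALSE, length(subjects), length(doses),
              dimnames = list(subjects, as.character(doses)))
  a <- matrix(NA_real_, length(subjects), length(doses),
              dimnames = dimnames(m))
  for (i in seq_len(nrow(aaec_df))) {
    r <- aaec_df[i, ]
    m[r$subject_id, as.character(r$dose)] <- r$responder
    a[r$subject_id, as.character(r$dose)] <- r$aaec
  }
  any_dose <- subjects[rowSums(m) >= 1]
  all_doses <- subjects[rowSums(m) == length(doses)]
  summaries <- do.call(rbind, lapply(as.character(doses), function(d) {
    do.call(rbind, lapply(c("any_dose", "all_doses"), function(set) {
      subs <- if (set == "any_dose") any_dose else all_doses
      # per-dose values from subset members that responded to this dose
      subs <- subs[m[subs, d]]
      v <- a[subs, d]
      s <- summarize_metric(v)
      cbind(data.frame(dose = as.numeric(d), subset = set), s)
    }))
  }))
  list(matrix = m, counts = colSums(m), any_dose = any_dose,
       all_doses = all_doses, summaries = summaries)
}
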