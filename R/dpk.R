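# Dermatopharmacokinetic metrics from paired uptake/clearance Q values,
# with Grubbs outlier screening and t-based summaries.

#' Average input flux from the SC into viable tissue
#'
#' `J = (Q_up - Q_cl) / dt` (ng cm^-2 h^-1).  A negative flux (clearance
#' load above uptake load) is reported with a warning, never clipped.
#'
#' @param q_up,q_cl areal drug loads at uptake and clearance (ng/cm^2).
#' @param dt elapsed time between the two measurements (h).
#' @return flux (ng cm^-2 h^-1), vectorised.
#' @export
dpk_flux <- function(q_up, q_cl, dt) {
  if (any(dt <= 0)) stop("`dt` must be > 0")
  j <- (q_up - q_cl) / dt
  if (any(j < 0, na.rm = TRUE))
    warning("negative flux: Q_cl exceeds Q_up for ",
            sum(j < 0, na.rm = TRUE), " site pair(s)", call. = FALSE)
  j
}

#' First-order SC elimination rate constant
#'
#' `k = -ln(Q_cl / Q_up) / dt` (1/h), from the two-point first-order
#' clearance model.  Undefined (NA, with a warning) when either Q is
#' zero or censored to zero; negative (Q_cl > Q_up) values are kept
#' with a warning.
#'
#' @inheritParams dpk_flux
#' @return rate constant (1/h), vectorised; `NA` where undefined.
#' @export
elim_rate <- function(q_up, q_cl, dt) {
  if (any(dt <= 0)) stop("`dt` must be > 0")
  ok <- q_up > 0 & q_cl > 0
  k <- rep(NA_real_, length(ok))
  k[ok] <- -log(q_cl[ok] / q_up[ok]) / dt[if (length(dt) == 1) 1 else ok]
  if (any(!ok))
    warning(sum(!ok), " site pair(s) with zero/censored Q: k undefined",
            call. = FALSE)
  if (any(k < 0, na.rm = TRUE))
    warning("negative k for ", sum(k < 0, na.rm = TRUE),
            " site pair(s)", call. = FALSE)
  k
}

#' Relative SC depletion over the clearance period
#'
#' `1 - Q_cl / Q_up`, the fraction of the uptake load lost during
#' clearance.
#'
#' @inheritParams dpk_flux
#' @return depletion fraction, vectorised.
#' @export
depletion <- function(q_up, q_cl) {
  ifelse(q_up > 0, 1 - q_cl / q_up, NA_real_)
}

#' Percent of the applied dose recovered in the SC
#'
#' The applied drug is `dose * drug_fraction`, converted from mg/cm^2 to
#' ng/cm^2; the recovery is `100 * q_up / applied`.
#'
#' @param q_up areal drug load at uptake (ng/cm^2).
#' @param dose areal dose of formulation (mg/cm^2).
#' @param drug_fraction drug mass fraction of the formulation (w/w).
#' @return percent of applied drug found in the SC.
#' @export
pct_dose_recovered <- function(q_up, dose, drug_fraction = 0.00122) {
  if (any(dose <= 0) || any(drug_fraction <= 0))
    stop("`dose` and `drug_fraction` must be > 0")
  applied_ng_cm2 <- dose * drug_fraction * 1e6
  100 * q_up / applied_ng_cm2
}

#' Grubbs outlier screen
#'
#' Single-pass two-sided Grubbs test: `G = max|x - mean| / sd` compared
#' with `G_crit = ((N-1)/sqrt(N)) * sqrt(t^2 / (N - 2 + t^2))` where `t`
#' is the upper `alpha/(2N)` quantile of Student's t with `N - 2`
#' degrees of freedom.  At most one value is removed per pass (default
#' one pass).  A zero-variance sample is degenerate: nothing removed.
#'
#' @param x numeric vector, `length(x) >= 3`.
#' @param alpha significance level of the screen.
#' @param passes maximum number of removal passes.
#' @return list: `kept` (values), `removed` (indices into `x`),
#'   `G`, `G_crit` (last pass), `degenerate`.
#' @export
grubbs_screen <- function(x, alpha = 0.05, passes = 1L) {
  if (length(x) < 3) stop("Grubbs test needs n >= 3")
  removed <- integer(0)
  live <- seq_along(x)
  G <- G_crit <- NA_real_
  degenerate <- FALSE
  for (p in seq_len(passes)) {
    v <- x[live]
    n <- length(v)
    if (n < 3) break
    s <- sd(v)
    if (s == 0) { degenerate <- TRUE; break }
    dev <- abs(v - mean(v))
    G <- max(dev) / s
    tq <- qt(1 - alpha / (2 * n), n - 2)
    G_crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (G > G_crit) {
      out <- live[which.max(dev)]
      removed <- c(removed, out)
      live <- setdiff(live, out)
    } else break
  }
  list(kept = x[live], removed = removed, G = G, G_crit = G_crit,
       degenerate = degenerate)
}

#' Arithmetic mean with a t-based 95% confidence half-width
#'
#' `ci95_half = t(0.975, n-1) * sd / sqrt(n)`.  With `n = 1` the CI is
#' undefined and flagged.
#'
#' @param x numeric vector (NAs dropped).
#' @param conf confidence level.
#' @return one-row data frame: `n`, `mean`, `sd`, `ci95_half`,
#'   `ci_defined`.
#' @export
summarize_metric <- function(x, conf = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0)
    return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_,
                      ci95_half = NA_real_, ci_defined = FALSE))
  m <- mean(x)
  s <- if (n > 1) sd(x) else NA_real_
  half <- if (n > 1) qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
          else NA_real_
  data.frame(n = n, mean = m, sd = s, ci95_half = half,
             ci_defined = n > 1)
}

# report-style half-up rounding (R's round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-subject DPK metrics from paired sites
#'
#' Joins each subject's uptake and clearance Q at the same dose and
#' derives J, k, depletion and percent dose recovered.
#'
#' @param siteq per-site Q table ([site_Q()] output) merged with site
#'   metadata: columns `subject_id`, `site_id`, `q_ng_cm2`, `dose`,
#'   `phase`.
#' @param dt clearance delay (h).
#' @param drug_fraction drug mass fraction of the formulation.
#' @return data frame, one row per subject x dose: `q_up`, `q_cl`, `dt`,
#'   `flux`, `k`, `depletion`, `pct_recovered`.
#' @export
dpk_metrics <- function(siteq, dt = 6, drug_fraction = 0.00122) {
  need <- c("subject_id", "q_ng_cm2", "dose", "phase")
  missing <- setdiff(need, names(siteq))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  up <- siteq[siteq$phase == "uptake", ]
  cl <- siteq[siteq$phase == "clearance", ]
  key <- function(d) paste(d$subject_id, d$dose, sep = "\r")
  m <- match(key(up), key(cl))
  if (anyNA(m))
    stop("unpaired uptake site(s): ",
         paste(up$subject_id[is.na(m)], up$dose[is.na(m)],
               collapse = ", "))
  q_up <- up$q_ng_cm2
  q_cl <- cl$q_ng_cm2[m]
  out <- data.frame(subject_id = up$subject_id, dose = up$dose,
                    q_up = q_up, q_cl = q_cl, dt = dt,
                    flux = dpk_flux(q_up, q_cl, dt),
                    k = suppressWarnings(elim_rate(q_up, q_cl, dt)),
                    depletion = depletion(q_up, q_cl),
                    pct_recovered = pct_dose_recovered(q_up, up$dose,
                                                       drug_fraction),
                    stringsAsFactors = FALSE)
  out[order(out$subject_id, out$dose), ]
}

#' Aggregate study report (per-dose means with 95% CIs)
#'
#' Summarises Q_up, Q_cl, J and 10^2 k per dose as arithmetic means with
#' t-based 95% confidence half-widths, after an optional Grubbs screen
#' per dose and metric.
#'
#' @param metrics output of [dpk_metrics()].
#' @param grubbs apply a single-pass Grubbs screen per dose x metric.
#' @param alpha significance level of the screen.
#' @return data frame, one row per dose x metric: summary columns of
#'   [summarize_metric()] plus `n_outliers`.
#' @export
table1_report <- function(metrics, grubbs = TRUE, alpha = 0.05) {
  cols <- c(q_up = "q_up", q_cl = "q_cl", flux = "flux",
            k_x100 = "k")
  out <- list()
  for (d in sort(unique(metrics$dose))) {
    sub <- metrics[metrics$dose == d, ]
    for (nm in names(cols)) {
      v <- sub[[cols[[nm]]]]
      if (nm == "k_x100") v <- 100 * v
      v <- v[!is.na(v)]
      n_out <- 0L
      if (grubbs && length(v) >= 3) {
        scr <- grubbs_screen(v, alpha)
        n_out <- length(scr$removed)
        v <- scr$kept
      }
      row <- summarize_metric(v)
      row$dose <- d; row$metric <- nm; row$n_outliers <- n_out
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)[, c("dose", "metric", "n", "mean", "sd",
                          "ci95_half", "ci_defined", "n_outliers")]
}
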