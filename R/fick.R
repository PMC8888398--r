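# Finite-membrane Fickian uptake with a constant-activity surface and a
# sink at the SC/viable-epidermis boundary, in the dimensionless depth
# coordinate x = z/L:
#
#   C(x, t) / (K C_v) = (1 - x) - sum_{n>=1} (2/(n pi)) sin(n pi x)
#                                  exp(-n^2 pi^2 (D/L^2) t)
#
# The slab integral over [a, b] (needed for per-strip drug masses) has
# the closed form
#
#   int_a^b C/(K C_v) dx = (b - a) - (b^2 - a^2)/2
#       - sum (2/(n^2 pi^2)) (cos(n pi a) - cos(n pi b)) exp(-n^2 pi^2 tau)
#
# Clearance is modelled as uniform first-order decay of the whole
# profile (a single multiplicative factor exp(-k dt)), matching the
# two-point elimination analysis so recovery tests have an exact truth.

# series terms are dropped once their magnitude bound 2/(n pi) exp(-n^2
# pi^2 tau) falls below `tol` (relative to K C_v); `n_terms` caps the sum
fick_series_n <- function(tau, n_terms, tol = 1e-12) {
  n <- seq_len(n_terms)
  bound <- (2 / (n * pi)) * exp(-n^2 * pi^2 * tau)
  keep <- which(bound >= tol)
  if (length(keep) == 0) 0L else max(keep)
}

fick_frac <- function(x, tau, n_terms = 500L, tol = 1e-12) {
  stopifnot(all(x >= 0 & x <= 1), tau >= 0)
  if (tau == 0) return(ifelse(x == 0, 1, 0))
  N <- fick_series_n(tau, n_terms, tol)
  out <- 1 - x
  if (N > 0) {
    n <- seq_len(N)
    En <- exp(-n^2 * pi^2 * tau)
    # outer() over strips x series terms; both are small here
    out <- out - as.numeric(sin(outer(x, n * pi)) %*% ((2 / (n * pi)) * En))
  }
  pmin(pmax(out, 0), 1)
}

fick_slab_frac <- function(a, b, tau, n_terms = 2000L, tol = 1e-15) {
  stopifnot(all(a >= 0), all(b <= 1 + 1e-12), all(b >= a), tau >= 0)
  b <- pmin(b, 1)
  if (tau == 0) return(rep(0, length(a)))
  base <- (b - a) - (b^2 - a^2) / 2
  n <- seq_len(n_terms)
  En <- exp(-n^2 * pi^2 * tau)
  keep <- (2 / (n^2 * pi^2)) * En >= tol
  if (any(keep)) {
    n <- n[keep]; En <- En[keep]
    coef <- (2 / (n^2 * pi^2)) * En
    ser <- as.numeric((cos(outer(a, n * pi)) - cos(outer(b, n * pi))) %*% coef)
    base <- base - ser
  }
  pmax(base, 0)
}

#' Fickian uptake concentration profile
#'
#' Concentration at fractional depth `x` after `t` hours of uptake into
#' an initially drug-free SC whose surface is held at the partitioned
#' vehicle concentration `partition_scale` (= K C_v) with a perfect sink
#' at the SC/viable-tissue boundary.
#'
#' @param x fractional depth in the SC, in \[0, 1\] (0 = surface).
#' @param t uptake time (h); must be `>= 0`.
#' @param params a [subject_params()] object (uses `partition_scale`,
#'   ng/cm^3, and `diffusivity_ratio` = D/L^2, 1/h).
#' @param n_terms maximum number of series terms; terms below a relative
#'   magnitude of 1e-12 are dropped.
#' @return concentration (ng/cm^3), in \[0, `partition_scale`\].
#' @export
uptake_profile <- function(x, t, params, n_terms = 500L) {
  stopifnot(inherits(params, "subject_params"))
  if (any(t < 0)) stop("`t` must be >= 0")
  params$partition_scale *
    fick_frac(x, params$diffusivity_ratio * t, n_terms)
}

# Internal profile state: everything needed to evaluate concentrations
# and slab integrals at the moment a site is stripped.  `decay` carries
# the first-order clearance factor (1 during uptake).
sc_sim_profile <- function(params, t_uptake, decay = 1) {
  structure(list(partition_scale = params$partition_scale,
                 tau = params$diffusivity_ratio * t_uptake,
                 L_um = params$sc_thickness, decay = decay),
            class = "sc_sim_profile")
}

#' First-order clearance of a simulated profile
#'
#' Scales every concentration in the profile by `exp(-k_true * elapsed)`,
#' so the total SC load Q scales identically — the exact generative
#' counterpart of the two-point elimination estimate.
#'
#' @param profile a profile produced by the generator (class
#'   `sc_sim_profile`).
#' @param elapsed hours since the end of uptake; `>= 0`.
#' @param k_true first-order elimination rate constant (1/h).
#' @return the decayed profile.
#' @export
clearance_profile <- function(profile, elapsed, k_true) {
  stopifnot(inherits(profile, "sc_sim_profile"), k_true >= 0)
  if (elapsed < 0) stop("`elapsed` must be >= 0")
  profile$decay <- profile$decay * exp(-k_true * elapsed)
  profile
}

# areal drug load (ng/cm^2) between two depths (um, from the surface)
profile_Q <- function(profile, from_um = 0, to_um = profile$L_um) {
  L_cm <- profile$L_um * 1e-4
  profile$decay * profile$partition_scale * L_cm *
    fick_slab_frac(from_um / profile$L_um, to_um / profile$L_um,
                   profile$tau)
}

profile_conc <- function(profile, x, n_terms = 500L) {
  profile$decay * profile$partition_scale * fick_frac(x, profile$tau,
                                                      n_terms)
}
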