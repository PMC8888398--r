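# In-code fixtures: no data files, everything built at test time.

# canonical single-site strip data: 20 tapes of 0.1225 mg over 5 cm^2
# (0.0245 mg/cm^2 each), groups [2, 6, 6, 6] with drug masses chosen to
# echo a Q of 55 ng/cm^2: {200, 50, 25, BLQ}
make_strip_data <- function(subject_id = "S01", site_id = "siteA",
                            drug = c(200, 50, 25, NA),
                            blq = c(FALSE, FALSE, FALSE, TRUE),
                            sc_mass_mg = rep(0.1225, 20),
                            area = 5) {
  grouping <- c(2L, 6L, 6L, 6L)
  ends <- cumsum(grouping)
  starts <- c(1L, head(ends, -1L) + 1L)
  gid <- sprintf("g%d", findInterval(1:20, starts))
  strips <- data.frame(subject_id = subject_id, site_id = site_id,
                       strip_index = 1:20, sc_mass_mg = sc_mass_mg,
                       area_cm2 = area, group_id = gid,
                       stringsAsFactors = FALSE)
  groups <- data.frame(subject_id = subject_id, site_id = site_id,
                       group_id = sprintf("g%d", 1:4),
                       strip_first = starts, strip_last = ends,
                       n_strips = grouping,
                       sc_mass_total_mg = vapply(1:4, function(g)
                         sum(sc_mass_mg[starts[g]:ends[g]]), numeric(1)),
                       area_cm2 = area, drug_mass_ng = drug, blq = blq,
                       stringsAsFactors = FALSE)
  structure(list(strips = strips, groups = groups), class = "strip_data")
}

# chromameter series for one treated site + 3 controls, built from
# per-time deltas; baseline rows have time_h = NA
make_chroma <- function(subject_id = "S01", site_id = "sb1",
                        times = c(2, 4, 6, 20, 22),
                        d_treated = rep(0, length(times)),
                        d_controls = matrix(0, 3, length(times)),
                        baselines = c(treated = 10, control1 = 10,
                                      control2 = 10, control3 = 10)) {
  roles <- names(baselines)
  rows <- do.call(rbind, lapply(seq_along(roles), function(i) {
    r <- roles[i]
    d <- if (r == "treated") d_treated else d_controls[i - 1, ]
    data.frame(subject_id = subject_id, site_id = site_id, role = r,
               time_h = c(NA, times),
               a_star = c(baselines[[r]], baselines[[r]] + d),
               stringsAsFactors = FALSE)
  }))
  structure(rows, class = c("chroma_data", "data.frame"))
}

# wrap assay_groups() output into a strip_data-style groups table
as_site_groups <- function(grp, subject_id = "S01", site_id = "siteA") {
  cbind(data.frame(subject_id = subject_id, site_id = site_id,
                   stringsAsFactors = FALSE),
        grp[, c("group_id", "strip_first", "strip_last", "n_strips",
                "sc_mass_total_mg", "area_cm2", "drug_mass_ng", "blq")])
}

default_params <- function(...) {
  args <- list(partition_scale = 3.1e5, diffusivity_ratio = 0.1,
               sc_thickness = 12, k_true = 0.065,
               strip_mass_mean = 0.0245)
  args[names(list(...))] <- list(...)
  do.call(subject_params, args)
}
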