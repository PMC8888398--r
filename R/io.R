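# Delimited-text I/O for the two study tables.
#
# Strip table: one row per tape (normalised long format); the pooled-group
# assay result (drug_mass_ng, blq_flag) is repeated on every row of its
# group so a single flat CSV is lossless for the two-level data.
# BLQ groups carry an empty drug_mass_ng and blq_flag = 1, never a 0:
# the numeric treatment of censored groups is an analysis-time policy.

STRIP_COLS <- c("subject_id", "site_id", "strip_index", "sc_mass_mg",
                "area_cm2", "group_id", "drug_mass_ng", "blq_flag")
CHROMA_COLS <- c("subject_id", "site_id", "role", "time_h", "a_star",
                 "replicate")
CONTROL_ROLES <- c("control1", "control2", "control3")

# full-precision numeric formatting so write -> read round-trips exactly
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

stop_row <- function(rows, msg) {
  # rows are data rows; +1 converts to file line numbers (header = line 1)
  stop(sprintf("%s (file line%s %s)", msg,
               if (length(rows) > 1) "s" else "",
               paste(rows + 1L, collapse = ", ")), call. = FALSE)
}

#' Read a tape-strip table
#'
#' Reads the flat CSV holding per-tape SC masses and the pooled-group
#' drug assay results, validates it, and splits it into per-tape records
#' and per-group assay records.
#'
#' The file has one row per tape with header columns `subject_id,
#' site_id, strip_index, sc_mass_mg, area_cm2, group_id, drug_mass_ng,
#' blq_flag`.  `drug_mass_ng` and `blq_flag` describe the pooled group a
#' tape belongs to and must be constant within a group; BLQ groups carry
#' an empty `drug_mass_ng` and `blq_flag = 1`.
#'
#' @param path path to a CSV file.
#' @return an object of class `strip_data`: a list with
#'   \describe{
#'     \item{strips}{one row per tape: `subject_id`, `site_id`,
#'       `strip_index`, `sc_mass_mg`, `area_cm2`, `group_id`.}
#'     \item{groups}{one row per pooled group: identifiers,
#'       `strip_first`, `strip_last`, `n_strips`, `sc_mass_total_mg`,
#'       `area_cm2`, `drug_mass_ng` (`NA` when censored), `blq`.}
#'   }
#' @seealso [write_strip_table()]
#' @export
read_strip_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "#")
  missing <- setdiff(STRIP_COLS, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- nrow(df)
  num <- function(col) suppressWarnings(as.numeric(df[[col]]))
  strip_index <- num("strip_index")
  sc_mass <- num("sc_mass_mg")
  area <- num("area_cm2")
  drug <- num("drug_mass_ng")
  blq <- num("blq_flag")

  bad <- which(is.na(strip_index) | strip_index < 1 |
                 strip_index != round(strip_index))
  if (length(bad)) stop_row(bad, "strip_index must be a positive integer")
  bad <- which(is.na(sc_mass) | sc_mass < 0)
  if (length(bad)) stop_row(bad, "sc_mass_mg must be a number >= 0")
  bad <- which(is.na(area) | area <= 0)
  if (length(bad)) stop_row(bad, "area_cm2 must be a number > 0")
  bad <- which(is.na(blq) | !(blq %in% c(0, 1)))
  if (length(bad)) stop_row(bad, "blq_flag must be 0 or 1")
  bad <- which(blq == 1 & nzchar(trimws(df$drug_mass_ng)))
  if (length(bad))
    stop_row(bad, "BLQ rows must leave drug_mass_ng empty")
  bad <- which(blq == 0 & (is.na(drug) | drug < 0))
  if (length(bad))
    stop_row(bad, "drug_mass_ng must be a number >= 0 unless blq_flag = 1")

  strips <- data.frame(subject_id = df$subject_id, site_id = df$site_id,
                       strip_index = as.integer(strip_index),
                       sc_mass_mg = sc_mass, area_cm2 = area,
                       group_id = df$group_id,
                       stringsAsFactors = FALSE)

  # per-site: indices consecutive from 1
  for (site in split(seq_len(n), paste(df$subject_id, df$site_id))) {
    idx <- sort(strip_index[site])
    if (!identical(idx, as.numeric(seq_along(idx))))
      stop_row(site[1],
               "strip_index must be consecutive from 1 within a site")
  }

  key <- paste(df$subject_id, df$site_id, df$group_id, sep = "\r")
  groups <- do.call(rbind, lapply(split(seq_len(n), key), function(i) {
    si <- sort(strip_index[i])
    if (!all(diff(si) == 1))
      stop_row(i[1], "strips within a group must be contiguous")
    if (length(unique(df$drug_mass_ng[i])) > 1 ||
        length(unique(blq[i])) > 1)
      stop_row(i[1], "group assay columns must be constant within a group")
    data.frame(subject_id = df$subject_id[i[1]],
               site_id = df$site_id[i[1]],
               group_id = df$group_id[i[1]],
               strip_first = as.integer(min(si)),
               strip_last = as.integer(max(si)),
               n_strips = length(si),
               sc_mass_total_mg = sum(sc_mass[i]),
               area_cm2 = area[i[1]],
               drug_mass_ng = if (blq[i[1]] == 1) NA_real_ else drug[i[1]],
               blq = blq[i[1]] == 1,
               stringsAsFactors = FALSE)
  }))
  groups <- groups[order(groups$subject_id, groups$site_id,
                         groups$strip_first), ]
  rownames(groups) <- NULL
  structure(list(strips = strips, groups = groups), class = "strip_data")
}

#' Write a tape-strip table
#'
#' Inverse of [read_strip_table()]: flattens a `strip_data` object back
#' to the one-row-per-tape CSV schema at full numeric precision, so that
#' a write/read cycle reproduces the values exactly.
#'
#' @param x a `strip_data` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_strip_table <- function(x, path) {
  stopifnot(inherits(x, "strip_data"))
  s <- x$strips
  g <- x$groups
  gi <- match(paste(s$subject_id, s$site_id, s$group_id, sep = "\r"),
              paste(g$subject_id, g$site_id, g$group_id, sep = "\r"))
  if (anyNA(gi)) stop("strip rows reference unknown groups")
  out <- data.frame(subject_id = s$subject_id, site_id = s$site_id,
                    strip_index = s$strip_index,
                    sc_mass_mg = fmt_num(s$sc_mass_mg),
                    area_cm2 = fmt_num(s$area_cm2),
                    group_id = s$group_id,
                    drug_mass_ng = fmt_num(g$drug_mass_ng[gi]),
                    blq_flag = as.integer(g$blq[gi]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$site_id, out$strip_index), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chromameter table
#'
#' Reads chromameter a* readings for treated and control sites.  Columns:
#' `subject_id, site_id, role, time_h, a_star, replicate`.  `role` is one
#' of `treated, control1, control2, control3`; `time_h` is hours after
#' formulation removal, with the sentinel `"pre"` marking the
#' pre-application baseline.  Duplicate replicates at one (site, role,
#' time) are averaged on ingest.
#'
#' @param path path to a CSV file.
#' @return an object of class `chroma_data`: a data frame with columns
#'   `subject_id, site_id, role, time_h, a_star`, one averaged value per
#'   (site, role, time); baseline rows have `time_h = NA`.
#' @export
read_chromameter_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "#")
  missing <- setdiff(CHROMA_COLS, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  roles <- c("treated", CONTROL_ROLES)
  bad <- which(!(df$role %in% roles))
  if (length(bad)) stop_row(bad, "unknown role")
  a_star <- suppressWarnings(as.numeric(df$a_star))
  bad <- which(is.na(a_star))
  if (length(bad)) stop_row(bad, "a_star must be numeric")
  is_pre <- trimws(df$time_h) == "pre"
  time_h <- suppressWarnings(as.numeric(df$time_h))
  time_h[is_pre] <- NA_real_
  bad <- which(!is_pre & (is.na(time_h) | time_h < 0))
  if (length(bad)) stop_row(bad, "time_h must be \"pre\" or a number >= 0")

  key <- paste(df$subject_id, df$site_id, df$role, df$time_h, sep = "\r")
  first <- !duplicated(key)
  avg <- tapply(a_star, key, mean)
  out <- data.frame(subject_id = df$subject_id[first],
                    site_id = df$site_id[first],
                    role = df$role[first],
                    time_h = time_h[first],
                    a_star = as.numeric(avg[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$site_id, out$role,
                   !is.na(out$time_h), out$time_h), ]
  rownames(out) <- NULL

  # every (site, role) needs a baseline; every treated site needs 3 controls
  for (i in split(seq_len(nrow(out)),
                  paste(out$subject_id, out$site_id, sep = "\r"))) {
    here <- out[i, ]
    site <- sprintf("subject %s site %s", here$subject_id[1],
                    here$site_id[1])
    have <- unique(here$role)
    if (length(setdiff(CONTROL_ROLES, have)))
      stop(site, ": fewer than 3 control roles (missing ",
           paste(setdiff(CONTROL_ROLES, have), collapse = ", "), ")",
           call. = FALSE)
    for (r in intersect(roles, have))
      if (!any(here$role == r & is.na(here$time_h)))
        stop(site, ": missing baseline (time_h = \"pre\") for role ", r,
             call. = FALSE)
  }
  structure(out, class = c("chroma_data", "data.frame"))
}

#' Write a chromameter table
#'
#' Inverse of [read_chromameter_table()].  Accepts either an averaged
#' `chroma_data` object (written with `replicate = 1`) or a raw data
#' frame that already carries a `replicate` column (e.g. duplicate
#' readings from [simulate_study()]), written as-is.
#'
#' @param x a `chroma_data` object or raw data frame with the CSV schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chromameter_table <- function(x, path) {
  df <- as.data.frame(x)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  time_chr <- ifelse(is.na(df$time_h), "pre", fmt_num(df$time_h))
  out <- data.frame(subject_id = df$subject_id, site_id = df$site_id,
                    role = df$role, time_h = time_chr,
                    a_star = fmt_num(df$a_star),
                    replicate = df$replicate, stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$site_id, out$role,
                   out$time_h != "pre",
                   suppressWarnings(as.numeric(out$time_h)),
                   out$replicate), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
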