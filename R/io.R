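# Profile readers and writers. A profile on disk is a directory of UTF-8
# tab-separated tables plus a small YAML config:
#   profile.yml          name, mode, nmr0, u5mr0
#   demography.tsv       year, live_births
#   causes.tsv           age_band, cause, fraction
#   interventions.tsv    id, name, period, age_bands (';'-joined),
#                        effectiveness, herd_threshold, herd_max_boost
#   affected_fractions.tsv  intervention_id, cause, affected_fraction
#   coverage.tsv         intervention_id, year, coverage (percent)
#   risk_factors.tsv     name, cause, relative_risk          (optional)
#   risk_prevalence.tsv  name, year, prevalence (percent)    (optional)
#   risk_links.tsv       name, intervention_id, efficacy     (optional)
# Numbers are written with 17 significant digits so a write/load round trip
# reproduces every numeric field exactly.

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

write_tsv <- function(df, path) {
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) vapply(seq_len(nrow(df)), function(i) {
               paste(vapply(df[i, , drop = FALSE], function(v) {
                 if (is.numeric(v)) fmt_num(v) else ifelse(is.na(v), "NA", as.character(v))
               }, character(1)), collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
}

read_tsv <- function(path, required = TRUE) {
  if (!file.exists(path)) {
    if (required) stop("load_profile: missing file '", path, "'")
    return(NULL)
  }
  utils::read.delim(path, sep = "\t", quote = "", na.strings = "NA",
                    stringsAsFactors = FALSE)
}

#' Write a country profile to a directory of delimited tables
#'
#' The layout is diff-able and spreadsheet-editable; see
#' [load_profile()] for the inverse. `load_profile(write_profile(p))`
#' reproduces `p` exactly, including `NA` herd cells.
#'
#' @param profile A validated `country_profile`.
#' @param path Directory to create/overwrite files in.
#' @return Invisibly, the vector of files written.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("write_profile: cannot create directory '", path, "'")

  yaml::write_yaml(
    list(name = profile$name, mode = profile$mode,
         nmr0 = profile$demography$nmr0, u5mr0 = profile$demography$u5mr0),
    file.path(path, "profile.yml"), precision = 17)

  write_tsv(data.frame(year = profile$demography$years,
                       live_births = as.numeric(profile$demography$live_births)),
            file.path(path, "demography.tsv"))

  causes <- do.call(rbind, lapply(AGE_BANDS, function(b) {
    data.frame(age_band = b, cause = names(profile$cod[[b]]),
               fraction = as.numeric(profile$cod[[b]]), stringsAsFactors = FALSE)
  }))
  write_tsv(causes, file.path(path, "causes.tsv"))

  ivs <- do.call(rbind, lapply(profile$interventions, function(iv) {
    data.frame(id = iv$id, name = iv$name, period = iv$period,
               age_bands = paste(iv$age_bands, collapse = ";"),
               effectiveness = iv$effectiveness,
               herd_threshold = if (is.null(iv$herd)) NA_real_ else iv$herd$threshold,
               herd_max_boost = if (is.null(iv$herd)) NA_real_ else iv$herd$max_boost,
               stringsAsFactors = FALSE)
  }))
  write_tsv(ivs, file.path(path, "interventions.tsv"))

  afs <- do.call(rbind, lapply(profile$interventions, function(iv) {
    data.frame(intervention_id = iv$id, cause = names(iv$affected_fractions),
               affected_fraction = as.numeric(iv$affected_fractions),
               stringsAsFactors = FALSE)
  }))
  write_tsv(afs, file.path(path, "affected_fractions.tsv"))

  cov <- do.call(rbind, lapply(profile$coverages, function(s) {
    data.frame(intervention_id = s$intervention_id,
               year = as.integer(names(s$anchors)),
               coverage = as.numeric(s$anchors), stringsAsFactors = FALSE)
  }))
  write_tsv(cov, file.path(path, "coverage.tsv"))

  files <- c("profile.yml", "demography.tsv", "causes.tsv",
             "interventions.tsv", "affected_fractions.tsv", "coverage.tsv")
  if (length(profile$risk_factors)) {
    rrs <- do.call(rbind, lapply(profile$risk_factors, function(rf) {
      data.frame(name = rf$name, cause = names(rf$relative_risks),
                 relative_risk = as.numeric(rf$relative_risks),
                 stringsAsFactors = FALSE)
    }))
    prevs <- do.call(rbind, lapply(profile$risk_factors, function(rf) {
      data.frame(name = rf$name, year = as.integer(names(rf$prevalence_anchors)),
                 prevalence = as.numeric(rf$prevalence_anchors),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(rrs, file.path(path, "risk_factors.tsv"))
    write_tsv(prevs, file.path(path, "risk_prevalence.tsv"))
    files <- c(files, "risk_factors.tsv", "risk_prevalence.tsv")
    links <- do.call(rbind, lapply(profile$risk_factors, function(rf) {
      if (is.null(rf$linked_interventions)) return(NULL)
      data.frame(name = rf$name,
                 intervention_id = names(rf$linked_interventions),
                 efficacy = as.numeric(rf$linked_interventions),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(links) && nrow(links)) {
      write_tsv(links, file.path(path, "risk_links.tsv"))
      files <- c(files, "risk_links.tsv")
    }
  }
  invisible(file.path(path, files))
}

#' Load a country profile from a directory of delimited tables
#'
#' Reads the layout written by [write_profile()] and rebuilds a fully
#' validated `country_profile`; any violated invariant (coverage outside
#' \[0,100\], fractions not summing to 1, a coverage series referencing an
#' unknown intervention id, ...) raises a validation error naming the field
#' and row.
#'
#' @param path Profile directory, or the path of its `profile.yml`
#'   (`format = "config"`).
#' @param format `"tables"` (a directory) or `"config"` (the YAML file).
#' @return A validated `country_profile`.
#' @export
load_profile <- function(path, format = c("tables", "config")) {
  format <- match.arg(format)
  dir <- if (format == "config") dirname(path) else path
  if (!dir.exists(dir)) stop("load_profile: no such directory '", dir, "'")
  cfg_path <- file.path(dir, "profile.yml")
  if (!file.exists(cfg_path)) stop("load_profile: missing file '", cfg_path, "'")
  cfg <- yaml::read_yaml(cfg_path)

  dem_df <- read_tsv(file.path(dir, "demography.tsv"))
  dem <- demography(stats::setNames(dem_df$live_births, dem_df$year),
                    nmr0 = cfg$nmr0, u5mr0 = cfg$u5mr0)

  causes <- read_tsv(file.path(dir, "causes.tsv"))
  get_band <- function(b) {
    d <- causes[causes$age_band == b, ]
    stats::setNames(d$fraction, d$cause)
  }
  cod <- cause_profile(get_band(AGE_BANDS[1]), get_band(AGE_BANDS[2]))

  ivs_df <- read_tsv(file.path(dir, "interventions.tsv"))
  afs_df <- read_tsv(file.path(dir, "affected_fractions.tsv"))
  interventions <- lapply(seq_len(nrow(ivs_df)), function(i) {
    r <- ivs_df[i, ]
    af <- afs_df[afs_df$intervention_id == r$id, ]
    intervention(
      id = r$id, name = r$name, period = r$period,
      age_bands = strsplit(r$age_bands, ";", fixed = TRUE)[[1]],
      effectiveness = r$effectiveness,
      affected_fractions = stats::setNames(af$affected_fraction, af$cause),
      herd = if (is.na(r$herd_threshold)) NULL else
        herd_spec(r$herd_threshold, r$herd_max_boost))
  })

  cov_df <- read_tsv(file.path(dir, "coverage.tsv"))
  coverages <- lapply(split(cov_df, cov_df$intervention_id), function(d) {
    coverage_series(d$intervention_id[1], stats::setNames(d$coverage, d$year))
  })
  # Preserve the interventions' order where possible.
  ord <- order(match(vapply(coverages, `[[`, "", "intervention_id"), ivs_df$id))
  coverages <- unname(coverages[ord])

  risk_factors <- list()
  rr_df <- read_tsv(file.path(dir, "risk_factors.tsv"), required = FALSE)
  if (!is.null(rr_df)) {
    prev_df <- read_tsv(file.path(dir, "risk_prevalence.tsv"))
    links_df <- read_tsv(file.path(dir, "risk_links.tsv"), required = FALSE)
    risk_factors <- lapply(unique(rr_df$name), function(nm) {
      rr <- rr_df[rr_df$name == nm, ]
      pv <- prev_df[prev_df$name == nm, ]
      lk <- if (is.null(links_df)) NULL else links_df[links_df$name == nm, ]
      risk_factor(
        name = nm,
        prevalence_anchors = stats::setNames(pv$prevalence, pv$year),
        relative_risks = stats::setNames(rr$relative_risk, rr$cause),
        linked_interventions = if (is.null(lk) || !nrow(lk)) NULL else
          stats::setNames(lk$efficacy, lk$intervention_id))
    })
  }

  country_profile(name = cfg$name, demography = dem, cod = cod,
                  interventions = interventions, coverages = coverages,
                  risk_factors = risk_factors, mode = cfg$mode)
}
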