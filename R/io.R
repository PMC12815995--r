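# File schemas: station-level growth CSV, Cobb and pressure CSVs, region
# scheme and scenario YAML, JSON summaries. Deterministic column order,
# UTF-8, '.' decimal. kPa and degrees at the I/O boundary.

growth_csv_columns <- c("animal_id", "cohort", "level", "physis", "x_mm",
                        "label_distance_mm", "growth_rate_um_day",
                        "interval_days", "ap_width_mm")

#' Write a cohort's station-level growth table to CSV
#'
#' One row per station with columns `animal_id`, `cohort`, `level`, `physis`,
#' `x_mm`, `label_distance_mm`, `growth_rate_um_day`, `interval_days`,
#' `ap_width_mm`.
#'
#' @param cohort A `vg_cohort` (or list of `animal_record`).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_growth_csv <- function(cohort, path) {
  animals <- if (inherits(cohort, "vg_cohort")) cohort$animals else cohort
  rows <- lapply(animals, function(an) {
    do.call(rbind, lapply(an$physes, function(ph) {
      data.frame(animal_id = an$id, cohort = an$cohort,
                 level = ph$level, physis = ph$physis,
                 x_mm = ph$positions,
                 label_distance_mm = ph$label_distance,
                 growth_rate_um_day = ph$growth_rate,
                 interval_days = ph$interval_days,
                 ap_width_mm = ph$ap_width_mm)
    }))
  })
  df <- do.call(rbind, rows)[, growth_csv_columns]
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a station-level growth CSV
#'
#' Validates the schema and rejects malformed rows with their line numbers.
#'
#' @param path CSV path as written by [write_growth_csv()].
#' @return data.frame with the growth CSV columns.
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("growth CSV not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop(sprintf("growth CSV is empty: %s", path))
  missing_cols <- setdiff(growth_csv_columns, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("growth CSV missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  num <- c("x_mm", "label_distance_mm", "growth_rate_um_day", "interval_days",
           "ap_width_mm")
  non_num <- num[!vapply(df[num], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    stop(sprintf("non-numeric value(s) in column(s): %s",
                 paste(non_num, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[num]))
  if (length(bad) > 0) {
    stop(sprintf("malformed growth CSV row(s) at line(s): %s",
                 paste(bad + 1L, collapse = ", ")))
  }
  df
}

#' Rebuild physis profiles from a growth CSV table
#'
#' @param df data.frame from [read_growth_csv()].
#' @return Nested list: per animal, a list with `id`, `cohort` and `physes`
#'   (list of [physis_profile()]).
#' @export
profiles_from_growth_df <- function(df) {
  lapply(split(df, df$animal_id), function(dfa) {
    keys <- interaction(dfa$level, dfa$physis, drop = TRUE)
    physes <- lapply(split(dfa, keys), function(dfp) {
      dfp <- dfp[order(dfp$x_mm), ]
      physis_profile(dfp$x_mm,
                     growth_rate_from_labels(dfp$label_distance_mm,
                                             dfp$interval_days[1]),
                     interval_days = dfp$interval_days[1],
                     ap_width_mm = dfp$ap_width_mm[1],
                     physis = dfp$physis[1], level = dfp$level[1])
    })
    list(id = dfa$animal_id[1], cohort = dfa$cohort[1], physes = unname(physes))
  })
}

#' Write / read serial Cobb angles
#'
#' Columns: `animal_id`, `day`, `cobb_deg`.
#' @param cohort A `vg_cohort`.
#' @param path CSV path.
#' @return The path (writer) or a data.frame (reader).
#' @export
write_cobb_csv <- function(cohort, path) {
  animals <- if (inherits(cohort, "vg_cohort")) cohort$animals else cohort
  df <- do.call(rbind, lapply(animals, function(an) {
    cbind(animal_id = an$id, an$cobb_series)
  }))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cobb_csv
#' @export
read_cobb_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("animal_id", "day", "cobb_deg") %in% names(df)))
  df
}

#' Write / read disc pressures (kPa)
#'
#' Columns: `animal_id`, `disc`, `kpa`.
#' @inheritParams write_cobb_csv
#' @export
write_pressures_csv <- function(cohort, path) {
  animals <- if (inherits(cohort, "vg_cohort")) cohort$animals else cohort
  df <- do.call(rbind, lapply(animals, function(an) {
    cbind(animal_id = an$id, an$pressures)
  }))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pressures_csv
#' @export
read_pressures_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("animal_id", "disc", "kpa") %in% names(df)))
  df
}

#' Region scheme from a name or a YAML file
#'
#' YAML schema: `boundaries` (fractions) and `labels` (one more than the
#' boundaries).
#'
#' @param x "quarters", "halves", "thirds", "fourths", or a YAML path.
#' @return A [region_scheme()].
#' @export
read_region_scheme <- function(x) {
  if (x %in% c("quarters", "halves", "thirds", "fourths")) {
    return(switch(x, quarters = scheme_quarters(), halves = scheme_halves(),
                  thirds = scheme_thirds(), fourths = scheme_fourths()))
  }
  if (!file.exists(x)) stop(sprintf("unknown scheme '%s' (not a preset or file)", x))
  y <- yaml::read_yaml(x)
  extra <- setdiff(names(y), c("boundaries", "labels"))
  if (length(extra) > 0) {
    stop(sprintf("unknown key(s) in scheme YAML: %s", paste(extra, collapse = ", ")))
  }
  region_scheme(unlist(y$boundaries), unlist(y$labels))
}

# ---- analysis over the CSV schema ----

#' Percent growth modulation analysis of a growth table
#'
#' Computes per-physis regional rates and percent growth modulation, averages
#' physes within animal, and summarizes the cohort as the mean of per-animal
#' values (cohort %GM is the mean of per-animal ratios, not the ratio of
#' cohort means).
#'
#' @param x A growth CSV path, a growth data.frame, or a `vg_cohort`.
#' @param scheme A [region_scheme()] or preset name.
#' @return List of data.frames: `per_physis`, `per_animal`, `cohort`.
#' @export
analyze_growth <- function(x, scheme = scheme_quarters()) {
  if (is.character(scheme)) scheme <- read_region_scheme(scheme)
  animals <- if (inherits(x, "vg_cohort")) {
    lapply(x$animals, function(an) list(id = an$id, cohort = an$cohort,
                                        physes = an$physes))
  } else {
    df <- if (is.character(x)) read_growth_csv(x) else x
    profiles_from_growth_df(df)
  }
  per_physis <- do.call(rbind, lapply(animals, function(an) {
    do.call(rbind, lapply(an$physes, function(ph) {
      gm <- growth_modulation_profile(ph, scheme)
      data.frame(animal_id = an$id, cohort = an$cohort, level = ph$level,
                 physis = ph$physis, anterior_rate = gm$anterior_rate,
                 posterior_rate = gm$posterior_rate,
                 mean_rate = gm$total_mean_rate, gm_percent = gm$gm_percent)
    }))
  }))
  per_animal <- do.call(rbind, lapply(split(per_physis, per_physis$animal_id),
                                      function(d) {
    data.frame(animal_id = d$animal_id[1], cohort = d$cohort[1],
               n_physes = nrow(d), mean_rate = mean(d$mean_rate),
               gm_percent = mean(d$gm_percent))
  }))
  rownames(per_animal) <- NULL
  cohort <- do.call(rbind, lapply(split(per_animal, per_animal$cohort),
                                  function(d) {
    data.frame(cohort = d$cohort[1], n_animals = nrow(d),
               mean_rate = mean(d$mean_rate), sd_rate = sd(d$mean_rate),
               gm_mean = mean(d$gm_percent), gm_sd = sd(d$gm_percent))
  }))
  rownames(cohort) <- NULL
  list(per_physis = per_physis, per_animal = per_animal, cohort = cohort)
}

# ---- manifest ----

# Polynomial content hash (plumbing: stable across platforms, no external deps).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in as.integer(charToRaw(s))) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a run manifest
#'
#' Every command run emits a manifest recording the command, a hash of its
#' configuration, the seed, the package version, the output paths and a
#' timestamp, so deterministic runs can be audited.
#'
#' @param command Command name.
#' @param config Configuration object (hashed).
#' @param seed Seed used (may be NULL).
#' @param outputs Character vector of output paths.
#' @param dir Directory where `manifest.json` is written.
#' @return Path to the manifest, invisibly.
#' @export
run_manifest <- function(command, config, seed, outputs, dir) {
  manifest <- list(command = command,
                   config_hash = config_hash(config),
                   seed = seed,
                   package_version = as.character(packageVersion("vertegrow")),
                   outputs = as.character(outputs),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
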