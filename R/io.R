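# Study CSV schema (versioned), readers/writers, and results-table output.
#
# One file holds both record kinds, linked by animal id:
#   row_type == "animal": id, genotype, sex, time_min, serum_tracer_cpm,
#                         serum_marker_cpm, aliquot_ul
#   row_type == "region": id, region, weight_g, tracer_cpm, marker_cpm
# The first line is a version header comment ("# patlakr study_csv v1").

.STUDY_SCHEMA <- "patlakr study_csv v1"
.STUDY_COLS <- c("row_type", "id", "genotype", "sex", "time_min",
                 "serum_tracer_cpm", "serum_marker_cpm", "aliquot_ul",
                 "region", "weight_g", "tracer_cpm", "marker_cpm")

# full-precision numeric formatting so write -> read round-trips exactly
.fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a study dataset to CSV
#'
#' Serialises the study to the versioned CSV schema at full floating-point
#' precision (the file round-trips bit-identically through [read_study()]).
#' When the dataset came from [simulate_study()], an optional ground-truth
#' sidecar (JSON) records the configured kinetic parameters, clearance rates
#' and seed for test harnesses.
#'
#' @param dataset a `study_dataset`.
#' @param path output CSV path.
#' @param truth_path optional path for the ground-truth sidecar; `NULL`
#'   (default) writes none.
#' @return `path`, invisibly.
#' @export
write_study <- function(dataset, path, truth_path = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  s <- dataset$serum; r <- dataset$regions
  blank <- rep(NA_character_, nrow(s))
  arows <- data.frame(
    row_type = "animal", id = s$id, genotype = s$genotype, sex = s$sex,
    time_min = .fmt_full(s$time_min),
    serum_tracer_cpm = .fmt_full(s$serum_tracer_cpm),
    serum_marker_cpm = .fmt_full(s$serum_marker_cpm),
    aliquot_ul = .fmt_full(s$aliquot_ul),
    region = blank, weight_g = blank, tracer_cpm = blank, marker_cpm = blank,
    stringsAsFactors = FALSE
  )
  blankr <- rep(NA_character_, nrow(r))
  rrows <- data.frame(
    row_type = "region", id = r$id, genotype = blankr, sex = blankr,
    time_min = blankr, serum_tracer_cpm = blankr, serum_marker_cpm = blankr,
    aliquot_ul = blankr,
    region = r$region, weight_g = .fmt_full(r$weight_g),
    tracer_cpm = .fmt_full(r$tracer_cpm), marker_cpm = .fmt_full(r$marker_cpm),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .STUDY_SCHEMA), con)
  write.csv(rbind(arows, rrows), con, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    cfg <- dataset$config
    truth <- list(
      schema = "patlakr truth v1",
      seed = cfg$seed, noise_model = cfg$noise_model, dose_cv = cfg$dose_cv,
      c0_tracer = cfg$c0_tracer, c0_marker = cfg$c0_marker,
      k_clear_tracer = as.list(cfg$k_clear_tracer),
      k_clear_marker = as.list(cfg$k_clear_marker),
      ki_true = apply(cfg$ki_true, 2, as.list),
      vi_true = apply(cfg$vi_true, 2, as.list),
      vv_true = apply(cfg$vv_true, 2, as.list),
      region_weights = cfg$region_weights
    )
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a study dataset from CSV
#'
#' Parses and validates the versioned study CSV written by [write_study()]
#' (or assembled by hand to the same schema). All schema violations —
#' unknown region names, orphan region rows, duplicate keys, negative
#' counts, missing animal fields — are collected and reported together,
#' each with the offending file row number.
#'
#' @param path CSV path.
#' @param canonical_regions vector of allowed region names; default the
#'   canonical vocabulary [brain_regions()] plus `"Whole Brain"`. Use `NULL`
#'   to skip the vocabulary check.
#' @return a `study_dataset` (without simulation config/ground truth).
#' @export
read_study <- function(path,
                       canonical_regions = brain_regions(include_whole_brain = TRUE)) {
  if (!file.exists(path)) stop("study file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (!length(first) || !startsWith(first, "#"))
    stop("not a study CSV: missing schema header in ", path, call. = FALSE)
  version <- trimws(sub("^#", "", first))
  if (version != .STUDY_SCHEMA)
    stop("unrecognised study schema version: '", version, "'", call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 colClasses = "character")
  if (!nrow(df)) stop("no animals in study file: ", path, call. = FALSE)
  missing_cols <- setdiff(.STUDY_COLS, names(df))
  if (length(missing_cols))
    stop("study file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  # file row = data row index + 2 (header comment + column names)
  rowno <- seq_len(nrow(df)) + 2L
  problems <- character()
  add <- function(msg, rows) {
    problems <<- c(problems, paste0(msg, " (row ", paste(rows, collapse = ", "), ")"))
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  bad_type <- !(df$row_type %in% c("animal", "region"))
  if (any(bad_type)) add("unknown row_type", rowno[bad_type])

  ai <- df$row_type == "animal"
  ri <- df$row_type == "region"
  if (!any(ai)) stop("no animals in study file: ", path, call. = FALSE)

  serum <- data.frame(
    id = df$id[ai], genotype = df$genotype[ai], sex = df$sex[ai],
    time_min = num(df$time_min[ai]),
    serum_tracer_cpm = num(df$serum_tracer_cpm[ai]),
    serum_marker_cpm = num(df$serum_marker_cpm[ai]),
    aliquot_ul = num(df$aliquot_ul[ai]),
    stringsAsFactors = FALSE
  )
  regions <- data.frame(
    id = df$id[ri], region = df$region[ri],
    weight_g = num(df$weight_g[ri]),
    tracer_cpm = num(df$tracer_cpm[ri]),
    marker_cpm = num(df$marker_cpm[ri]),
    stringsAsFactors = FALSE
  )

  arow <- rowno[ai]; rrow <- rowno[ri]
  if (anyNA(serum$time_min) || anyNA(serum$serum_tracer_cpm) ||
      anyNA(serum$serum_marker_cpm) || anyNA(serum$aliquot_ul)) {
    bad <- !complete.cases(serum[c("time_min", "serum_tracer_cpm",
                                   "serum_marker_cpm", "aliquot_ul")])
    add("animal row with missing/non-numeric fields", arow[bad])
  }
  if (anyNA(regions$weight_g) || anyNA(regions$tracer_cpm) ||
      anyNA(regions$marker_cpm)) {
    bad <- !complete.cases(regions[c("weight_g", "tracer_cpm", "marker_cpm")])
    add("region row with missing/non-numeric fields", rrow[bad])
  }
  dupa <- duplicated(serum$id)
  if (any(dupa)) add("duplicate animal id", arow[dupa])
  orphan <- !(regions$id %in% serum$id)
  if (any(orphan)) add("region row for unknown animal id", rrow[orphan])
  dupr <- duplicated(regions[c("id", "region")])
  if (any(dupr)) add("duplicate (id, region)", rrow[dupr])
  if (!is.null(canonical_regions)) {
    badreg <- !(regions$region %in% canonical_regions)
    if (any(badreg)) {
      add(paste0("unknown region name '",
                 paste(unique(regions$region[badreg]), collapse = "', '"), "'"),
          rrow[badreg])
    }
  }
  negs <- with(serum, serum_tracer_cpm < 0 | serum_marker_cpm < 0)
  if (any(negs, na.rm = TRUE)) add("negative serum counts", arow[which(negs)])
  negr <- with(regions, tracer_cpm < 0 | marker_cpm < 0)
  if (any(negr, na.rm = TRUE)) add("negative brain counts", rrow[which(negr)])
  badw <- !is.na(regions$weight_g) & regions$weight_g <= 0
  if (any(badw)) add("non-positive region weight", rrow[badw])
  badt <- !is.na(serum$time_min) & serum$time_min <= 0
  if (any(badt)) add("non-positive terminal time", arow[badt])

  if (length(problems))
    stop("invalid study file ", path, ":\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)

  rownames(serum) <- NULL
  rownames(regions) <- NULL
  structure(
    list(serum = serum, regions = regions, config = NULL,
         provenance = list(source = path, schema = version)),
    class = "study_dataset"
  )
}

# 6-significant-digit copy of a results table for human-readable CSVs.
.round_sig <- function(df, digits = 6) {
  for (col in names(df)) if (is.numeric(df[[col]])) df[[col]] <- signif(df[[col]], digits)
  df
}

#' Write analysis results to a directory
#'
#' Emits the tidy result tables of a [run_pipeline()] bundle as CSVs
#' (vascular_space.csv, whole_brain_pk.csv, regional_ki.csv, regional_vi.csv,
#' clearance.csv, patlak_points.csv) at 6 significant digits, a
#' full-precision machine-readable sidecar (results.json), and the run log
#' (log.txt).
#'
#' @param results a `bbb_results` bundle.
#' @param dir output directory (created if needed).
#' @param log_lines extra lines prepended to the log file.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir, log_lines = character()) {
  stopifnot(inherits(results, "bbb_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    vascular_space = as.data.frame(results$vascular_space),
    whole_brain_pk = results$whole_brain_pk,
    regional_ki = results$regional_ki,
    regional_vi = results$regional_vi,
    clearance = results$clearance,
    patlak_points = results$points
  )
  for (nm in names(tables)) {
    write.csv(.round_sig(tables[[nm]]), file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE, na = "")
  }
  jsonlite::write_json(
    c(tables, list(settings = results$settings[
      !vapply(results$settings, is.null, logical(1))])),
    file.path(dir, "results.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  writeLines(c(log_lines, results$log), file.path(dir, "log.txt"))
  invisible(dir)
}
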