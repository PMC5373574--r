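# CSV dialect: UTF-8, comma-separated, header row, '.' decimal. Files using
# the European convention (';' separator, ',' decimal) are normalized on
# ingest. Malformed rows and non-numeric cells raise line-numbered errors.

read_numeric_csv <- function(file, numeric_cols = NULL,
                             non_numeric_cols = NULL) {
  lines <- readLines(file, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", file)
  sep <- if (grepl(";", lines[1], fixed = TRUE)) ";" else ","
  dec <- if (sep == ";") "," else "."
  fields <- strsplit(lines, sep, fixed = TRUE)
  ncol <- length(fields[[1]])
  bad <- which(vapply(fields, length, integer(1)) != ncol)
  if (length(bad))
    stop(sprintf("malformed CSV %s: expected %d fields but found %d on line %d",
                 file, ncol, length(fields[[bad[1]]]), bad[1]))
  header <- fields[[1]]
  if (any(header == "")) stop("malformed header in ", file)
  body <- fields[-1]
  df <- as.data.frame(
    stats::setNames(lapply(seq_len(ncol), function(j)
      vapply(body, `[[`, character(1), j)), header),
    stringsAsFactors = FALSE)
  if (is.null(numeric_cols) && !is.null(non_numeric_cols)) {
    numeric_cols <- setdiff(names(df), non_numeric_cols)
  } else if (is.null(numeric_cols)) {
    looks_numeric <- function(x) {
      x2 <- gsub(",", ".", trimws(x), fixed = TRUE)
      ok <- x2 == "" | x2 == "NA" | !is.na(suppressWarnings(as.numeric(x2)))
      all(ok) && any(x2 != "" & x2 != "NA")
    }
    numeric_cols <- names(df)[vapply(df, looks_numeric, logical(1))]
  }
  for (nm in intersect(numeric_cols, names(df))) {
    x2 <- gsub(",", ".", trimws(df[[nm]]), fixed = TRUE)
    x2[x2 == ""] <- NA
    conv <- suppressWarnings(as.numeric(x2))
    bad_cell <- which(is.na(conv) & !is.na(x2) & x2 != "NA")
    if (length(bad_cell))
      stop(sprintf("non-numeric cell '%s' in column '%s' on line %d of %s",
                   df[[nm]][bad_cell[1]], nm, bad_cell[1] + 1L, file))
    df[[nm]] <- conv
  }
  df
}

#' Write a cohort to long-format CSV
#'
#' Serializes the measurement tables of a cohort as a long CSV with columns
#' `subject, group, eye, record_type, layer_or_sector, point_id, value`.
#' Record types are `layer_map` (64-cell thickness maps), `sector`
#' (peripapillary profile incl. the `NT` ratio), `sensitivity` (64-point dB
#' maps) and `meta` (age, sex, per-eye visual acuity, analysis-eye flag).
#' Fixation traces are serialized separately with
#' [write_fixation_csv()]; the generator's internal forced-scotoma flags
#' are diagnostics and are not serialized.
#'
#' @param cohort A `pp_cohort`.
#' @param file Path to the CSV file.
#' @param params_file Optional path for a JSON sidecar of the generator
#'   parameters (see [write_params_json()]).
#' @return `file`, invisibly.
#' @export
write_cohort_csv <- function(cohort, file, params_file = NULL) {
  stopifnot(inherits(cohort, "pp_cohort"))
  eyes <- cohort$eyes
  layers <- dimnames(cohort$thickness)[[2]]
  rows <- list()
  for (i in seq_len(nrow(eyes))) {
    for (li in seq_along(layers)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = eyes$subject_id[i], group = eyes$group[i],
        eye = eyes$eye[i], record_type = "layer_map",
        layer_or_sector = layers[li], point_id = 0:63,
        value = cohort$thickness[i, li, ], stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject = eyes$subject_id[i], group = eyes$group[i],
      eye = eyes$eye[i], record_type = "sector",
      layer_or_sector = colnames(cohort$sectors), point_id = NA_integer_,
      value = cohort$sectors[i, ], stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = eyes$subject_id[i], group = eyes$group[i],
      eye = eyes$eye[i], record_type = "sensitivity",
      layer_or_sector = "sensitivity", point_id = 0:63,
      value = cohort$sensitivity[i, ], stringsAsFactors = FALSE)
  }
  subj <- cohort$subjects
  meta <- data.frame(
    subject = rep(subj$subject_id, each = 4L),
    group = rep(subj$group, each = 4L),
    eye = "", record_type = "meta",
    layer_or_sector = rep(c("age", "bcva_od", "bcva_os", "analysis_eye_od"),
                          nrow(subj)),
    point_id = NA_integer_,
    value = c(rbind(subj$age, subj$bcva_od, subj$bcva_os,
                    as.numeric(subj$analysis_eye == "OD"))),
    stringsAsFactors = FALSE)
  sex <- data.frame(subject = subj$subject_id, group = subj$group, eye = "",
                    record_type = "meta", layer_or_sector = "sex_is_female",
                    point_id = NA_integer_,
                    value = as.numeric(subj$sex == "F"),
                    stringsAsFactors = FALSE)
  out <- do.call(rbind, c(rows, list(meta, sex)))
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   file, row.names = FALSE, quote = FALSE, na = "NA")
  if (!is.null(params_file)) write_params_json(cohort$params, params_file)
  invisible(file)
}

#' Read a cohort from long-format CSV
#'
#' Reconstructs a `pp_cohort` from a file written by [write_cohort_csv()]
#' (decimal commas are normalized on ingest). Fixation traces and the
#' generator's internal diagnostics are not part of the CSV contract and
#' come back empty.
#'
#' @param file Path to the CSV file.
#' @param params_file Optional JSON parameter sidecar to re-attach.
#' @return A `pp_cohort` object.
#' @export
read_cohort_csv <- function(file, params_file = NULL) {
  df <- read_numeric_csv(file, numeric_cols = c("point_id", "value"))
  need <- c("subject", "group", "eye", "record_type", "layer_or_sector",
            "point_id", "value")
  if (!all(need %in% names(df)))
    stop("cohort CSV must contain columns: ", paste(need, collapse = ", "))
  em <- unique(df[df$record_type != "meta", c("subject", "group", "eye")])
  em <- em[order(match(em$group, c("ADOA", "control")), em$subject, em$eye), ]
  rownames(em) <- NULL
  eyes <- data.frame(eye_index = seq_len(nrow(em)), subject_id = em$subject,
                     group = em$group, eye = em$eye, stringsAsFactors = FALSE)
  key <- paste(df$subject, df$eye)
  ekey <- paste(eyes$subject_id, eyes$eye)
  layers <- unique(df$layer_or_sector[df$record_type == "layer_map"])
  secs <- unique(df$layer_or_sector[df$record_type == "sector"])
  nE <- nrow(eyes)
  thickness <- array(NA_real_, c(nE, length(layers), 64),
                     dimnames = list(NULL, layers, NULL))
  sectors <- matrix(NA_real_, nE, length(secs),
                    dimnames = list(NULL, secs))
  sensitivity <- matrix(NA_integer_, nE, 64)
  lm_rows <- df$record_type == "layer_map"
  thickness[cbind(match(key[lm_rows], ekey),
                  match(df$layer_or_sector[lm_rows], layers),
                  df$point_id[lm_rows] + 1L)] <- df$value[lm_rows]
  sc_rows <- df$record_type == "sector"
  sectors[cbind(match(key[sc_rows], ekey),
                match(df$layer_or_sector[sc_rows], secs))] <- df$value[sc_rows]
  sn_rows <- df$record_type == "sensitivity"
  sensitivity[cbind(match(key[sn_rows], ekey),
                    df$point_id[sn_rows] + 1L)] <- as.integer(df$value[sn_rows])
  meta <- df[df$record_type == "meta", ]
  sid <- unique(eyes$subject_id)
  getm <- function(what) meta$value[match(paste(sid, what),
                                          paste(meta$subject, meta$layer_or_sector))]
  subjects <- data.frame(
    subject_id = sid,
    group = eyes$group[match(sid, eyes$subject_id)],
    age = getm("age"),
    sex = ifelse(getm("sex_is_female") == 1, "F", "M"),
    bcva_od = getm("bcva_od"), bcva_os = getm("bcva_os"),
    analysis_eye = ifelse(getm("analysis_eye_od") == 1, "OD", "OS"),
    stringsAsFactors = FALSE)
  eyes$is_analysis <- eyes$eye ==
    subjects$analysis_eye[match(eyes$subject_id, subjects$subject_id)]
  params <- if (!is.null(params_file)) read_params_json(params_file) else NULL
  structure(list(
    subjects = subjects, eyes = eyes, thickness = thickness,
    sectors = sectors, sensitivity = sensitivity,
    forced = NULL, fixation = NULL,
    subject_layers = NULL, subject_sectors = NULL,
    params = params, seed = NA_integer_,
    n_per_group = sum(subjects$group == "ADOA"),
    grid_spec = grid_spec(), grid = generate_pp_grid()
  ), class = "pp_cohort")
}

#' Write or read fixation traces as CSV
#'
#' Long format with columns `subject, eye, t, x_deg, y_deg`.
#'
#' @param cohort A `pp_cohort` with fixation traces.
#' @param file Path to a CSV file.
#' @return `read_fixation_csv` returns the long data.frame.
#' @export
write_fixation_csv <- function(cohort, file) {
  stopifnot(inherits(cohort, "pp_cohort"), !is.null(cohort$fixation))
  eyes <- cohort$eyes
  out <- do.call(rbind, lapply(seq_len(nrow(eyes)), function(i) {
    tr <- cohort$fixation[[i]]
    data.frame(subject = eyes$subject_id[i], eye = eyes$eye[i],
               t = seq_len(nrow(tr)), x_deg = tr[, 1], y_deg = tr[, 2],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_fixation_csv
#' @export
read_fixation_csv <- function(file) {
  read_numeric_csv(file, numeric_cols = c("t", "x_deg", "y_deg"))
}

#' Serialize generator parameters to JSON
#'
#' @param params A `pp_cohort_params` object.
#' @param file Path to a JSON file.
#' @return `read_params_json` returns a validated `pp_cohort_params`.
#' @export
write_params_json <- function(params, file) {
  stopifnot(inherits(params, "pp_cohort_params"))
  x <- unclass(params)
  # named vectors must become JSON objects, not bare arrays
  x$sens_offset <- as.list(x$sens_offset)
  x$fixation <- lapply(x$fixation, as.list)
  jsonlite::write_json(x, file, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(file)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (nm in c("layers", "sectors", "points", "demographics"))
    x[[nm]] <- as.data.frame(x[[nm]], stringsAsFactors = FALSE)
  x$sens_offset <- unlist(x$sens_offset)
  x$fixation <- lapply(x$fixation, unlist)
  x$db_range <- as.numeric(x$db_range)
  class(x) <- "pp_cohort_params"
  validate_params(x)
  x
}

#' Write or read a JSON report
#'
#' Thin wrappers over jsonlite with the package's JSON conventions
#' (auto-unboxed scalars, full precision).
#'
#' @param x A (nested) list of results.
#' @param file Path to a JSON file.
#' @return `read_json_report` returns the parsed list.
#' @export
write_json_report <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(file)
}

#' @rdname write_json_report
#' @export
read_json_report <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
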