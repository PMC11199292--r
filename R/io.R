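#' File formats: BrainVision recordings, subject tables, result bundles
#'
#' BrainVision recordings are stored as a text header (`.vhdr`), a text
#' marker file (`.vmrk`) and a binary multiplexed data file (`.eeg`).
#' The writer emits IEEE float-32 little-endian data; the reader additionally
#' accepts INT_16 with per-channel resolution scaling. Annotations map to
#' marker lines and back.
#'
#' @name io
NULL

#' Write a recording to BrainVision files
#'
#' @param rec An `eeg_recording`.
#' @param path_base Path without extension; `.vhdr`, `.vmrk`, `.eeg` are
#'   written next to each other.
#' @return `path_base.vhdr`, invisibly.
#' @export
write_brainvision <- function(rec, path_base) {
  stopifnot(inherits(rec, "eeg_recording"))
  base <- basename(path_base)
  vhdr <- paste0(path_base, ".vhdr")
  lines <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$sfreq),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$labels)
  )
  writeLines(lines, vhdr, useBytes = FALSE)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]",
          paste0("DataFile=", base, ".eeg"),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  ann <- rec$annotations
  if (nrow(ann) > 0) {
    mk <- c(mk, sprintf("Mk%d=Comment,%s,%d,%d,0",
                        seq_len(nrow(ann)) + 1L, ann$tag,
                        as.integer(round(ann$onset * rec$sfreq)) + 1L,
                        as.integer(round(ann$duration * rec$sfreq))))
  }
  writeLines(mk, paste0(path_base, ".vmrk"))
  con <- file(paste0(path_base, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

.parse_vhdr_ini <- function(lines) {
  sec <- NULL; out <- list()
  for (l in lines) {
    l <- sub(";.*$", "", l)
    l <- trimws(l)
    if (l == "") next
    if (grepl("^\\[.*\\]$", l)) { sec <- gsub("\\[|\\]", "", l); next }
    if (!grepl("=", l) || is.null(sec)) next
    kv <- regmatches(l, regexpr("=", l), invert = TRUE)[[1]]
    out[[sec]][[trimws(kv[1])]] <- trimws(kv[2])
  }
  out
}

#' Read a BrainVision recording
#'
#' Supports BINARY MULTIPLEXED data in IEEE_FLOAT_32 or INT_16 (with
#' per-channel resolution scaling) and maps `.vmrk` Comment markers to
#' annotations.
#'
#' @param vhdr_path Path to the `.vhdr` header.
#' @return An `eeg_recording`.
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("header file not found: ", vhdr_path)
  hdr <- .parse_vhdr_ini(readLines(vhdr_path, encoding = "UTF-8"))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("malformed vhdr: no [Common Infos] section")
  if (!identical(ci$DataFormat, "BINARY") ||
      !identical(ci$DataOrientation, "MULTIPLEXED"))
    stop("only BINARY MULTIPLEXED BrainVision data is supported")
  n_ch <- as.integer(ci$NumberOfChannels)
  sfreq <- 1e6 / as.numeric(ci$SamplingInterval)
  fmt <- hdr[["Binary Infos"]]$BinaryFormat
  chinfo <- hdr[["Channel Infos"]]
  ord <- order(as.integer(sub("^Ch", "", names(chinfo))))
  chinfo <- chinfo[ord]
  parts <- lapply(chinfo, function(x) strsplit(x, ",")[[1]])
  labels <- unname(vapply(parts, `[`, character(1), 1))
  res <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1))
  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, ci$DataFile)
  n_bytes <- file.size(eeg_path)
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    raw <- readBin(con, numeric(), n = n_bytes / 4, size = 4, endian = "little")
  } else if (identical(fmt, "INT_16")) {
    raw <- readBin(con, integer(), n = n_bytes / 2, size = 2, endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  n_samp <- length(raw) %/% n_ch
  data <- matrix(raw[seq_len(n_ch * n_samp)], nrow = n_ch)
  data <- data * res
  ann <- NULL
  vmrk_path <- file.path(dir, ci$MarkerFile)
  if (!is.null(ci$MarkerFile) && file.exists(vmrk_path)) {
    mi <- .parse_vhdr_ini(readLines(vmrk_path, encoding = "UTF-8"))[["Marker Infos"]]
    rows <- lapply(mi, function(x) strsplit(x, ",")[[1]])
    rows <- Filter(function(p) length(p) >= 4 && p[1] == "Comment", rows)
    if (length(rows) > 0) {
      ann <- data.frame(
        onset = (vapply(rows, function(p) as.numeric(p[3]), numeric(1)) - 1) / sfreq,
        duration = vapply(rows, function(p) as.numeric(p[4]), numeric(1)) / sfreq,
        tag = vapply(rows, `[`, character(1), 2),
        stringsAsFactors = FALSE)
    }
  }
  eeg_recording(data, sfreq, labels = labels, annotations = ann)
}

#' Read and validate a subject table
#'
#' Expects a UTF-8 CSV with columns `subject_id`, `gender`, and
#' `aq_item_01` .. `aq_item_12` (integers in 1..6). Unknown extra columns are
#' preserved with a warning; schema violations raise an error naming the
#' offending columns.
#'
#' @param path CSV file path.
#' @export
read_subject_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("subject_id", "gender", sprintf("aq_item_%02d", 1:12))
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("subject table missing columns: ", paste(missing, collapse = ", "))
  itemcols <- sprintf("aq_item_%02d", 1:12)
  bad <- itemcols[vapply(itemcols, function(cn)
    anyNA(tab[[cn]]) || !all(tab[[cn]] %in% 1:6), logical(1))]
  if (length(bad) > 0)
    stop("AQ items outside 1..6 (or missing) in columns: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(tab$subject_id)) stop("duplicate subject_id values")
  extra <- setdiff(names(tab), required)
  if (length(extra) > 0)
    warning("unknown columns preserved: ", paste(extra, collapse = ", "))
  tab
}

#' Write a subject table
#'
#' @param subjects data.frame in the schema of [read_subject_table()].
#' @param path Output CSV path.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an analysis results bundle
#'
#' Writes the outcome x predictor grid as CSV, the full bundle (including
#' ICCs and model comparisons) as JSON, and a provenance sidecar.
#'
#' @param bundle A `trait_analysis` (or the list returned by
#'   [run_pipeline()]).
#' @param dir Output directory (created if needed).
#' @param provenance Optional named list recorded alongside the results.
#' @export
write_results <- function(bundle, dir, provenance = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  analysis <- if (inherits(bundle, "trait_analysis")) bundle else bundle$analysis
  if (!is.null(analysis)) {
    utils::write.csv(analysis$grid, file.path(dir, "trait_grid.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$subject_stats)) {
    utils::write.csv(bundle$subject_stats, file.path(dir, "subject_stats.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(.unclass_deep(if (inherits(bundle, "trait_analysis"))
    list(analysis = bundle) else bundle[setdiff(names(bundle), "labels")]),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  provenance$written_utc <- format(Sys.time(), tz = "UTC")
  provenance$package_version <- as.character(utils::packageVersion("microstability"))
  jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# strip S3 classes / matrices so jsonlite serializes plainly
.unclass_deep <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, identity, simplify = FALSE))
  if (is.list(x) && !is.data.frame(x)) return(lapply(unclass(x), .unclass_deep))
  if (is.object(x) && !is.data.frame(x)) return(unclass(x))
  x
}
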