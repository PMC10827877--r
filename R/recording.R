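#' Participant metadata
#'
#' @param id participant identifier (string).
#' @param group study arm, `"PEM"` (childhood protein-energy malnutrition)
#'   or `"CON"` (control).
#' @param age age in years at recording.
#' @param sex `"M"` or `"F"`.
#' @param handedness `"L"` or `"R"`.
#' @param ses childhood socioeconomic factor score (standardized, unitless).
#' @param age_bounds plausible adult age range used for validation.
#' @return An object of class `participant_info`.
#' @export
participant_info <- function(id, group, age, sex = "M", handedness = "R",
                             ses = 0, age_bounds = c(18, 100)) {
  group <- as.character(group)
  if (!group %in% c("PEM", "CON")) {
    stop(sprintf("unknown group label '%s' (only PEM/CON supported)", group))
  }
  if (!is.finite(age) || age < age_bounds[1] || age > age_bounds[2]) {
    stop(sprintf("age %s outside plausible bounds [%g, %g]", format(age),
                 age_bounds[1], age_bounds[2]))
  }
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'")
  if (!handedness %in% c("L", "R")) stop("handedness must be 'L' or 'R'")
  structure(list(id = as.character(id), group = group, age = age, sex = sex,
                 handedness = handedness, ses = ses),
            class = "participant_info")
}

#' Multichannel NIRS intensity recording
#'
#' Raw continuous-wave optical intensity with its sampling rate, the
#' participant it belongs to, a per-sample validity mask and the set of
#' excluded channels. Intensity must be strictly positive wherever the
#' mask is true (light counts cannot be zero or negative).
#'
#' @param intensity numeric array, time x channel x wavelength.
#' @param fs sampling rate in Hz (default 7.81).
#' @param wavelengths wavelengths (nm) along the third dimension.
#' @param participant a `participant_info`.
#' @param valid_mask logical time x channel matrix; defaults to all-true.
#' @param excluded_channels integer channel indices excluded upstream.
#' @return An object of class `nirs_recording`.
#' @export
nirs_recording <- function(intensity, fs = 7.81, wavelengths = c(760, 850),
                           participant = NULL, valid_mask = NULL,
                           excluded_channels = integer(0)) {
  stopifnot(length(dim(intensity)) == 3)
  if (!is.finite(fs) || fs <= 0) stop("sampling rate fs must be > 0")
  if (dim(intensity)[3] != length(wavelengths)) {
    stop(sprintf("intensity has %d wavelength planes but %d wavelengths given",
                 dim(intensity)[3], length(wavelengths)))
  }
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, dim(intensity)[1], dim(intensity)[2])
  }
  if (!all(dim(valid_mask) == dim(intensity)[1:2])) {
    stop("valid_mask must share the time x channel shape of intensity")
  }
  ok <- rep(valid_mask, length(wavelengths))
  if (any(intensity[ok] <= 0, na.rm = TRUE)) {
    stop("intensity must be strictly positive wherever valid_mask is true")
  }
  structure(list(intensity = intensity, fs = fs,
                 wavelengths = as.numeric(wavelengths),
                 participant = participant, valid_mask = valid_mask,
                 excluded_channels = as.integer(excluded_channels)),
            class = "nirs_recording")
}

#' @exportS3Method base::print
print.nirs_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("nirs_recording: %d samples x %d channels x %d wavelengths (%s nm), fs %g Hz (%.1f s)\n",
              d[1], d[2], d[3], paste(x$wavelengths, collapse = "/"), x$fs, d[1] / x$fs))
  if (!is.null(x$participant)) {
    cat(sprintf("participant: %s (%s)\n", x$participant$id, x$participant$group))
  }
  invisible(x)
}

#' Write / read a recording as delimited text
#'
#' Plain-text container for continuous-wave intensity data: `#`-prefixed
#' header lines carry the sampling rate, wavelengths and participant
#' metadata (JSON); the body is a tab-separated table with one column per
#' channel x wavelength (`ch<c>_w<nm>`) plus one 0/1 validity column per
#' channel (`ch<c>_valid`). Values are written with 10 significant digits,
#' so a write/read/write cycle reproduces the data payload byte-exactly.
#'
#' @param rec a `nirs_recording`.
#' @param path file path (conventionally `.nirs.tsv`).
#' @return `read_recording` returns a `nirs_recording`.
#' @export
write_recording <- function(rec, path) {
  d <- dim(rec$intensity)
  cols <- list()
  nms <- character(0)
  for (w in seq_len(d[3])) {
    for (ch in seq_len(d[2])) {
      cols[[length(cols) + 1L]] <- rec$intensity[, ch, w]
      nms <- c(nms, sprintf("ch%03d_w%d", ch, round(rec$wavelengths[w])))
    }
  }
  for (ch in seq_len(d[2])) {
    cols[[length(cols) + 1L]] <- as.integer(rec$valid_mask[, ch])
    nms <- c(nms, sprintf("ch%03d_valid", ch))
  }
  df <- as.data.frame(cols)
  names(df) <- nms
  hdr <- c(sprintf("#fs=%.10g", rec$fs),
           sprintf("#wavelengths=%s", paste(rec$wavelengths, collapse = ",")),
           sprintf("#excluded_channels=%s",
                   paste(rec$excluded_channels, collapse = ",")))
  if (!is.null(rec$participant)) {
    hdr <- c(hdr, paste0("#participant=",
                         jsonlite::toJSON(unclass(rec$participant), auto_unbox = TRUE)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param require_wavelengths wavelengths (nm) that must be present; a file
#'   missing any of them is rejected with an error naming what was found.
#' @export
read_recording <- function(path, require_wavelengths = c(760, 850)) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(sprintf("^#%s=", key), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(sprintf("^#%s=", key), "", hit[1])
  }
  fs <- as.numeric(get("fs"))
  if (!length(fs) || !is.finite(fs) || fs <= 0) {
    stop("recording format error: non-positive or missing sampling rate")
  }
  wl <- as.numeric(strsplit(get("wavelengths"), ",")[[1]])
  missing_wl <- setdiff(require_wavelengths, wl)
  if (length(missing_wl)) {
    stop(sprintf("recording format error: wavelengths found {%s} nm, required {%s} nm",
                 paste(wl, collapse = ", "),
                 paste(require_wavelengths, collapse = ", ")))
  }
  excl <- get("excluded_channels")
  excl <- if (is.null(excl) || excl == "") integer(0) else as.integer(strsplit(excl, ",")[[1]])
  pinfo <- get("participant")
  participant <- NULL
  if (!is.null(pinfo)) {
    pl <- jsonlite::fromJSON(pinfo)
    participant <- participant_info(pl$id, pl$group, pl$age, pl$sex,
                                    pl$handedness, pl$ses)
  }
  df <- utils::read.table(textConnection(lines[!grepl("^#", lines)]),
                          sep = "\t", header = TRUE)
  vcols <- grep("_valid$", names(df))
  nch <- length(vcols)
  nt <- nrow(df)
  intensity <- array(NA_real_, c(nt, nch, length(wl)))
  for (w in seq_along(wl)) {
    for (ch in seq_len(nch)) {
      intensity[, ch, w] <- df[[sprintf("ch%03d_w%d", ch, round(wl[w]))]]
    }
  }
  valid <- matrix(FALSE, nt, nch)
  for (ch in seq_len(nch)) valid[, ch] <- df[[sprintf("ch%03d_valid", ch)]] == 1
  nirs_recording(intensity, fs = fs, wavelengths = wl, participant = participant,
                 valid_mask = valid, excluded_channels = excl)
}

#' Read / write a participant roster
#'
#' CSV with columns `id`, `group`, `age`, `sex`, `handedness`, `ses`.
#' Group labels other than PEM/CON (e.g. the kwashiorkor arm, which is not
#' part of this analysis) are rejected with the offending row number.
#'
#' @param path CSV file path.
#' @return `read_roster` returns a list of `participant_info`.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "age", "sex", "handedness", "ses")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("roster missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    warning("empty roster file: ", path)
    return(list())
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      participant_info(df$id[i], df$group[i], df$age[i], df$sex[i],
                       df$handedness[i], df$ses[i]),
      error = function(e) stop(sprintf("roster row %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
  }
  out
}

#' @rdname read_roster
#' @param roster list of `participant_info`.
#' @export
write_roster <- function(roster, path) {
  df <- roster_frame(roster)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Roster as a data.frame
#'
#' @param roster list of `participant_info`.
#' @return data.frame with one row per participant.
#' @export
roster_frame <- function(roster) {
  do.call(rbind, lapply(roster, function(p) {
    data.frame(id = p$id, group = p$group, age = p$age, sex = p$sex,
               handedness = p$handedness, ses = p$ses,
               stringsAsFactors = FALSE)
  }))
}

#' Write / read a labeled symmetric matrix as TSV
#'
#' @param m square numeric matrix.
#' @param labels row/column labels, same length as `nrow(m)`.
#' @param path file path.
#' @param digits significant digits written (values round-trip exactly at
#'   this precision).
#' @return `read_matrix` returns a labeled matrix.
#' @export
write_matrix <- function(m, labels, path, digits = 10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("matrix must be square, got %d x %d", NROW(m), NCOL(m)))
  }
  if (length(labels) != nrow(m)) stop("labels length must match matrix dimension")
  dimnames(m) <- list(labels, labels)
  utils::write.table(signif(m, digits), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}
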