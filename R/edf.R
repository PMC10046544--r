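# Minimal EDF / EDF+C reader and writer (16-bit integer samples, physical
# dimension fixed to microvolts). Covers the exchange needs of this
# workflow: one sampling rate across ordinary signals, an optional
# "EDF Annotations" stream carrying artifact/event marks.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a symmetric per-channel
#' physical range; annotations, when present, are stored in an EDF+
#' annotations stream (timestamped annotation lists).
#'
#' @param rec a `recording` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  nchan <- nrow(data)
  n <- ncol(data)
  fs <- rec$fs_hz
  has_ann <- !is.null(rec$annotations) && nrow(rec$annotations) > 0

  if (n %% fs == 0 && fs == round(fs)) {
    spr <- as.integer(fs); nrec <- n %/% fs; recdur <- 1
  } else {
    spr <- n; nrec <- 1L; recdur <- n / fs
  }

  # Per-channel symmetric physical range (avoids zero-width ranges).
  pmaxs <- apply(abs(data), 1, max)
  pmaxs <- ifelse(pmaxs <= 0, 1, pmaxs * 1.0001)
  dmin <- -32768; dmax <- 32767

  ann_bytes <- 0L
  ann_tal <- NULL
  if (has_ann) {
    tal <- vapply(seq_len(nrow(rec$annotations)), function(i) {
      a <- rec$annotations[i, ]
      paste0(sprintf("+%.4f", a$onset_s), "\x15",
             sprintf("%.4f", a$duration_s), "\x14", a$label, "\x14")
    }, character(1))
    # TALs are NUL-separated within the annotation stream.
    ann_tal <- unlist(lapply(tal, function(s) c(charToRaw(s), as.raw(0))))
    ann_bytes <- as.integer(ceiling((length(ann_tal) + 32L) / 2) * 2)
  }

  ns <- nchan + as.integer(has_ann)
  con <- file(path, "wb")
  on.exit(close(con))

  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste0("X X X ", rec$subject_id), 80),
    edf_pad(paste0("Startdate X X X X visit_", rec$visit), 80),
    "01.01.20", "00.00.00",
    edf_pad(256 * (1 + ns), 8),
    edf_pad(if (has_ann) "EDF+C" else "", 44),
    edf_pad(nrec, 8),
    edf_num(recdur, 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)

  field <- function(vals, width) {
    paste(vapply(vals, edf_pad, character(1), width = width), collapse = "")
  }
  labels <- c(rec$channel_labels, if (has_ann) "EDF Annotations")
  writeChar(field(labels, 16), con, eos = NULL)
  writeChar(field(rep("", ns), 80), con, eos = NULL)                # transducer
  writeChar(field(c(rep("uV", nchan), if (has_ann) ""), 8), con, eos = NULL)
  writeChar(field(c(edf_num_v(-pmaxs), if (has_ann) "-1"), 8), con, eos = NULL)
  writeChar(field(c(edf_num_v(pmaxs), if (has_ann) "1"), 8), con, eos = NULL)
  writeChar(field(c(rep(dmin, nchan), if (has_ann) dmin), 8), con, eos = NULL)
  writeChar(field(c(rep(dmax, nchan), if (has_ann) dmax), 8), con, eos = NULL)
  writeChar(field(rep("", ns), 80), con, eos = NULL)                # prefilter
  writeChar(field(c(rep(spr, nchan), if (has_ann) ann_bytes %/% 2), 8),
            con, eos = NULL)
  writeChar(field(rep("", ns), 32), con, eos = NULL)

  scale <- (2 * pmaxs) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(nchan)) {
      dig <- round((data[ch, idx] + pmaxs[ch]) / scale[ch]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
    if (has_ann) {
      ts <- c(charToRaw(paste0("+", format((r - 1) * recdur), "\x14\x14")),
              as.raw(0))
      raw_p <- if (r == 1) c(ts, ann_tal) else ts
      raw_p <- c(raw_p, raw(ann_bytes - length(raw_p)))
      writeBin(raw_p, con)
    }
  }
  invisible(path)
}

edf_num_v <- function(x) vapply(x, edf_num, character(1), width = 8)

#' Read an EDF file into a recording
#'
#' Supports the subset written by [write_edf()] plus plain EDF files with a
#' common sampling rate across ordinary signals. Sample values are returned
#' in the file's physical units (microvolts for this workflow); EDF+
#' annotation streams are decoded into the `annotations` table.
#'
#' @param path EDF file path.
#' @return a `recording` object.
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("format error: not an EDF file (too short)")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nb) {
    raw_b <- readBin(con, "raw", nb)
    trimws(rawToChar(raw_b))
  }
  version <- rd(8)
  if (version != "0") stop("format error: unsupported EDF version header")
  patient <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8)                       # start date/time
  hdr_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(nrec) || nrec < 1) {
    stop("format error: malformed EDF header counts")
  }
  fld <- function(width) {
    vapply(seq_len(ns), function(i) rd(width), character(1))
  }
  labels <- fld(16)
  fld(80)                            # transducer
  dims <- fld(8)
  pmin_ <- as.numeric(fld(8))
  pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8))
  dmax_ <- as.numeric(fld(8))
  fld(80)                            # prefiltering
  spr <- as.integer(fld(8))
  fld(32)
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr))) {
    stop("format error: malformed EDF signal header")
  }
  is_ann <- labels == "EDF Annotations"
  sig <- which(!is_ann)
  if (length(unique(spr[sig])) > 1) {
    stop("unsupported-layout error: mixed sampling rates across channels")
  }
  fs <- spr[sig[1]] / recdur
  n <- spr[sig[1]] * nrec
  data <- matrix(0, nrow = length(sig), ncol = n)
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  ann_raw <- raw(0)
  seek(con, hdr_bytes)
  for (r in seq_len(nrec)) {
    for (k in seq_len(ns)) {
      if (is_ann[k]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", spr[k] * 2))
      } else {
        dig <- readBin(con, "integer", spr[k], size = 2, endian = "little")
        row <- match(k, sig)
        idx <- ((r - 1) * spr[k] + 1):(r * spr[k])
        data[row, idx] <- pmin_[k] + (dig - dmin_[k]) * scale[k]
      }
    }
  }
  ann <- parse_edf_annotations(ann_raw)
  subject_id <- sub("^X X X ", "", patient)
  visit <- sub(".*visit_", "", rec_id)
  if (identical(visit, rec_id)) visit <- "unknown"
  new_recording(data, labels[sig], fs,
                reference = "linked-ears",
                subject_id = subject_id, visit = visit, annotations = ann)
}

# Decode EDF+ timestamped annotation lists (TALs) from raw bytes.
parse_edf_annotations <- function(ann_raw) {
  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      label = character(0))
  if (!length(ann_raw)) return(empty)
  # TALs are NUL-separated; make the separator printable, then split.
  ann_raw[ann_raw == as.raw(0)] <- as.raw(31)
  tals <- strsplit(rawToChar(ann_raw), "\x1f", fixed = TRUE)[[1]]
  tals <- tals[nzchar(tals)]
  out <- list()
  for (tal in tals) {
    # Each TAL looks like "+onset(\x15duration)\x14label(\x14...)"
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    head_p <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head_p[1]))
    durat <- if (length(head_p) > 1) {
      suppressWarnings(as.numeric(head_p[2]))
    } else {
      0
    }
    labs <- parts[-1]
    labs <- labs[nzchar(labs)]
    for (lb in labs) {
      out[[length(out) + 1]] <- data.frame(onset_s = onset,
                                           duration_s = durat, label = lb)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[is.finite(res$onset_s), , drop = FALSE]
}

#' Read a recording and check it parses as a study EEG file
#'
#' Thin wrapper over [read_edf()] kept as the public ingestion point; errors
#' are format errors, montage problems are reported by
#' [validate_montage()].
#'
#' @inheritParams read_edf
#' @export
read_recording <- function(path) read_edf(path)
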