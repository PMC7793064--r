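# FCS 3.0 I/O. Written dialect: single dataset, $DATATYPE F,
# little-endian ($BYTEORD 1,2,3,4), $PnN = detector, $PnS = marker,
# $SPILLOVER in the "n,names...,values..." convention. The reader also
# accepts $DATATYPE I and big-endian files.

#' Write a tube frame to an FCS 3.0 file
#'
#' @param tube A [tube_frame()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(tube, path) {
  stopifnot(inherits(tube, "tube_frame"))
  ev <- tube$events
  n_par <- ncol(ev)
  n_tot <- nrow(ev)
  delim <- "/"
  kw <- c(
    "$FIL" = basename(path),
    "$MODE" = "L",
    "$DATATYPE" = "F",
    "$BYTEORD" = "1,2,3,4",
    "$PAR" = as.character(n_par),
    "$TOT" = as.character(n_tot),
    "$NEXTDATA" = "0",
    "TUBE" = tube$tube_id,
    "PATIENT" = tube$patient_id
  )
  for (j in seq_len(n_par)) {
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- "262144"
    kw[sprintf("$P%dN", j)] <- tube$channels[j]
    kw[sprintf("$P%dS", j)] <- tube$markers[j]
  }
  if (!is.null(tube$spillover)) {
    kw["$SPILLOVER"] <- paste(
      c(n_par, tube$channels,
        format(as.vector(t(tube$spillover)), trim = TRUE, digits = 15)),
      collapse = ",")
  }

  render_text <- function(kw, begin_data, end_data) {
    kw2 <- c(kw, "$BEGINDATA" = as.character(begin_data),
             "$ENDDATA" = as.character(end_data),
             "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
             "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0")
    paste0(delim, paste0(names(kw2), delim, unname(kw2), delim,
                         collapse = ""))
  }
  header_len <- 58L  # "FCS3.0" + 4 spaces + 6 offset fields of 8 bytes
  # fixed point: text length depends on the data offsets it encodes
  text <- render_text(kw, 0, 0)
  for (i in 1:5) {
    begin_text <- header_len
    end_text <- begin_text + nchar(text, type = "bytes") - 1L
    begin_data <- end_text + 1L
    end_data <- begin_data + 4L * n_par * n_tot - 1L
    new_text <- render_text(kw, begin_data, end_data)
    if (nchar(new_text, type = "bytes") == nchar(text, type = "bytes")) {
      text <- new_text
      break
    }
    text <- new_text
  }
  off <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.0    ", off(begin_text), off(end_text),
                   off(begin_data), off(end_data), off(0), off(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(ev)), con, size = 4L, endian = "little")
  invisible(path)
}

.parse_spillover <- function(s, channels) {
  parts <- strsplit(s, ",")[[1]]
  n <- as.integer(parts[1])
  nm <- parts[2:(n + 1)]
  vals <- as.numeric(parts[(n + 2):(n + 1 + n * n)])
  mat <- matrix(vals, n, n, byrow = TRUE, dimnames = list(nm, nm))
  mat
}

#' Read an FCS 3.0 file into a tube frame
#'
#' Supports `$DATATYPE` F (IEEE float) and I (unsigned integer), both
#' byte orders. Marker names are taken from `$PnS`, falling back to
#' `$PnN`. A missing `$SPILLOVER` keyword yields an identity spillover
#' with a warning.
#'
#' @param path FCS file path.
#' @return A [tube_frame()] on raw scale.
#' @export
read_fcs <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 58) {
    stop("not an FCS file (too short): ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (version != "FCS3.0" && version != "FCS3.1") {
    stop("unsupported FCS version '", version, "' in ", path)
  }
  offs <- suppressWarnings(as.integer(substring(
    header, 10 + 8 * (0:5) + 1, 10 + 8 * (1:6))))
  begin_text <- offs[1]; end_text <- offs[2]
  begin_data <- offs[3]; end_data <- offs[4]
  if (anyNA(c(begin_text, end_text)) || end_text > size) {
    stop("truncated FCS file ", path, ": TEXT segment [",
         begin_text, ", ", end_text, "] exceeds file size ", size)
  }
  seek(con, begin_text)
  text <- readChar(con, end_text - begin_text + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(trimws(parts[seq(1, length(parts), 2)])))
  need <- function(k) {
    if (!k %in% names(kw)) stop("FCS file ", path, " lacks keyword ", k)
    kw[[k]]
  }
  datatype <- need("$DATATYPE")
  if (!datatype %in% c("F", "I")) {
    stop("unsupported $DATATYPE '", datatype, "' in ", path,
         " (only F and I are handled)")
  }
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  if (begin_data == 0) begin_data <- as.integer(need("$BEGINDATA"))
  if (end_data == 0) end_data <- as.integer(need("$ENDDATA"))
  bits <- as.integer(kw[sprintf("$P%dB", seq_len(n_par))])
  if (any(is.na(bits))) bits <- rep(32L, n_par)
  if (length(unique(bits)) != 1) {
    stop("mixed $PnB widths are not supported: ", path)
  }
  bytes_per <- bits[1] / 8
  expected <- n_par * n_tot * bytes_per
  if (begin_data + expected - 1 > size) {
    stop("truncated FCS file ", path, ": DATA needs bytes up to offset ",
         begin_data + expected - 1, " but file has ", size)
  }
  seek(con, begin_data)
  if (datatype == "F") {
    vals <- readBin(con, "numeric", n = n_par * n_tot, size = 4L,
                    endian = endian)
  } else {
    vals <- readBin(con, "integer", n = n_par * n_tot,
                    size = bytes_per, endian = endian,
                    signed = bytes_per >= 4)
  }
  ev <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  channels <- vapply(seq_len(n_par),
                     function(j) need(sprintf("$P%dN", j)), character(1))
  markers <- vapply(seq_len(n_par), function(j) {
    s <- kw[[sprintf("$P%dS", j)]]
    if (is.null(s) || !nzchar(s)) channels[j] else s
  }, character(1))
  if ("$SPILLOVER" %in% names(kw)) {
    sp <- .parse_spillover(kw[["$SPILLOVER"]], channels)
    full <- diag(n_par)
    dimnames(full) <- list(channels, channels)
    idx <- match(rownames(sp), channels)
    full[idx, idx] <- sp
    spill <- full
  } else {
    warning("no $SPILLOVER keyword in ", basename(path),
            "; assuming identity spillover")
    spill <- diag(n_par)
    dimnames(spill) <- list(channels, channels)
  }
  tube_frame(ev, channels = channels, markers = markers,
             spillover = spill,
             tube_id = if ("TUBE" %in% names(kw)) kw[["TUBE"]] else "T1",
             patient_id = if ("PATIENT" %in% names(kw))
               kw[["PATIENT"]] else basename(path),
             scale = "raw", compensated = FALSE)
}

#' Write a cohort to disk as FCS files plus a clinical table
#'
#' Emits one FCS 3.0 file per tube per patient
#' (`<patient>_<tube>.fcs`) and a UTF-8 comma-delimited clinical table
#' (`clinical.csv`, missing values as empty fields).
#'
#' @param cohort A `flow_cohort` (normally after [cohort_raw()]).
#' @param dir Output directory (created if needed).
#' @return Tibble listing the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "flow_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (p in cohort$patients) {
    if (is.null(p$tubes)) stop("cohort has no tube data to write")
    for (tb in p$tubes) {
      f <- file.path(dir, paste0(p$patient_id, "_", tb$tube_id, ".fcs"))
      write_fcs(tb, f)
      files <- c(files, f)
    }
  }
  clin <- file.path(dir, "clinical.csv")
  utils::write.csv(cohort$clinical, clin, row.names = FALSE, na = "")
  invisible(tibble::tibble(file = c(files, clin)))
}

#' Read the clinical table written by [write_cohort()]
#'
#' @param path Path to `clinical.csv` (or the cohort directory).
#' @return Tibble with one row per patient; empty fields become `NA`.
#' @export
read_clinical <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "clinical.csv")
  tb <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::as_tibble(tb)
}
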