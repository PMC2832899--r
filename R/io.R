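# File I/O: delimited text and FCS event input, a minimal FCS writer for
# round-trip testing, JSON gate interchange, and membership CSV output.

GATE_SCHEMA <- "curvgate/1"

#' Read events from a file
#'
#' Loads an event table from delimited text (CSV/TSV with a header row, one
#' row per event) or from an FCS file (versions 2.0/3.0/3.1, list mode,
#' integer / float / double data). Channel names come from the file header
#' (`$PnN`, falling back to `$PnS`, for FCS). Row order is preserved;
#' selecting channels reorders columns to the requested order.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or `"fcs"`.
#' @param channels optional channel names or indices to keep, in order.
#' @return An [event_table()] in original units.
#' @export
read_events <- function(path, format = c("auto", "csv", "tsv", "fcs"),
                        channels = NULL) {
  format <- match.arg(format)
  cg_assert(file.exists(path), sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, fcs = "fcs", tsv = "tsv", txt = "tsv", "csv")
  }
  if (format == "fcs") {
    parsed <- read_fcs(path)
    t <- event_table(parsed$values, parsed$channel_names)
  } else {
    df <- data.table::fread(path, sep = if (format == "tsv") "\t" else ",",
                            header = TRUE, data.table = FALSE)
    cg_assert(nrow(df) >= 1 && ncol(df) >= 1, "no events in file")
    bad <- !vapply(df, is.numeric, logical(1))
    cg_assert(!any(bad), sprintf("non-numeric column(s): %s",
                                 paste(names(df)[bad], collapse = ", ")))
    t <- event_table(as.matrix(df), names(df))
  }
  if (!is.null(channels)) {
    if (is.character(channels)) {
      missing <- setdiff(channels, t$channel_names)
      if (length(missing) > 0) {
        cg_abort(sprintf("channel(s) not found: %s (available: %s)",
                         paste(missing, collapse = ", "),
                         paste(t$channel_names, collapse = ", ")))
      }
      channels <- match(channels, t$channel_names)
    }
    t <- event_table(t$values[, channels, drop = FALSE],
                     t$channel_names[channels])
  }
  t
}

# Minimal FCS list-mode reader.
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 58))
  version <- substr(hdr, 1, 6)
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1")) {
    cg_abort(sprintf("not a supported FCS file (version field '%s' at offset 0)",
                     version), class = "curvgate_format_error")
  }
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(hdr, a, b))))
  text_start <- off(11, 18); text_end <- off(19, 26)
  data_start <- off(27, 34); data_end <- off(35, 42)
  if (anyNA(c(text_start, text_end))) {
    cg_abort("malformed FCS header: unreadable TEXT offsets at bytes 10-25",
             class = "curvgate_format_error")
  }
  seek(con, text_start)
  text <- rawToChar(readBin(con, "raw", text_end - text_start + 1))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  parts <- parts[nchar(parts) > 0 | seq_along(parts) %% 2 == 0]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(trimws(parts[seq(1, length(parts), 2)])))
  need <- function(k) {
    v <- kw[[k]]
    if (is.null(v)) cg_abort(sprintf("FCS TEXT segment lacks %s", k),
                             class = "curvgate_format_error")
    v
  }
  if (toupper(need("$MODE")) != "L") {
    cg_abort("only list-mode ($MODE L) FCS data is supported",
             class = "curvgate_format_error")
  }
  par <- as.integer(need("$PAR")); tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- gsub("[^0-9,]", "", need("$BYTEORD"))
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
  else if (byteord %in% c("4,3,2,1", "2,1")) "big"
  else cg_abort(sprintf("unsupported $BYTEORD '%s'", byteord),
                class = "curvgate_format_error")
  if (is.na(data_start) || data_start == 0) data_start <- as.numeric(need("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0) data_end <- as.numeric(need("$ENDDATA"))
  seek(con, data_start)
  nvals <- par * tot
  values <- switch(dtype,
    F = readBin(con, "numeric", nvals, size = 4, endian = endian),
    D = readBin(con, "numeric", nvals, size = 8, endian = endian),
    I = {
      bits <- unique(vapply(seq_len(par), function(k) {
        as.integer(need(sprintf("$P%dB", k)))
      }, integer(1)))
      if (length(bits) != 1 || !bits %in% c(8L, 16L, 32L)) {
        cg_abort("integer FCS data requires uniform $PnB of 8, 16 or 32 bits",
                 class = "curvgate_format_error")
      }
      if (bits == 32L) {
        v <- readBin(con, "integer", nvals, size = 4, endian = endian)
        v <- as.numeric(v); v[v < 0] <- v[v < 0] + 2^32; v
      } else {
        as.numeric(readBin(con, "integer", nvals, size = bits / 8,
                           signed = FALSE, endian = endian))
      }
    },
    cg_abort(sprintf("unsupported $DATATYPE '%s' (byte offset %d)",
                     dtype, data_start), class = "curvgate_format_error")
  )
  if (length(values) != nvals) {
    cg_abort(sprintf("FCS DATA segment truncated at byte %.0f", data_start),
             class = "curvgate_format_error")
  }
  nm <- vapply(seq_len(par), function(k) {
    v <- kw[[sprintf("$P%dN", k)]]
    if (is.null(v) || !nzchar(v)) v <- kw[[sprintf("$P%dS", k)]]
    if (is.null(v) || !nzchar(v)) v <- sprintf("P%d", k)
    v
  }, character(1))
  list(values = matrix(values, nrow = tot, ncol = par, byrow = TRUE),
       channel_names = nm)
}

#' Write an event table as a minimal FCS 3.0 file
#'
#' List mode, 32-bit float, little endian; sufficient for lossless (within
#' float precision) round trips through [read_events()].
#'
#' @param t an [event_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_fcs <- function(t, path) {
  cg_assert(inherits(t, "event_table"), "expected an event_table")
  delim <- "/"
  kv <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0", "$BEGINSTEXT" = "0",
    "$ENDSTEXT" = "0", "$NEXTDATA" = "0", "$MODE" = "L", "$DATATYPE" = "F",
    "$BYTEORD" = "1,2,3,4", "$PAR" = as.character(t$d),
    "$TOT" = as.character(t$n)
  )
  for (k in seq_len(t$d)) {
    kv[sprintf("$P%dB", k)] <- "32"
    kv[sprintf("$P%dN", k)] <- t$channel_names[k]
    kv[sprintf("$P%dE", k)] <- "0,0"
    kv[sprintf("$P%dR", k)] <- format(ceiling(max(t$values[, k], 1)),
                                      scientific = FALSE)
  }
  ndata <- 4 * t$n * t$d
  text_start <- 58
  # data offsets appear inside TEXT; fixed-width values keep lengths stable
  build_text <- function(b, e) {
    kv2 <- c(kv, "$BEGINDATA" = sprintf("%010d", b), "$ENDDATA" = sprintf("%010d", e))
    paste0(delim, paste0(names(kv2), delim, unname(kv2), delim, collapse = ""))
  }
  tlen <- nchar(build_text(0, 0), type = "bytes")
  data_start <- text_start + tlen
  data_end <- data_start + ndata - 1
  text <- build_text(data_start, data_end)
  hdr <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                 text_start, text_start + tlen - 1, data_start, data_end, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(t$values)), con, size = 4, endian = "little")
  invisible(path)
}

#' Serialize a gate region to JSON
#'
#' The package's gate interchange format: a versioned JSON object with the
#' dimension, coordinate space and the list of components (intervals,
#' polygons as vertex rings, triangle meshes as vertex and face arrays).
#' Numbers are written at full precision so round trips are lossless.
#'
#' @param region a [gate_region()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gate <- function(region, path) {
  cg_assert(inherits(region, "gate_region"), "expected a gate_region")
  comps <- lapply(region$components, function(cmp) {
    switch(cmp$type,
      interval = list(type = "interval", lo = cmp$lo, hi = cmp$hi),
      polygon = list(type = "polygon", vertices = cmp$vertices),
      trimesh = {
        out <- list(type = "trimesh", vertices = cmp$vertices, faces = cmp$faces)
        if (!is.null(cmp$clip_box)) out$clip_box <- cmp$clip_box
        out
      })
  })
  obj <- list(schema = GATE_SCHEMA, dimension = region$d,
              space = region$space_tag, components = comps)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gate region from JSON
#'
#' @param path a file written by [write_gate()].
#' @return A [gate_region()].
#' @export
read_gate <- function(path) {
  cg_assert(file.exists(path), sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, GATE_SCHEMA)) {
    cg_abort(sprintf("unsupported gate schema '%s' (this build reads '%s')",
                     obj$schema %||% "<missing>", GATE_SCHEMA),
             class = "curvgate_schema_error")
  }
  as_mat <- function(x, ncol, int = FALSE) {
    if (is.list(x)) x <- do.call(rbind, lapply(x, unlist))
    m <- matrix(if (int) as.integer(as.matrix(x)) else as.numeric(as.matrix(x)),
                ncol = ncol)
    m
  }
  comps <- obj$components
  if (is.data.frame(comps)) comps <- split(comps, seq_len(nrow(comps)))
  comps <- lapply(comps, function(cmp) {
    cmp <- as.list(cmp)
    switch(cmp$type,
      interval = list(type = "interval", lo = as.numeric(cmp$lo),
                      hi = as.numeric(cmp$hi)),
      polygon = list(type = "polygon", vertices = as_mat(cmp$vertices, 2)),
      trimesh = {
        out <- list(type = "trimesh", vertices = as_mat(cmp$vertices, 3),
                    faces = as_mat(cmp$faces, 3, int = TRUE))
        if (!is.null(cmp$clip_box)) {
          out$clip_box <- matrix(as.numeric(as.matrix(cmp$clip_box)), nrow = 2)
        }
        out
      },
      cg_abort(sprintf("unknown component type '%s' in gate file", cmp$type),
               class = "curvgate_schema_error"))
  })
  gate_region(obj$dimension, unname(comps), space_tag = obj$space)
}

#' Write per-event membership as CSV
#'
#' @param membership logical vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_membership <- function(membership, path) {
  data.table::fwrite(
    data.frame(event_index = seq_along(membership),
               member = as.integer(membership)),
    path)
  invisible(path)
}
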