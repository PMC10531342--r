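# Minimal FCS 3.0/3.1 reader (list mode, read-only).
#
# Parses the 58-byte ASCII header, the delimited TEXT segment and a numeric
# DATA segment of type F (float), D (double) or I (unsigned integer with a
# uniform $PnB).  Channels are named by the $PnS stain name with $PnN as
# fallback.  This covers the standard instrument output needed here; it does
# not implement ANALYSIS segments, multi-dataset files ($NEXTDATA != 0) or
# escaped delimiters inside keyword values.

readFCSFile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stopf("unsupported FCS version '%s' in %s (FCS 3.0/3.1 only)", version, path)
  }
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(header, a, b))))
  textBeg <- off(11L, 18L); textEnd <- off(19L, 26L)
  dataBeg <- off(27L, 34L); dataEnd <- off(35L, 42L)
  if (is.na(textBeg) || is.na(textEnd) || textEnd <= textBeg) {
    stopf("corrupt FCS header in %s", path)
  }
  seek(con, textBeg)
  txt <- readChar(con, textEnd - textBeg + 1L, useBytes = TRUE)
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) < 2L) stopf("empty TEXT segment in %s", path)
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- stats::setNames(trimws(parts[seq(2L, length(parts), 2L)]),
                        toupper(trimws(parts[seq(1L, length(parts), 2L)])))
  kwGet <- function(key) if (key %in% names(kw)) kw[[key]] else NULL
  need <- function(key) {
    if (!key %in% names(kw)) stopf("FCS keyword %s missing in %s", key, path)
    kw[[key]]
  }
  nPar <- as.integer(need("$PAR"))
  nTot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  mode <- toupper(need("$MODE"))
  if (mode != "L") stopf("only list-mode ($MODE L) FCS files are supported")
  if (!is.na(dataBeg) && dataBeg == 0 && "$BEGINDATA" %in% names(kw)) {
    dataBeg <- as.numeric(kw[["$BEGINDATA"]])
    dataEnd <- as.numeric(kw[["$ENDDATA"]])
  }
  if (is.na(dataBeg) || dataBeg <= 0) stopf("no DATA segment offset in %s", path)

  channels <- vapply(seq_len(nPar), function(i) {
    s <- kwGet(sprintf("$P%dS", i))
    n <- kwGet(sprintf("$P%dN", i))
    if (!is.null(s) && nzchar(s)) s else if (!is.null(n)) n else sprintf("P%d", i)
  }, "")
  if (anyDuplicated(channels)) {
    stopf("duplicate channel names in %s: %s", path,
          paste(unique(channels[duplicated(channels)]), collapse = ", "))
  }

  seek(con, dataBeg)
  nVal <- nPar * nTot
  raw <- switch(dtype,
    F = readBin(con, "double", n = nVal, size = 4L, endian = endian),
    D = readBin(con, "double", n = nVal, size = 8L, endian = endian),
    I = {
      bits <- unique(vapply(seq_len(nPar),
                            function(i) as.integer(need(sprintf("$P%dB", i))), 1L))
      if (length(bits) != 1L || !bits %in% c(16L, 32L)) {
        stopf("integer FCS data requires a uniform $PnB of 16 or 32 (got %s)",
              paste(bits, collapse = ","))
      }
      if (bits == 16L) {
        readBin(con, "integer", n = nVal, size = 2L, signed = FALSE, endian = endian)
      } else {
        v <- readBin(con, "integer", n = nVal, size = 4L, endian = endian)
        v <- as.double(v)
        v[v < 0] <- v[v < 0] + 4294967296
        v
      }
    },
    stopf("unsupported $DATATYPE '%s' in %s", dtype, path)
  )
  if (length(raw) != nVal) {
    stopf("truncated DATA segment in %s: expected %d values, read %d",
          path, nVal, length(raw))
  }
  list(data = matrix(as.double(raw), nrow = nTot, ncol = nPar, byrow = TRUE),
       channels = channels, keywords = kw, version = version)
}
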