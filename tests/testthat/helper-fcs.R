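# Minimal FCS 3.0 writer used only to build test fixtures in code
# (list mode, float32 data, little endian).
writeTestFCS <- function(path, data, channels = colnames(data),
                         stains = NULL) {
  n <- nrow(data); p <- ncol(data)
  delim <- "/"
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", p, "$TOT", n, "$NEXTDATA", "0")
  for (i in seq_len(p)) {
    kw <- c(kw, sprintf("$P%dN", i), channels[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), "262144")
    if (!is.null(stains) && nzchar(stains[i])) {
      kw <- c(kw, sprintf("$P%dS", i), stains[i])
    }
  }
  txt <- paste0(delim, paste(kw, collapse = delim), delim)
  textStart <- 58L
  textEnd <- textStart + nchar(txt) - 1L
  dataStart <- textEnd + 1L
  dataEnd <- dataStart + 4L * n * p - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    textStart, textEnd, dataStart, dataEnd, 0L, 0L)
  stopifnot(nchar(header) == 58L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.numeric(t(data)), con, size = 4L, endian = "little")
  invisible(path)
}
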