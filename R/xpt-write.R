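# SAS transport (XPT) v5 writer.
#
# The transport format is a sequence of 80-byte card images: library and
# member header records, one 140-byte NAMESTR per variable (packed, blank
# padded), then observation records with numerics stored as 8-byte IBM
# hexadecimal floating point (big endian) and character values space-padded
# ASCII. IEEE doubles convert losslessly: the IBM fraction carries 56 bits
# against IEEE's 53, and hex alignment costs at most 3 bits.

xpt_pad <- function(s, n) {
  raw_s <- charToRaw(substr(s, 1L, n))
  c(raw_s, rep(charToRaw(" "), n - length(raw_s)))
}

xpt_datetime <- function() {
  # ddMMMyy:hh:mm:ss with English month abbreviation regardless of locale
  t <- as.POSIXlt(Sys.time(), tz = "UTC")
  mons <- c("JAN", "FEB", "MAR", "APR", "MAY", "JUN",
            "JUL", "AUG", "SEP", "OCT", "NOV", "DEC")
  sprintf("%02d%s%02d:%02d:%02d:%02d", t$mday, mons[t$mon + 1L],
          as.integer(t$year) %% 100L, as.integer(t$hour), as.integer(t$min),
          as.integer(t$sec))
}

# one IEEE double -> 8 bytes of IBM hex float
ieee_to_ibm <- function(x) {
  if (is.na(x)) return(as.raw(c(0x2e, rep(0, 7))))   # SAS missing "."
  if (x == 0) return(as.raw(rep(0, 8)))
  s <- if (x < 0) 0x80 else 0x00
  m <- abs(x)
  e16 <- floor(log(m, base = 16)) + 1
  f <- m / 16^e16
  while (f >= 1) { e16 <- e16 + 1; f <- f / 16 }
  while (f < 1 / 16) { e16 <- e16 - 1; f <- f * 16 }
  if (e16 + 64 < 0 || e16 + 64 > 127) stop("value out of IBM float range: ", x)
  bytes <- integer(7)
  for (i in 1:7) {           # exact: f has <= 56 significant bits here
    f <- f * 256
    bytes[i] <- floor(f)
    f <- f - bytes[i]
  }
  as.raw(c(bitwOr(s, as.integer(e16 + 64)), bytes))
}

xpt_header_record <- function(name, tail = "000000000000000000000000000000  ") {
  rec <- sprintf("HEADER RECORD*******%-8sHEADER RECORD!!!!!!!%s", name, tail)
  stopifnot(nchar(rec) == 80L)
  charToRaw(rec)
}

#' Write a data frame as a SAS transport (XPT) v5 file
#'
#' Numeric columns are stored as 8-byte IBM hexadecimal floats (lossless for
#' IEEE doubles), character/factor columns as fixed-width space-padded ASCII,
#' and `NA`s as the SAS missing value. Column names are truncated to 8
#' characters and upper-cased, the v5 convention; they must remain unique.
#' Files written here are read back by `foreign::read.xport()`.
#'
#' @param data a data frame (logical columns are stored as 0/1 numerics).
#' @param path destination file.
#' @param dsname member (dataset) name inside the transport file.
#' @return `path`, invisibly.
#' @export
write_xpt <- function(data, path, dsname = "DATA") {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  nm <- toupper(substr(names(data), 1L, 8L))
  if (anyDuplicated(nm))
    stop("column names collide after truncation to 8 characters: ",
         paste(nm[duplicated(nm)], collapse = ", "))
  cols <- lapply(data, function(col) {
    if (is.logical(col)) as.numeric(col)
    else if (is.factor(col)) as.character(col)
    else col
  })
  is_char <- vapply(cols, is.character, TRUE)
  widths <- ifelse(is_char,
                   vapply(cols, function(c) max(1L, nchar(c[!is.na(c)], type = "bytes"), 0L), 1L),
                   8L)
  widths <- pmin(widths, 200L)
  ts <- xpt_datetime()

  out <- file(path, "wb")
  on.exit(close(out))
  wr <- function(r) writeBin(r, out)

  wr(xpt_header_record("LIBRARY "))
  wr(c(xpt_pad("SAS", 8), xpt_pad("SAS", 8), xpt_pad("SASLIB", 8),
       xpt_pad("9.4", 8), xpt_pad("R", 8), xpt_pad("", 24), xpt_pad(ts, 16)))
  wr(c(xpt_pad(ts, 16), xpt_pad("", 64)))
  wr(xpt_header_record("MEMBER  ", "000000000000000001600000000140  "))
  wr(xpt_header_record("DSCRPTR "))
  wr(c(xpt_pad("SAS", 8), xpt_pad(toupper(dsname), 8), xpt_pad("SASDATA", 8),
       xpt_pad("9.4", 8), xpt_pad("R", 8), xpt_pad("", 24), xpt_pad(ts, 16)))
  wr(c(xpt_pad(ts, 16), xpt_pad("", 16), xpt_pad("", 40), xpt_pad("", 8)))
  wr(xpt_header_record("NAMESTR ",
                       sprintf("000000%04d00000000000000000000  ", length(cols))))

  short2 <- function(v) writeBin(as.integer(v), out, size = 2L, endian = "big")
  long4 <- function(v) writeBin(as.integer(v), out, size = 4L, endian = "big")
  pos <- 0L
  namestr_bytes <- 0L
  for (j in seq_along(cols)) {
    short2(if (is_char[j]) 2L else 1L)  # ntype
    short2(0L)                          # nhfun
    short2(widths[j])                   # nlng
    short2(j)                           # nvar0
    wr(xpt_pad(nm[j], 8))               # nname
    wr(xpt_pad(names(data)[j], 40))     # nlabel
    wr(xpt_pad("", 8)); short2(0L); short2(0L); short2(0L)  # nform/nfl/nfd/nfj
    wr(xpt_pad("", 2)); wr(xpt_pad("", 8)); short2(0L); short2(0L)  # nfill/niform/nifl/nifd
    long4(pos)                          # npos
    wr(as.raw(rep(0x20, 52)))           # rest
    pos <- pos + widths[j]
    namestr_bytes <- namestr_bytes + 140L
  }
  pad <- (80L - namestr_bytes %% 80L) %% 80L
  if (pad) wr(as.raw(rep(0x20, pad)))

  wr(xpt_header_record("OBS     "))
  reclen <- sum(widths)
  obs_bytes <- 0L
  for (i in seq_len(nrow(data))) {
    for (j in seq_along(cols)) {
      v <- cols[[j]][i]
      if (is_char[j]) {
        wr(xpt_pad(if (is.na(v)) "" else v, widths[j]))
      } else {
        wr(ieee_to_ibm(v))
      }
    }
    obs_bytes <- obs_bytes + reclen
  }
  pad <- (80L - obs_bytes %% 80L) %% 80L
  if (pad) wr(as.raw(rep(0x20, pad)))
  invisible(path)
}
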