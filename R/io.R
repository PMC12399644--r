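# ---------------------------------------------------------------------------
# On-disk interchange: frames and label maps as portable graymaps (PGM,
# binary P5 for frames, plain text P2 for labels) plus a JSON metadata file.
# PGM is used because it is self-describing and dependency-free; any image
# tool can convert it to PNG.
# ---------------------------------------------------------------------------

write_pgm <- function(m, path, maxval = 255L, ascii = FALSE) {
  v <- as.integer(round(t(m)))  # PGM is row-major
  v <- pmin(pmax(v, 0L), maxval)
  if (ascii) {
    con <- file(path, "w")
    writeLines(sprintf("P2\n%d %d\n%d", ncol(m), nrow(m), maxval), con)
    writeLines(paste(v, collapse = " "), con)
    close(con)
  } else {
    con <- file(path, "wb")
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(m), nrow(m), maxval), con,
              eos = NULL)
    writeBin(as.raw(v), con)
    close(con)
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  hdr <- character(0)
  while (length(hdr) < 3) {
    ln <- readLines(con, 1)
    ln <- sub("#.*", "", ln)
    hdr <- c(hdr, strsplit(trimws(ln), "\\s+")[[1]])
  }
  w <- as.integer(hdr[1]); h <- as.integer(hdr[2]); mx <- as.integer(hdr[3])
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", w * h))
  } else if (magic == "P2") {
    v <- scan(con, integer(), n = w * h, quiet = TRUE)
  } else stop("not a PGM file")
  matrix(v, h, w, byrow = TRUE)
}

#' Write a phantom (video, labels, metadata) to a directory
#'
#' Frames become 8-bit binary PGM files, label maps plain-text PGM files,
#' and all annotation metadata (ED/ES indices, measurement segments, pixel
#' spacing, cycle schedule) a single JSON file.
#'
#' @param phantom output of [generate_phantom()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- phantom$video; a <- phantom$annotation
  n <- dim(v$frames)[3]
  for (t in seq_len(n)) {
    write_pgm(v$frames[, , t] * 255, file.path(dir, sprintf("frame_%03d.pgm",
                                                            t - 1L)))
    write_pgm(a$labels[, , t], file.path(dir, sprintf("label_%03d.pgm",
                                                      t - 1L)),
              maxval = max(1L, a$n_classes - 1L), ascii = TRUE)
  }
  meta <- list(n_frames = n, times = v$times, mm_per_px = v$mm_per_px,
               ed_frames = a$ed_frames, es_frames = a$es_frames,
               cycle_schedule = a$cycle_schedule,
               classes = as.list(a$classes),
               segments = a$segments)
  jsonlite::write_json(meta, file.path(dir, "annotation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom directory written by [write_phantom()]
#' @param dir directory path
#' @return list with `frames`, `labels`, `meta`
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "annotation.json"),
                              simplifyVector = TRUE)
  n <- meta$n_frames
  f1 <- read_pgm(file.path(dir, "frame_000.pgm"))
  frames <- array(0, c(nrow(f1), ncol(f1), n))
  labels <- array(0L, c(nrow(f1), ncol(f1), n))
  for (t in seq_len(n)) {
    frames[, , t] <- read_pgm(file.path(dir, sprintf("frame_%03d.pgm",
                                                     t - 1L))) / 255
    labels[, , t] <- read_pgm(file.path(dir, sprintf("label_%03d.pgm",
                                                     t - 1L)))
  }
  list(frames = frames, labels = labels, meta = meta)
}
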