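#' Write trajectory frames as extended XYZ
#'
#' One block per frame: the particle count, a comment line carrying the
#' simulated time and the column layout
#' (`Properties=id:I:1:species:S:1:slice:I:1:pos:R:3`), then one record per
#' particle: id, species (`F` fluid / `S` solid), slice id (-1 for fluid) and
#' the three coordinates. The dialect is readable by common
#' particle-visualisation tools and round-trips through [read_trajectory()].
#'
#' @param frames list of frames, each a list with `time`, `id`, `species`,
#'   `slice`, `pos` (n x 3 matrix).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path) {
  if (length(frames) == 0) stop("no frames to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$pos)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      "Time=%.9g Properties=id:I:1:species:S:1:slice:I:1:pos:R:3", fr$time),
      con)
    writeLines(sprintf("%d %s %d %.10e %.10e %.10e",
                       fr$id, fr$species, fr$slice,
                       fr$pos[, 1], fr$pos[, 2], fr$pos[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory written by [write_trajectory()]
#'
#' @param path file to read.
#' @return list of frames in the same layout [write_trajectory()] accepts.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  k <- 1
  while (k <= length(lines)) {
    n <- as.integer(lines[k])
    hdr <- lines[k + 1]
    time <- as.numeric(sub("^Time=([^ ]+).*$", "\\1", hdr))
    rec <- lines[(k + 2):(k + 1 + n)]
    parts <- strsplit(rec, " ", fixed = TRUE)
    m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
    frames[[length(frames) + 1]] <- list(
      time = time,
      id = as.integer(m[, 1]),
      species = m[, 2],
      slice = as.integer(m[, 3]),
      pos = cbind(as.numeric(m[, 4]), as.numeric(m[, 5]), as.numeric(m[, 6])))
    k <- k + 2 + n
  }
  frames
}
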