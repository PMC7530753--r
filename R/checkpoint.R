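# 32-bit FNV-1a hash of a string; small content fingerprint for checkpoints
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b)  # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

config_hash <- function(...) {
  fnv1a32(jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = NA))
}

#' Save a checkpoint
#'
#' Writes a JSON container of named numeric arrays: the network weights and
#' biases (`W1`, `b1`, ...), optionally the full particle state of a tube
#' environment (`pos`, `vel`, `rho`, `wind`), a content hash, the recorded
#' seed, and any extra metadata. Plain text, portable, human-inspectable.
#'
#' @param path output file.
#' @param net optional `qnet`.
#' @param env optional `tube_env` whose particle state should be stored.
#' @param seed seed to record.
#' @param extra named list of additional scalar metadata.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(path, net = NULL, env = NULL, seed = NULL,
                            extra = list()) {
  obj <- list(format = "peristim-checkpoint", version = 1L)
  if (!is.null(net)) {
    obj$sizes <- net$sizes
    for (l in seq_along(net$W)) {
      obj[[paste0("W", l)]] <- net$W[[l]]
      obj[[paste0("b", l)]] <- net$b[[l]]
    }
  }
  if (!is.null(env)) {
    obj$pos <- env$raw$pos
    obj$vel <- env$raw$vel
    obj$rho <- env$raw$rho
    obj$wind <- env$raw$wind
    obj$state <- env$raw$state
  }
  obj$seed <- seed
  obj <- c(obj, extra)
  obj$hash <- config_hash(obj$sizes, obj$seed, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return list with `net` (a `qnet`, when weights are present; optimiser
#'   state starts fresh), any stored particle arrays, and the metadata.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "peristim-checkpoint"))
    stop("not a recognised checkpoint file")
  out <- obj
  if (!is.null(obj$sizes)) {
    sizes <- as.integer(obj$sizes)
    net <- qnet(sizes, seed = NULL)
    for (l in seq_len(length(sizes) - 1)) {
      W <- as.matrix(obj[[paste0("W", l)]])
      if (nrow(W) != sizes[l] || ncol(W) != sizes[l + 1])
        stop("incompatible checkpoint: weight shapes do not match sizes")
      net$W[[l]] <- W
      net$b[[l]] <- as.numeric(obj[[paste0("b", l)]])
    }
    out$net <- net
  }
  out
}
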