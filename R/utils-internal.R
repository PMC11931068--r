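# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
dga_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "dganet_error", "error", "condition")))
}

#' Run code with a temporary RNG seed, restoring the caller's RNG state.
#' Keeps all package randomness reproducible without clobbering the session.
#' @noRd
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Derive a child seed from a root seed and a stage label, staying < 2^31.
#' @noRd
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647L)
}

#' Numerically stable log(sum(exp(x))).
#' @noRd
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Atomic file write: write to a sibling temp file, then rename into place.
#' @noRd
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
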