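# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators are reproducible
#' without disturbing the caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# condition-based log channel: messages with a class so callers can mute
pb_log <- function(..., level = "info") {
  message(structure(
    class = c("pathbridge_log", "message", "condition"),
    list(message = paste0("[pathbridge ", level, "] ", ..., "\n"),
         call = NULL)))
}

# Write text atomically: temp file in the same directory, then rename.
write_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")  # binary: byte-stable newlines
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("could not move temporary file onto ", path)
  }
  invisible(path)
}

stop_pb <- function(msg, class) {
  stop(structure(class = c(class, "pathbridge_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count1 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == as.integer(x) && x >= 1

# Shortest decimal that reparses to the same double: numeric attributes are
# byte-stable AND round-trip exactly through write/read.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    for (d in c(15L, 16L, 17L)) {
      s <- format(v, trim = TRUE, scientific = FALSE, digits = d)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}
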