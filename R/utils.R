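# Internal helpers shared across modules.

# Wrap an angle in degrees to (-180, 180].
wrap_deg <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    stop_invalid(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_invalid(name, " must be >= ", lower)
  if (x > upper)
    stop_invalid(name, " must be <= ", upper)
  invisible(x)
}

# Write a file atomically: write to a temp file in the same directory, then
# rename, so an interrupted run never leaves a truncated output.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = ".tmp_", tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop_invalid("failed to move temporary file onto ", path)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  atomic_write(path, function(tmp) {
    write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  })
}

write_json_atomic <- function(x, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
}
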