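# Internal helpers: argument checks, seed derivation, formatted table output.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("fateline_config_error", "error")))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_config("'", name, "' must be a single non-missing number")
  }
  if (x < lower || x > upper) {
    stop_config("'", name, "' must be in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_config("'", name, "' must be TRUE or FALSE")
  }
  invisible(x)
}

#' Derive a stage-specific seed from a global seed
#'
#' One global seed drives the whole pipeline; each stage gets its own stream
#' by hashing the stage name into an offset, so toggling stages on or off
#' never shifts the random numbers another stage sees. The result always fits
#' a 32-bit R integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1L, "simulate")
derive_seed <- function(seed, stage) {
  check_scalar_number(seed, "seed")
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1987654321
  as.integer((abs(as.numeric(seed)) + h) %% .Machine$integer.max)
}

# Tab-delimited writer used for all tabular outputs: UTF-8, single header
# line, floats at 10 significant digits so reruns are byte-identical.
write_tsv <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    lines <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}
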