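# Plain-text interchange: TSV with "#! key value" metadata header lines.
# Full-precision decimal serialization (%.17g) guarantees exact round-trips.

write_meta <- function(con, meta) {
  for (k in names(meta))
    writeLines(sprintf("#! %s\t%s", k, format(meta[[k]], digits = 17)), con)
}

read_meta <- function(lines) {
  meta_lines <- grep("^#! ", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    parts <- strsplit(sub("^#! ", "", ln), "\t")[[1]]
    out[[parts[1]]] <- utils::type.convert(parts[2], as.is = TRUE)
  }
  out
}

#' Read and write long-format synapse trajectory tables
#'
#' The on-disk format is a TSV with columns `synapse_id`, `time`,
#' `strength`, preceded by `#!`-prefixed metadata lines. Reading validates
#' the table (nonnegative strengths, strictly increasing times per synapse,
#' no duplicate records) and reports offending lines.
#'
#' @param table a `trajectory_table`.
#' @param path file path.
#' @return `read_trajectory_table` returns a validated `trajectory_table`.
#' @export
write_trajectory_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, attr(table, "metadata") %||% list())
  writeLines("synapse_id\ttime\tstrength", con)
  writeLines(sprintf("%s\t%.17g\t%.17g",
                     table$synapse_id, table$time, table$strength), con)
  invisible(path)
}

#' @rdname write_trajectory_table
#' @export
read_trajectory_table <- function(path) {
  lines <- readLines(path)
  meta <- read_meta(lines)
  body_start <- which(!startsWith(lines, "#!"))[1]
  header <- strsplit(lines[body_start], "\t")[[1]]
  need <- c("synapse_id", "time", "strength")
  if (!all(need %in% header))
    stop_format(paste("missing columns:",
                      paste(setdiff(need, header), collapse = ", ")))
  body <- lines[-seq_len(body_start)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad_len <- which(lengths(parts) != length(header))
  if (length(bad_len))
    stop_format(sprintf("malformed row at line %d", body_start + bad_len[1]))
  m <- matrix(unlist(parts), ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  df <- data.frame(synapse_id = as.integer(m[, "synapse_id"]),
                   time = as.numeric(m[, "time"]),
                   strength = as.numeric(m[, "strength"]))
  neg <- which(df$strength < 0 | !is.finite(df$strength))
  if (length(neg))
    stop_format(sprintf("negative or non-numeric strength at line %d",
                        body_start + neg[1]))
  ord <- order(df$synapse_id, df$time)
  nonmono <- tapply(df$time[ord], df$synapse_id[ord],
                    function(x) any(diff(x) <= 0))
  if (any(unlist(nonmono)))
    stop_format("duplicate or non-increasing times within a synapse")
  trajectory_table(df, metadata = meta)
}

#' Read and write synaptic states
#'
#' Serializes the factor tensor, inhibitory currents and metadata of a
#' `synaptic_state` as a single long-format TSV (`record` column `u` for
#' factor entries, `inh` for inhibitory currents) with full-precision
#' decimals, so the round-trip is exact, including hard zeros of pruned
#' components.
#'
#' @param state a `synaptic_state`.
#' @param path file path.
#' @param expect_z optional factor count the file must match.
#' @return `read_state` returns the `synaptic_state`.
#' @export
write_state <- function(state, path) {
  stopifnot(inherits(state, "synaptic_state"))
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(N = state$N, z = state$z))
  writeLines("record\ti\tj\tk\tvalue", con)
  u <- state$u
  idx <- which(u != 0, arr.ind = TRUE)
  if (nrow(idx))
    writeLines(sprintf("u\t%d\t%d\t%d\t%.17g",
                       idx[, 1], idx[, 2], idx[, 3], u[idx]), con)
  writeLines(sprintf("inh\t%d\t0\t0\t%.17g", seq_len(state$N), state$I_inh), con)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path, expect_z = NULL) {
  lines <- readLines(path)
  meta <- read_meta(lines)
  if (is.null(meta$N) || is.null(meta$z))
    stop_format("state file is missing N/z metadata")
  if (!is.null(expect_z) && meta$z != expect_z)
    stop_format(sprintf("state file has z = %d, expected %d", meta$z, expect_z))
  body_start <- which(!startsWith(lines, "#!"))[1]
  df <- utils::read.table(text = lines[-seq_len(body_start)], sep = "\t",
                          col.names = c("record", "i", "j", "k", "value"))
  N <- meta$N; z <- meta$z
  uu <- df[df$record == "u", ]
  if (nrow(uu) && (max(uu$i, uu$j) > N || max(uu$k) > z))
    stop_format("factor indices exceed declared dimensions")
  u <- array(0, c(N, N, z))
  u[cbind(uu$i, uu$j, uu$k)] <- uu$value
  inh <- df[df$record == "inh", ]
  if (nrow(inh) != N) stop_format("inhibitory record count does not match N")
  I_inh <- numeric(N)
  I_inh[inh$i] <- inh$value
  synaptic_state(u, I_inh)
}

#' Read and write pattern sets
#'
#' Patterns are stored as rows of 0/1 characters (one row per pattern) after
#' `#!` metadata lines recording `N`, `M`, `f` and the seed.
#'
#' @param patterns a `pattern_set`.
#' @param path file path.
#' @return `read_patterns` returns the `pattern_set`.
#' @export
write_patterns <- function(patterns, path) {
  stopifnot(inherits(patterns, "pattern_set"))
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(N = patterns$N, M = patterns$M, f = patterns$f,
                       seed = patterns$seed %||% NA))
  writeLines(apply(patterns$xi, 1, paste, collapse = ""), con)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  meta <- read_meta(lines)
  rows <- lines[!startsWith(lines, "#!")]
  rows <- rows[nzchar(rows)]
  xi <- do.call(rbind, lapply(strsplit(rows, ""), as.numeric))
  if (!is.null(meta$N) && ncol(xi) != meta$N)
    stop_format("pattern width does not match declared N")
  pattern_set(xi, f = meta$f,
              seed = if (!is.null(meta$seed) && !is.na(meta$seed)) meta$seed)
}
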