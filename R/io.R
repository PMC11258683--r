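## Delimited-text interchange. All files are comma-delimited with a header row
## and a leading format-version comment; times in seconds, concentrations in
## nM, rate constants in M^-1 s^-1 (bimolecular) or s^-1 (unimolecular) with
## an explicit unit column. Numerics survive a round trip to at least 12
## significant digits.

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

write_kp_csv <- function(df, path, format_tag) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kproof_format: ", format_tag, " v1"), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

read_kp_csv <- function(path, format_tag) {
  first <- readLines(path, n = 1)
  if (!grepl(paste0("kproof_format: ", format_tag), first, fixed = TRUE))
    stop("'", path, "' is not a ", format_tag, " file")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a trajectory as delimited text
#'
#' One `time_s` column plus one column per species (nM).
#'
#' @param trajectory A `kp_trajectory`.
#' @param path File path.
#' @return `read_trajectory` returns a `kp_trajectory` (without strand
#'   bookkeeping, which is not serialized).
#' @export
write_trajectory <- function(trajectory, path) {
  df <- data.frame(time_s = fmt_num(trajectory$times))
  for (s in colnames(trajectory$conc)) df[[s]] <- fmt_num(trajectory$conc[, s])
  write_kp_csv(df, path, "trajectory")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read_kp_csv(path, "trajectory")
  conc <- as.matrix(df[, -1, drop = FALSE])
  structure(list(times = df$time_s, conc = conc, kind = NA_character_,
                 strands = list()),
            class = "kp_trajectory")
}

#' Write / read a signal trace
#'
#' Columns: `well_id`, `channel`, `time_s`, `signal`.
#' @param trace A `kp_signal_trace`.
#' @param path File path.
#' @export
write_signal_trace <- function(trace, path) {
  df <- data.frame(well_id = trace$well_id, channel = trace$channel,
                   time_s = fmt_num(trace$times),
                   signal = fmt_num(trace$signal))
  write_kp_csv(df, path, "signal_trace")
  invisible(path)
}

#' @rdname write_signal_trace
#' @export
read_signal_trace <- function(path) {
  df <- read_kp_csv(path, "signal_trace")
  structure(list(well_id = df$well_id[1], channel = df$channel[1],
                 times = df$time_s, signal = df$signal),
            class = "kp_signal_trace")
}

#' Write / read a rate set
#'
#' Columns: `rate`, `value`, `unit`, `status` (known/unknown), `low`, `high`
#' (search bounds, empty for known rates).
#'
#' @param rates A `kp_rates`.
#' @param path File path.
#' @param network For reading: the `kp_network` the rates belong to.
#' @export
write_rates <- function(rates, path) {
  u <- ifelse(rates$molecularity == 2L, "M-1s-1", "s-1")
  lo <- vapply(names(rates$values), function(nm)
    if (nm %in% rates$unknown) rates$bounds[[nm]][1] else NA_real_, 0)
  hi <- vapply(names(rates$values), function(nm)
    if (nm %in% rates$unknown) rates$bounds[[nm]][2] else NA_real_, 0)
  df <- data.frame(rate = names(rates$values),
                   value = fmt_num(unname(rates$values)), unit = unname(u),
                   status = ifelse(names(rates$values) %in% rates$unknown,
                                   "unknown", "known"),
                   low = ifelse(is.na(lo), "", fmt_num(lo)),
                   high = ifelse(is.na(hi), "", fmt_num(hi)))
  write_kp_csv(df, path, "rate_set")
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path, network) {
  df <- read_kp_csv(path, "rate_set")
  vals <- stats::setNames(as.numeric(df$value), df$rate)
  unknown <- df$rate[df$status == "unknown"]
  bounds <- list()
  for (i in which(df$status == "unknown"))
    bounds[[df$rate[i]]] <- c(as.numeric(df$low[i]), as.numeric(df$high[i]))
  rate_set(network, vals, unknown = unknown, bounds = bounds)
}

#' Write / read a network descriptor
#'
#' Human-readable key-value config: species as `name = strand+strand [roles]`,
#' reactions as `A + B -> C + D @ rate [rev reverse_rate]`.
#'
#' @param network A `kp_network`.
#' @param path File path.
#' @export
write_network_config <- function(network, path) {
  lines <- c("format_version: 1", paste0("kind: ", network$kind))
  for (s in network$species)
    lines <- c(lines, paste0("species: ", s$name, " = ",
                             paste(s$strands, collapse = "+"), " [",
                             paste(s$roles, collapse = ","), "]"))
  for (r in network$reactions)
    lines <- c(lines, paste0("reaction: ",
                             paste(r$reactants, collapse = " + "), " -> ",
                             paste(r$products, collapse = " + "),
                             " @ ", r$rate,
                             if (!is.na(r$reverse)) paste0(" rev ", r$reverse)
                             else ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  lines <- readLines(path)
  kind <- sub("^kind: ", "", grep("^kind: ", lines, value = TRUE))
  species <- lapply(grep("^species: ", lines, value = TRUE), function(ln) {
    m <- regmatches(ln, regexec(
      "^species: (\\S+) = (\\S+) \\[(.*)\\]$", ln))[[1]]
    if (length(m) != 4) stop("malformed species line: ", ln)
    kp_species(m[2], strsplit(m[3], "+", fixed = TRUE)[[1]],
               if (nzchar(m[4])) strsplit(m[4], ",", fixed = TRUE)[[1]]
               else character(0))
  })
  reactions <- lapply(grep("^reaction: ", lines, value = TRUE), function(ln) {
    m <- regmatches(ln, regexec(
      "^reaction: (.+) -> (.+) @ (\\S+)( rev (\\S+))?$", ln))[[1]]
    if (length(m) < 4) stop("malformed reaction line: ", ln)
    kp_reaction(trimws(strsplit(m[2], " + ", fixed = TRUE)[[1]]),
                trimws(strsplit(m[3], " + ", fixed = TRUE)[[1]]),
                m[4], if (nzchar(m[6])) m[6] else NA_character_)
  })
  new_network(kind, species, reactions)
}

#' Write a synthetic study to disk
#'
#' One signal-trace file per well and channel, one ground-truth trajectory
#' file per well, and a `manifest.csv` tying them together with the design
#' metadata and seeds.
#'
#' @param study A `kp_study`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ds in study$datasets) {
    truth_file <- paste0(ds$well_id, "_truth.csv")
    write_trajectory(ds$truth, file.path(dir, truth_file))
    for (ch in names(ds$traces)) {
      f <- paste0(ds$well_id, "_", ch, ".csv")
      write_signal_trace(ds$traces[[ch]], file.path(dir, f))
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = ds$well_id, class = ds$class %||% "", channel = ch,
        variant = ds$variant %||% "", trace_file = f,
        truth_file = truth_file, seed = ds$seed,
        dead_time_s = ds$design$dead_time, duration_s = ds$design$duration)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write_kp_csv(manifest, path, "study_manifest")
  invisible(path)
}

#' Read a study manifest
#'
#' Checks that every referenced file resolves next to the manifest.
#'
#' @param path Path to a `manifest.csv` written by [write_study()].
#' @return The manifest data frame, with an attribute `dir`.
#' @export
read_study_manifest <- function(path) {
  df <- read_kp_csv(path, "study_manifest")
  dir <- dirname(path)
  for (f in unique(c(df$trace_file, df$truth_file)))
    if (!file.exists(file.path(dir, f)))
      stop("manifest references missing file: ", f)
  attr(df, "dir") <- dir
  df
}
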