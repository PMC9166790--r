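# Sequence and configuration I/O. FASTA parsing is delegated to Biostrings
# after a light structural pre-scan that produces line-numbered errors for
# malformed files; plain-text input is one sequence per line.

#' Read peptide sequences from FASTA or plain text
#'
#' Sequences are uppercased and validated against the 20 standard one-letter
#' residue codes; the end cursor `"@"` is forbidden in inputs. FASTA wrapped
#' lines are joined; in text format blank lines are skipped.
#'
#' @param path Path to an existing file.
#' @param format "fasta", "txt", or "auto" (by extension, falling back to a
#'   leading `>` probe).
#' @return Character vector of sequences (named by FASTA headers when
#'   applicable).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fasta", "fa", "faa", "fas")) "fasta"
      else if (ext %in% c("txt", "seq")) "txt"
      else {
        first <- readLines(path, n = 1)
        if (length(first) && startsWith(first, ">")) "fasta" else "txt"
      }
  }
  seqs <- if (format == "fasta") {
    lines <- readLines(path)
    nonblank <- which(nzchar(trimws(lines)))
    if (!length(nonblank)) stop("empty file: ", path)
    if (!startsWith(trimws(lines[nonblank[1]]), ">"))
      stop("malformed FASTA: sequence before header at line ", nonblank[1])
    x <- Biostrings::readBStringSet(path)
    stats::setNames(as.character(x), names(x))
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty file: ", path)
    lines
  }
  seqs <- toupper(seqs)
  if (!length(seqs) || any(nchar(seqs) == 0))
    stop("empty sequence in ", path)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    bad <- setdiff(unique(chars), .aa20)
    if (length(bad))
      stop("illegal character '", bad[1], "' in sequence ", i)
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param sequences Character vector.
#' @param path Output path.
#' @param headers Optional headers; defaults to `seq_1 ...` or existing
#'   names.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, headers = NULL) {
  stopifnot(length(sequences) >= 1)
  if (is.null(headers))
    headers <- if (!is.null(names(sequences)) && all(nzchar(names(sequences))))
      names(sequences) else sprintf("seq_%d", seq_along(sequences))
  x <- Biostrings::BStringSet(stats::setNames(as.character(sequences), headers))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export a conductance or voltage trace as CSV
#'
#' @param time_s Times (s).
#' @param values Trace values.
#' @param path Output path.
#' @param value_name Column name for the values (units embedded, e.g.
#'   `conductance_S`, `v_c_V`).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(time_s, values, path, value_name = "conductance_S") {
  df <- data.frame(time_s = time_s, v = values)
  names(df)[2] <- value_name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Nested list mirroring the module parameters; unknown keys in a user
#' config are rejected by [load_config()].
#'
#' @param seed Global RNG seed; stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    synth = list(n_sequences = 200, length_range = c(7, 48),
                 target_charge = 2.28, amphipathic_period = 4),
    corpus_file = NULL,
    reservoir = list(duties = c(0.05, 0.10, 0.15, 0.20), set_amplitude = 4,
                     slot_time_scale = 13),
    readout = list(epochs = 5, lr = 1e-3, n_hidden = 500,
                   corpus_alphabet = FALSE),
    generation = list(n = 50, max_len = 60),
    eval = list(pH = 7.0)
  )
}

#' Load a pipeline configuration from JSON or YAML
#'
#' Values override the defaults; unknown keys are an error.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @param seed Fallback global seed if the file does not set one.
#' @return Merged configuration list.
#' @export
load_config <- function(path, seed = 1) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config(seed)
  merge_into <- function(base, user, prefix = "") {
    for (k in names(user)) {
      if (!k %in% names(base))
        stop("unknown configuration key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(user[[k]]))
        base[[k]] <- merge_into(base[[k]], user[[k]], paste0(prefix, k, "."))
      else base[[k]] <- user[[k]]
    }
    base
  }
  merge_into(base, user)
}
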