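# BrainVision triplet input/output.
#
# One dialect only: multiplexed IEEE float32 binary, resolution 1 microvolt.
# Anything else is rejected loudly — the goal is a bit-exact round trip for
# simulated sessions, not broad vendor compatibility.

#' Write a session to a BrainVision file triplet
#'
#' Writes `<basepath>.vhdr` (header), `<basepath>.vmrk` (markers) and
#' `<basepath>.eeg` (multiplexed IEEE float32 binary, little-endian). One
#' stimulus marker is written per event, with description `S<code>` at the
#' event's 1-based sample position.
#'
#' @param raw A [raw_session()].
#' @param basepath Output path without extension.
#' @return Invisibly, the three file paths.
#' @export
write_brainvision <- function(raw, basepath) {
  stopifnot(inherits(raw, "raw_session"))
  dir <- dirname(basepath)
  if (!dir.exists(dir)) stopf("output directory does not exist: %s", dir)
  base <- basename(basepath)
  vhdr <- paste0(basepath, ".vhdr")
  vmrk <- paste0(basepath, ".vmrk")
  eeg <- paste0(basepath, ".eeg")

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(raw$data)),
    sprintf("SamplingInterval=%s", format(1e6 / raw$fs, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1", seq_len(nrow(raw$data)), raw$channel_names)
  )
  writeLines(hdr, vhdr)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  )
  if (nrow(raw$events) > 0) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,S%d,%d,1,0",
                        seq_len(nrow(raw$events)) + 1L,
                        raw$events$code, raw$events$sample))
  }
  writeLines(mk, vmrk)

  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(raw$data), con, size = 4, endian = "little")
  invisible(c(vhdr = vhdr, vmrk = vmrk, eeg = eeg))
}

.bv_parse_ini <- function(lines) {
  kv <- grep("^[A-Za-z0-9]+=", lines, value = TRUE)
  pos <- regexpr("=", kv, fixed = TRUE)
  stats::setNames(substring(kv, pos + 1), substring(kv, 1, pos - 1))
}

#' Read a BrainVision file triplet
#'
#' Reads the multiplexed IEEE float32 dialect written by
#' [write_brainvision()]; other binary layouts are rejected with an error
#' naming the offending dialect. Stimulus markers become events; event
#' labels are `task_names[code]` when a task vocabulary is supplied,
#' otherwise `"S<code>"`.
#'
#' @param header_path Path to the `.vhdr` file.
#' @param task_names Optional vocabulary mapping marker codes to labels.
#' @param participant_id Identifier stored in the session.
#' @return A [raw_session()].
#' @export
read_brainvision <- function(header_path, task_names = NULL,
                             participant_id = "P01") {
  if (!file.exists(header_path)) stopf("header file not found: %s",
                                       header_path)
  lines <- readLines(header_path, warn = FALSE)
  kv <- .bv_parse_ini(lines)
  dir <- dirname(header_path)
  for (key in c("DataFile", "MarkerFile", "NumberOfChannels",
                "SamplingInterval")) {
    if (is.na(kv[key])) stopf("header lacks required key %s", key)
  }
  eeg <- file.path(dir, kv[["DataFile"]])
  vmrk <- file.path(dir, kv[["MarkerFile"]])
  if (!file.exists(eeg)) stopf("missing companion data file: %s", eeg)
  if (!file.exists(vmrk)) stopf("missing companion marker file: %s", vmrk)
  fmt <- kv["BinaryFormat"]
  if (is.na(fmt) || fmt != "IEEE_FLOAT_32") {
    stopf("unsupported binary layout '%s' (only IEEE_FLOAT_32 is supported)",
          fmt)
  }
  orient <- kv["DataOrientation"]
  if (!is.na(orient) && orient != "MULTIPLEXED") {
    stopf("unsupported data orientation '%s' (only MULTIPLEXED)", orient)
  }
  n_ch <- as.integer(kv[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(kv[["SamplingInterval"]])

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_names <- vapply(ch_lines,
                     function(l) strsplit(sub("^Ch[0-9]+=", "", l),
                                          ",")[[1]][1],
                     character(1), USE.NAMES = FALSE)
  if (length(ch_names) != n_ch) {
    stopf("header lists %d channels but NumberOfChannels=%d",
          length(ch_names), n_ch)
  }

  nbytes <- file.size(eeg)
  frame <- 4 * n_ch
  if (nbytes %% frame != 0) {
    stopf(paste0("truncated or corrupt binary file: %d bytes is not a whole",
                 " number of %d-channel float32 frames (expected %d or %d",
                 " samples' worth, found %.2f)"),
          nbytes, n_ch, floor(nbytes / frame), ceiling(nbytes / frame),
          nbytes / frame)
  }
  n_samp <- nbytes / frame
  con <- file(eeg, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n_ch * n_samp, size = 4,
                  endian = "little")
  data <- matrix(vals, nrow = n_ch)

  mlines <- grep("^Mk[0-9]+=", readLines(vmrk, warn = FALSE), value = TRUE)
  ev <- list()
  for (l in mlines) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", l), ",")[[1]]
    if (parts[1] != "Stimulus") next
    code <- as.integer(sub("^S\\s*", "", parts[2]))
    ev[[length(ev) + 1]] <- data.frame(sample = as.integer(parts[3]),
                                       code = code)
  }
  events <- if (length(ev) > 0) do.call(rbind, ev) else {
    data.frame(sample = integer(0), code = integer(0))
  }
  events$label <- if (!is.null(task_names)) {
    task_names[events$code]
  } else {
    sprintf("S%d", events$code)
  }
  raw_session(data, fs, ch_names, events, participant_id = participant_id,
              provenance = list(source = header_path))
}

#' Write events to a tab-separated file
#'
#' @param raw A [raw_session()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events_tsv <- function(raw, path) {
  utils::write.table(
    data.frame(onset_sample = raw$events$sample, code = raw$events$code,
               label = raw$events$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write subjective data to a tab-separated file
#'
#' Trial-level table (`trial`, `self_eval`, `trial_gain`) preceded by
#' comment lines carrying the questionnaire scores and preferences.
#'
#' @param subjective A [simulate_subjective()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_subjective_tsv <- function(subjective, path) {
  stopifnot(inherits(subjective, "subjective_data"))
  hdr <- c(
    sprintf("# participant_id\t%s", subjective$participant_id),
    sprintf("# kviq_visual\t%d", subjective$kviq_visual),
    sprintf("# kviq_kinesthetic\t%d", subjective$kviq_kinesthetic),
    sprintf("# kviq_total\t%d", subjective$kviq_total),
    sprintf("# preference_top4\t%s",
            paste(subjective$preference$top4, collapse = ",")),
    sprintf("# preference_t_vs_si\t%s", subjective$preference$t_vs_si),
    sprintf("# preference_si\t%s", subjective$preference$sikin_vs_sinokin),
    sprintf("# mode\t%s", subjective$mode)
  )
  writeLines(hdr, path)
  df <- data.frame(trial = seq_along(subjective$self_eval),
                   self_eval = as.character(subjective$self_eval),
                   trial_gain = subjective$trial_gain)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(path)
}
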