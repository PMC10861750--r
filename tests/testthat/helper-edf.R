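# Writes a minimal EDF file in code (text-free fixture, built at test time):
# 256-byte main header, 256 bytes of headers per signal, then data records
# of 2-byte little-endian integers.
write_minimal_edf <- function(path, channels, fs, record_dur = 1,
                              phys_scale = 1) {
  ns <- length(channels)
  n <- length(channels[[1]])
  n_records <- n / (fs * record_dur)
  stopifnot(n_records == round(n_records))
  pad <- function(x, width) formatC(as.character(x), width = width,
                                    flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic subject", 80),
                pad("synthetic recording", 80),
                "01.01.24", "00.00.00",
                pad(256 * (1 + ns), 8), pad("", 44),
                pad(n_records, 8), pad(record_dur, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  grp <- function(vals, width)
    writeChar(paste0(vapply(vals, pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  dmin <- -32768; dmax <- 32767
  grp(names(channels), 16)                       # labels
  grp(rep("", ns), 80)                           # transducer
  grp(rep("uV", ns), 8)                          # unit
  grp(rep(dmin * phys_scale, ns), 8)             # physical min
  grp(rep(dmax * phys_scale, ns), 8)             # physical max
  grp(rep(dmin, ns), 8)                          # digital min
  grp(rep(dmax, ns), 8)                          # digital max
  grp(rep("", ns), 80)                           # prefilter
  grp(rep(fs * record_dur, ns), 8)               # samples per record
  grp(rep("", ns), 32)                           # reserved
  spr <- fs * record_dur
  for (rec in seq_len(n_records)) {
    for (ch in channels) {
      seg <- ch[((rec - 1) * spr + 1):(rec * spr)]
      writeBin(as.integer(round(seg)), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
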