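# WFDB record reading/writing and beat-class remapping.
#
# A minimal reader for the standard WFDB layout: a text .hea header, a
# binary .dat signal file (formats 16 and 212 -- format 212 is what the
# MIT-BIH arrhythmia recordings use) and a binary .atr annotation file in
# the MIT annotation format. The writer emits format-16 .hea/.dat pairs
# plus a CSV annotation file; a plain CSV record dialect is provided as a
# fully text-based alternative.

# standard WFDB annotation code -> symbol table (beat and non-beat codes)
.atr_symbols <- c(
  "N", "L", "R", "a", "V", "F", "J", "A", "S", "E",       # 1-10
  "j", "/", "Q", "~", "", "|", "", "s", "T", "*",         # 11-20
  "D", "\"", "=", "p", "B", "^", "t", "+", "u", "?",      # 21-30
  "!", "[", "]", "e", "n", "@", "x", "f", "(", ")",       # 31-40
  "r")

#' Default mapping from WFDB beat symbols to the four beat classes
#'
#' Groups the native WFDB beat codes by underlying mechanism:
#' sinus/bundle-branch/escape beats (`N`, `L`, `R`, `e`, `j`) map to `N`;
#' supraventricular premature beats (`A`, `a`, `J`, `S`) to `APC`;
#' ventricular ectopy (`V`, `E`) to `VPC`; fusion, paced, unclassifiable
#' and noise codes (`F`, `f`, `/`, `Q`, `~`, `|`) to `A`. Common non-beat
#' annotation symbols map to `ignore` and are dropped on reading.
#'
#' @return Named character vector: native symbol -> one of `"N"`, `"APC"`,
#'   `"VPC"`, `"A"`, `"ignore"`.
#' @export
default_class_map <- function() {
  c(N = "N", L = "N", R = "N", e = "N", j = "N",
    A = "APC", a = "APC", J = "APC", S = "APC",
    V = "VPC", E = "VPC",
    F = "A", f = "A", "/" = "A", Q = "A", "~" = "A", "|" = "A",
    "+" = "ignore", "\"" = "ignore", "=" = "ignore", p = "ignore",
    t = "ignore", u = "ignore", "^" = "ignore", "*" = "ignore",
    D = "ignore", "@" = "ignore", "(" = "ignore", ")" = "ignore",
    "[" = "ignore", "]" = "ignore", "!" = "ignore", "?" = "ignore",
    s = "ignore", T = "ignore", r = "ignore", x = "ignore",
    n = "APC", B = "N")
}

#' Read or write a class-map config file
#'
#' The file is a two-column CSV (`symbol,class`) so the 15-to-4 class
#' grouping is data, not code.
#'
#' @param path File path.
#' @param map Named character vector as returned by [default_class_map()].
#' @return `read_class_map` returns the named vector.
#' @export
read_class_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stats::setNames(df$class, df$symbol)
}

#' @rdname read_class_map
#' @export
write_class_map <- function(map, path) {
  utils::write.csv(data.frame(symbol = names(map), class = unname(map),
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

.parse_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  name <- sub("/.*$", "", top[1L])
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*$", "", top[3L])) else 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  sig <- vector("list", nsig)
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1L + i]), "\\s+")[[1L]]
    fmt <- as.integer(sub("x.*$", "", f[2L]))
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_field)))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else NA_real_
    adczero <- if (length(f) >= 5L) as.numeric(f[5L]) else 0
    if (is.na(baseline)) baseline <- adczero
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ")
            else paste0("sig", i)
    sig[[i]] <- list(file = f[1L], format = fmt, gain = gain,
                     baseline = baseline, desc = desc)
  }
  files <- unique(vapply(sig, `[[`, "", "file"))
  if (length(files) != 1L) {
    stop("multi-file WFDB records are not supported")
  }
  list(name = name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

.read_dat <- function(dat_path, hdr) {
  nsig <- hdr$nsig
  fmt <- hdr$signals[[1L]]$format
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  if (fmt == 16L) {
    vals <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                    signed = TRUE, endian = "little")
  } else if (fmt == 212L) {
    if (nsig != 2L && length(raw) %% 3L != 0L) {
      raw <- raw[seq_len(length(raw) - length(raw) %% 3L)]
    }
    b <- as.integer(raw)
    n3 <- length(b) %/% 3L
    b1 <- b[seq(1L, by = 3L, length.out = n3)]
    b2 <- b[seq(2L, by = 3L, length.out = n3)]
    b3 <- b[seq(3L, by = 3L, length.out = n3)]
    s1 <- b1 + bitwAnd(b2, 15L) * 256L
    s2 <- b3 + bitwAnd(b2 %/% 16L, 15L) * 256L
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    vals <- as.vector(rbind(s1, s2))
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
  nsamp <- length(vals) %/% nsig
  if (!is.na(hdr$nsamp)) nsamp <- min(nsamp, hdr$nsamp)
  m <- matrix(vals[seq_len(nsamp * nsig)], ncol = nsig, byrow = TRUE)
  out <- matrix(0, nsamp, nsig)
  for (j in seq_len(nsig)) {
    out[, j] <- (m[, j] - hdr$signals[[j]]$baseline) / hdr$signals[[j]]$gain
  }
  out
}

# MIT annotation (.atr) format: a stream of 16-bit little-endian words;
# the high 6 bits carry the annotation code, the low 10 bits the sample
# interval since the previous annotation. Codes 59-63 are pseudo-codes
# (SKIP carries a 32-bit interval in the following two words; NUM, SUB,
# CHN set modifier fields; AUX is followed by its byte count of text).
.read_atr <- function(atr_path) {
  raw <- readBin(atr_path, "raw", n = file.size(atr_path))
  b <- as.integer(raw)
  i <- 1L
  time <- 0
  samples <- integer(0)
  codes <- integer(0)
  while (i + 1L <= length(b)) {
    word <- b[i] + b[i + 1L] * 256L
    i <- i + 2L
    code <- word %/% 1024L
    interval <- word %% 1024L
    if (code == 0L && interval == 0L) break
    if (code == 59L) {          # SKIP: 32-bit interval, high word first
      if (i + 3L > length(b)) break
      hi <- b[i] + b[i + 1L] * 256L
      lo <- b[i + 2L] + b[i + 3L] * 256L
      i <- i + 4L
      skip <- hi * 65536 + lo
      if (skip >= 2147483648) skip <- skip - 4294967296
      time <- time + skip
    } else if (code == 63L) {   # AUX: interval = byte count (padded even)
      nb <- interval + interval %% 2L
      i <- i + nb
    } else if (code %in% 60:62) {
      # NUM/SUB/CHN modifiers: ignored
    } else {
      time <- time + interval
      samples <- c(samples, as.integer(time))
      codes <- c(codes, code)
    }
  }
  sym <- ifelse(codes >= 1L & codes <= length(.atr_symbols),
                .atr_symbols[codes], sprintf("<code %d>", codes))
  data.frame(sample = samples + 1L, symbol = sym,
             stringsAsFactors = FALSE)  # WFDB times are 0-based
}

.apply_class_map <- function(ann, class_map) {
  mapped <- unname(class_map[ann$symbol])
  unknown <- unique(ann$symbol[is.na(mapped)])
  if (length(unknown)) {
    stop("annotation symbol(s) not covered by the class map: ",
         paste(sprintf("'%s'", unknown), collapse = ", "))
  }
  keep <- mapped != "ignore"
  data.frame(sample = ann$sample[keep], label = mapped[keep],
             stringsAsFactors = FALSE)
}

#' Read a WFDB record with beat-class remapping
#'
#' Reads `<path>.hea` / `<path>.dat` and annotations from `<path>.atr`
#' (native symbols, remapped through `class_map`, `ignore` entries
#' dropped) or, if no .atr file exists, from `<path>_annotations.csv` as
#' written by [write_record_wfdb()] (labels already in the 4-class scheme).
#'
#' @param path Record path prefix (no extension).
#' @param class_map Named symbol-to-class vector; see
#'   [default_class_map()].
#' @return An [ecg_record()] at the native sample rate.
#' @export
read_record <- function(path, class_map = default_class_map()) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("no header file: ", hea)
  hdr <- .parse_header(hea)
  dat <- file.path(dirname(hea), hdr$signals[[1L]]$file)
  if (!file.exists(dat)) stop("no signal file: ", dat)
  sig <- .read_dat(dat, hdr)
  leads <- vapply(hdr$signals, `[[`, "", "desc")

  atr <- paste0(path, ".atr")
  csv <- paste0(path, "_annotations.csv")
  if (file.exists(atr)) {
    ann <- .apply_class_map(.read_atr(atr), class_map)
  } else if (file.exists(csv)) {
    ann <- utils::read.csv(csv, stringsAsFactors = FALSE)
  } else {
    stop("record '", path, "' has no annotation file (.atr or ",
         "_annotations.csv)")
  }
  ann <- ann[ann$sample >= 1L & ann$sample <= nrow(sig), , drop = FALSE]
  ecg_record(sig, fs = hdr$fs, annotations = ann, leads = leads)
}

#' Write a record as a WFDB-compatible format-16 pair plus CSV annotations
#'
#' Amplitudes are quantized at `gain` ADC units per mV.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory.
#' @param name Record name (file prefix).
#' @param gain ADC gain (units/mV), default 1000.
#' @return The record path prefix, invisibly.
#' @export
write_record_wfdb <- function(record, dir, name, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(record$signal)
  nsig <- ncol(record$signal)
  adc <- round(record$signal * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  dat_name <- paste0(name, ".dat")
  hea <- c(sprintf("%s %d %g %d", name, nsig, record$fs, n),
           sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 %s",
                   dat_name, gain, as.integer(adc[1, ]), record$leads))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  interleaved <- as.integer(t(adc))
  writeBin(interleaved, file.path(dir, dat_name), size = 2L,
           endian = "little")
  utils::write.csv(record$annotations,
                   file.path(dir, paste0(name, "_annotations.csv")),
                   row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, name))
}

#' Write/read a record in the plain CSV dialect
#'
#' The signal file has a `# sample_rate=<Hz>` comment line, a header of
#' lead labels, and one column per lead; annotations go to
#' `<prefix>_annotations.csv` with columns `sample,label` (1-based
#' indices).
#'
#' @param record An [ecg_record()].
#' @param prefix Output path prefix (writes `<prefix>.csv` and
#'   `<prefix>_annotations.csv`).
#' @return `write_record_csv`: the prefix, invisibly; `read_record_csv`:
#'   the [ecg_record()].
#' @export
write_record_csv <- function(record, prefix) {
  stopifnot(inherits(record, "ecg_record"))
  path <- paste0(prefix, ".csv")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate=%g", record$fs), con)
  utils::write.table(record$signal, con, sep = ",", row.names = FALSE,
                     col.names = record$leads, quote = FALSE)
  utils::write.csv(record$annotations, paste0(prefix, "_annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(prefix) {
  path <- paste0(prefix, ".csv")
  first <- readLines(path, n = 1L)
  fs <- as.numeric(sub("^#\\s*sample_rate=", "", first))
  sig <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  ann_path <- paste0(prefix, "_annotations.csv")
  ann <- if (file.exists(ann_path)) utils::read.csv(ann_path) else NULL
  ecg_record(as.matrix(sig), fs = fs, annotations = ann,
             leads = colnames(sig))
}

#' Resample a record to a target rate
#'
#' Band-limited polyphase resampling of every lead (via
#' [signal::resample()]); annotation indices are rescaled by
#' `target_rate / fs` and rounded half-up, so annotation times are
#' preserved to within one sample.
#'
#' @param record An [ecg_record()].
#' @param target_rate Target sample rate in Hz.
#' @return The resampled [ecg_record()].
#' @export
resample_record <- function(record, target_rate) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.numeric(target_rate) || target_rate <= 0) {
    stop("target_rate must be positive")
  }
  if (target_rate == record$fs) return(record)
  scale <- 1000L
  p <- as.integer(round(target_rate * scale))
  q <- as.integer(round(record$fs * scale))
  g <- .gcd(p, q)
  p <- p %/% g
  q <- q %/% g
  n <- nrow(record$signal)
  n_out <- as.integer(round(n * target_rate / record$fs))
  sig <- matrix(0, n_out, ncol(record$signal))
  for (j in seq_len(ncol(sig))) {
    y <- signal::resample(record$signal[, j], p, q)
    if (length(y) >= n_out) {
      sig[, j] <- y[seq_len(n_out)]
    } else {
      sig[, j] <- c(y, rep(y[length(y)], n_out - length(y)))
    }
  }
  ann <- record$annotations
  if (nrow(ann)) {
    r <- target_rate / record$fs
    ann$sample <- as.integer(floor((ann$sample - 1L) * r + 0.5)) + 1L
    ann$sample <- pmin(pmax(ann$sample, 1L), n_out)
    ann <- ann[!duplicated(ann$sample), , drop = FALSE]
  }
  ecg_record(sig, fs = target_rate, annotations = ann,
             leads = record$leads)
}

.gcd <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
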