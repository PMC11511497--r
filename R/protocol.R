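#' Build the modified Sheffield adjacent stimulation/measurement protocol
#'
#' Constructs the stimulation and measurement schedule used by the portable
#' 16-electrode EIT monitor. Current is injected across adjacent electrode
#' pairs with alternating polarity: odd electrodes only ever act as current
#' source, even electrodes only as sink (a consequence of the two-multiplexer
#' current routing, where odd electrodes hang off one multiplexer and even
#' electrodes off the other). For each of the `n_electrodes` stimulation
#' patterns, differential voltages are read on every adjacent pair not
#' touching a drive electrode, giving `n_electrodes - 3` measurements per
#' pattern and `n_electrodes * (n_electrodes - 3)` combinations per frame.
#'
#' The pair sequence for 16 electrodes is `(+E1,-E2), (+E3,-E2), (+E3,-E4),
#' (+E5,-E4), ...` up to `(+E1,-E16)`. Measurement pairs within a pattern
#' follow the same alternating sequence, starting just after the drive pair
#' and skipping pairs that share a drive electrode; e.g. pattern 1 (drive
#' E1-E2) measures (E3,E4), (E5,E4), ..., (E15,E16) and pattern 2 (drive
#' E3-E2) measures (E5,E4), ..., (E1,E16).
#'
#' @param n_electrodes Even integer >= 4; number of ring electrodes.
#' @return An object of class `eit_protocol` with elements
#'   `n_electrodes`, `stim_pairs` (matrix, columns `source`, `sink`),
#'   `meas_pairs` (list of 2-column matrices, columns `first`, `second`),
#'   and `n_measurements`.
#' @examples
#' p <- build_protocol(16)
#' p$n_measurements  # 208
#' @export
build_protocol <- function(n_electrodes = 16L) {
  n <- as.integer(n_electrodes)
  if (is.na(n) || n < 4L || n %% 2L != 0L) {
    stop("protocol size error: n_electrodes must be an even integer >= 4, got ",
         n_electrodes)
  }
  wrap <- function(e) ((e - 1L) %% n) + 1L
  k <- seq_len(n)
  src <- wrap(ifelse(k %% 2L == 1L, k, k + 1L))
  snk <- wrap(2L * ((k + 1L) %/% 2L))
  stim <- cbind(source = src, sink = snk)

  # ordered cycle of adjacent pairs in stimulation-pattern order; measurement
  # schedule for pattern j walks the same cycle starting after pair j
  pairs <- cbind(first = src, second = snk)
  meas <- vector("list", n)
  for (j in seq_len(n)) {
    idx <- wrap(j + seq_len(n - 1L))
    cand <- pairs[idx, , drop = FALSE]
    drive <- stim[j, ]
    keep <- cand[, 1L] != drive[1L] & cand[, 1L] != drive[2L] &
            cand[, 2L] != drive[1L] & cand[, 2L] != drive[2L]
    meas[[j]] <- cand[keep, , drop = FALSE]
  }
  spec <- structure(
    list(n_electrodes = n, stim_pairs = stim, meas_pairs = meas,
         n_measurements = n * (n - 3L)),
    class = "eit_protocol")
  stopifnot(sum(vapply(meas, nrow, 0L)) == spec$n_measurements)
  spec
}

#' @exportS3Method base::print
print.eit_protocol <- function(x, ...) {
  cat(sprintf(
    "EIT adjacent protocol: %d electrodes, %d stimulation patterns x %d measurements = %d combinations/frame\n",
    x$n_electrodes, x$n_electrodes, x$n_electrodes - 3L, x$n_measurements))
  invisible(x)
}

#' Flat table of all stimulation/measurement combinations
#'
#' One row per (stimulation, measurement) combination in acquisition order;
#' 208 rows for the 16-electrode protocol. `slot` is the 0-based measurement
#' index within its stimulation pattern, the value carried in the 4-bit field
#' of each raw data word.
#'
#' @param spec An `eit_protocol`.
#' @return A data.frame with columns `pattern`, `source`, `sink`, `slot`,
#'   `meas_first`, `meas_second`.
#' @export
protocol_table <- function(spec) {
  stopifnot(inherits(spec, "eit_protocol"))
  rows <- lapply(seq_len(spec$n_electrodes), function(j) {
    m <- spec$meas_pairs[[j]]
    data.frame(pattern = j,
               source = unname(spec$stim_pairs[j, "source"]),
               sink = unname(spec$stim_pairs[j, "sink"]),
               slot = seq_len(nrow(m)) - 1L,
               meas_first = unname(m[, "first"]),
               meas_second = unname(m[, "second"]))
  })
  do.call(rbind, rows)
}

#' Current-multiplexer selector codes for an adjacent electrode pair
#'
#' Maps an adjacent stimulation pair to the pair of 3-bit selector codes of
#' the two 1:8 analog multiplexers that route the current source. Odd
#' electrodes are wired to one multiplexer, even electrodes to the other;
#' electrode `E` sits on channel `floor((E - 1) / 2)` of its multiplexer.
#' Selectors are returned in the order the electrodes are listed.
#'
#' @param pair Integer vector of length 2, an adjacent pair on the
#'   16-electrode ring (e.g. `c(1, 2)` or `c(16, 1)`).
#' @param n_electrodes Ring size (default 16).
#' @return Named integer vector `c(selector_A, selector_B)`, each in 0..7.
#' @examples
#' mux_select(c(1, 2))   # 0 0
#' mux_select(c(16, 1))  # 7 0
#' @export
mux_select <- function(pair, n_electrodes = 16L) {
  pair <- as.integer(pair)
  n <- as.integer(n_electrodes)
  if (length(pair) != 2L || anyNA(pair) || any(pair < 1L | pair > n)) {
    stop("pair must be two electrode indices in 1..", n)
  }
  d <- abs(pair[1L] - pair[2L])
  if (!(d == 1L || d == n - 1L)) {
    stop("pair (", pair[1L], ",", pair[2L], ") is not adjacent on the ring")
  }
  c(selector_A = (pair[1L] - 1L) %/% 2L,
    selector_B = (pair[2L] - 1L) %/% 2L)
}

#' Signed stimulation-pattern matrix
#'
#' Column k holds +1 at the current source electrode and -1 at the sink for
#' stimulation pattern k, 0 elsewhere.
#'
#' @param spec An `eit_protocol`.
#' @return Integer matrix, `n_electrodes` rows x `n_electrodes` columns.
#' @export
stim_pattern_matrix <- function(spec) {
  stopifnot(inherits(spec, "eit_protocol"))
  n <- spec$n_electrodes
  m <- matrix(0L, n, n)
  for (j in seq_len(n)) {
    m[spec$stim_pairs[j, "source"], j] <- 1L
    m[spec$stim_pairs[j, "sink"], j] <- -1L
  }
  m
}

#' Export a protocol as CSV
#'
#' @param spec An `eit_protocol`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol_csv <- function(spec, path) {
  utils::write.csv(protocol_table(spec), path, row.names = FALSE)
  invisible(path)
}

# ---- raw-data codec ---------------------------------------------------------

MAX_SLOT <- 12L  # slots 13-15 are reserved; their appearance marks bad framing

#' Pack one measurement burst into the device byte dialect
#'
#' Each of the 64 ADC samples is emitted as one 16-bit word: the 12-bit ADC
#' code in the low bits and the 4-bit measurement slot (0-12, the position of
#' the measurement within its stimulation pattern) in the high bits. Words
#' are written high byte first, so a hex dump reads slot-then-code.
#'
#' @param slot Integer 0..12.
#' @param codes Integer vector of 64 ADC codes, each 0..4095.
#' @return Raw vector of 128 bytes.
#' @examples
#' pack_measurement(3, rep(2748L, 64))[1:2]  # 3a bc
#' @export
pack_measurement <- function(slot, codes) {
  slot <- as.integer(slot)
  codes <- as.integer(codes)
  if (length(slot) != 1L || is.na(slot) || slot < 0L || slot > MAX_SLOT) {
    stop("slot must be a single integer in 0..12")
  }
  if (length(codes) != 64L || anyNA(codes) || any(codes < 0L | codes > 4095L)) {
    stop("codes must be 64 integers in 0..4095")
  }
  pack_words(rep.int(slot, 64L), codes)
}

# vectorized word packer used by the simulator (slots/codes same length)
pack_words <- function(slots, codes) {
  hi <- bitwOr(bitwShiftL(slots, 4L), bitwShiftR(codes, 8L))
  lo <- bitwAnd(codes, 255L)
  out <- matrix(0L, nrow = 2L, ncol = length(codes))
  out[1L, ] <- hi
  out[2L, ] <- lo
  as.raw(as.vector(out))
}

# inverse of pack_words: raw vector -> list(slots, codes); length(bytes) even
unpack_words <- function(bytes) {
  if (length(bytes) %% 2L != 0L) {
    stop("framing error: odd byte count (", length(bytes), ")")
  }
  v <- as.integer(bytes)
  hi <- v[c(TRUE, FALSE)]
  lo <- v[c(FALSE, TRUE)]
  list(slots = bitwShiftR(hi, 4L),
       codes = bitwOr(bitwShiftL(bitwAnd(hi, 15L), 8L), lo))
}

#' Unpack one 128-byte measurement
#'
#' Inverse of [pack_measurement()]. All 64 words must carry the same, valid
#' slot index (0-12); a mixed or reserved slot marks a sync-invalid block.
#'
#' @param bytes Raw vector of 128 bytes.
#' @return List with `slot` and `codes` (64 integers).
#' @export
unpack_measurement <- function(bytes) {
  if (length(bytes) != 128L) {
    stop("framing error: expected 128 bytes per measurement, got ", length(bytes))
  }
  w <- unpack_words(bytes)
  s <- unique(w$slots)
  if (length(s) != 1L || s > MAX_SLOT) {
    stop("sync-invalid measurement: slot field not constant/valid (",
         paste(s, collapse = ","), ")")
  }
  list(slot = s, codes = w$codes)
}
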