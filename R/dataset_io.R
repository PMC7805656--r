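#' Band combination
#'
#' A nonempty subset of the four band positions (1 wrist, 2 forearm
#' midway, 3 forearm muscle belly, 4 upper arm).
#'
#' @param positions Integer vector, subset of 1:4.
#' @return An `fmg_combo` object (sorted unique positions).
#' @export
band_combination <- function(positions) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0L || anyNA(positions) || !all(positions %in% 1:4)) {
    stop_input("band combination must be a nonempty subset of {1, 2, 3, 4}")
  }
  structure(positions, class = "fmg_combo")
}

#' @export
format.fmg_combo <- function(x, ...) paste(unclass(x), collapse = "+")

#' @export
print.fmg_combo <- function(x, ...) {
  cat("<band combination> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Enumerate all 15 band combinations
#'
#' All nonempty subsets of the four band positions, ordered by size then
#' lexicographically: the four singles first, then six doubles, four
#' triples, and the full four-band set last.
#'
#' @return List of 15 [band_combination()] objects.
#' @export
enumerate_combinations <- function() {
  combos <- list()
  for (size in 1:4) {
    sets <- utils::combn(1:4, size, simplify = FALSE)
    combos <- c(combos, lapply(sets, band_combination))
  }
  combos
}

#' Restrict a subject dataset to the channels of selected bands
#'
#' Labels, trial and session indexing are untouched; only FMG columns are
#' filtered. Idempotent, and commutes with trial slicing.
#'
#' @param ds An `fmg_subject`.
#' @param combo A [band_combination()] (or integer vector of positions).
#' @return The restricted `fmg_subject`.
#' @export
select_bands <- function(ds, combo) {
  combo <- band_combination(combo)
  keep <- ds$channel_band %in% unclass(combo)
  if (!any(keep)) {
    stop_input("no active channels remain for band combination ", format(combo))
  }
  ds$fmg <- ds$fmg[, keep, drop = FALSE]
  ds$channel_band <- ds$channel_band[keep]
  ds
}

#' Write a subject dataset to CSV plus a JSON sidecar
#'
#' The CSV carries `sample_index` (0-based), `trial_id`, `session_id`,
#' the active channel columns (`ch_###`, zero-padded for stable ordering)
#' and the six label columns. The sidecar records the band layout, the
#' active-sensor mask, and generation metadata, which the CSV cannot
#' carry.
#'
#' @param ds An `fmg_subject`.
#' @param path Path prefix; `<path>.csv` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_subject <- function(ds, path) {
  df <- data.table::data.table(
    sample_index = seq_len(nrow(ds$fmg)) - 1L,
    trial_id = ds$trial_id,
    session_id = ds$session_id
  )
  df <- cbind(df,
              data.table::as.data.table(signif(ds$fmg, 8)),
              data.table::as.data.table(signif(ds$labels, 8)))
  data.table::fwrite(df, paste0(path, ".csv"))
  sidecar <- list(
    band_sizes = ds$layout$band_sizes,
    active_mask = layout_with_mask(ds)$active_mask,
    channel_names = colnames(ds$fmg),
    meta = ds$meta[setdiff(names(ds$meta), "config")],
    config = ds$meta$config
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a subject dataset from CSV plus its JSON sidecar
#'
#' The reader tolerates comma- or tab-delimited files. Channels flagged
#' inactive in the sidecar mask are dropped. Fails with labeled I/O
#' errors on a missing sidecar, channel-count disagreement between files,
#' or a non-monotone `sample_index`.
#'
#' @param path Path prefix used in [write_subject()], or the `.csv` path.
#' @return An `fmg_subject` (active channels only).
#' @export
load_subject <- function(path) {
  path <- sub("\\.csv$", "", path)
  csv <- paste0(path, ".csv")
  side <- paste0(path, ".json")
  if (!file.exists(csv)) stop_io("dataset CSV not found: ", csv)
  if (!file.exists(side)) stop_io("sidecar not found: ", side)
  sidecar <- jsonlite::read_json(side, simplifyVector = TRUE)
  df <- data.table::fread(csv)
  ch_cols <- grep("^ch_\\d+$", names(df), value = TRUE)
  layout <- band_layout(sidecar$band_sizes, as.logical(sidecar$active_mask))
  want <- layout$channel_names[layout$active_mask]
  if (!all(want %in% ch_cols) &&
      length(ch_cols) != sum(layout$band_sizes)) {
    stop_io("channel columns in CSV (", length(ch_cols),
            ") do not match the sidecar layout")
  }
  si <- df$sample_index
  if (is.unsorted(si, strictly = TRUE)) {
    stop_io("sample_index is not strictly increasing")
  }
  # accept either all-channel or pre-masked CSVs
  have <- if (all(want %in% ch_cols)) want else ch_cols
  new_fmg_subject(
    fmg = as.matrix(df[, have, with = FALSE]),
    labels = as.matrix(df[, FMG_AXES, with = FALSE]),
    trial_id = df$trial_id,
    session_id = df$session_id,
    layout = layout,
    meta = c(sidecar$meta, list(config = sidecar$config))
  )
}
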