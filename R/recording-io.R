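#' Read and write body-surface recordings
#'
#' Plain-text container for recordings: a CSV of channel potentials (rows =
#' channels, columns = samples; chest channels `E001..E128` followed by limb
#' rows `RA`, `LA`, `LL`, `REF`) plus a JSON sidecar (same path with
#' extension `.json`) carrying the sampling rate, QRS window, SNR and seed.
#'
#' @param recording a `body_surface_recording`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_recording()`: `path`, invisibly; `read_recording()`: a
#'   `body_surface_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "body_surface_recording"))
  pot <- recording$potentials
  rn <- sprintf("E%03d", seq_len(nrow(pot)))
  M <- pot
  if (!is.null(recording$limb)) {
    M <- rbind(M, recording$limb)
    rn <- c(rn, c("RA", "LA", "LL", "REF"))
  }
  df <- data.frame(channel = rn, M, check.names = FALSE)
  colnames(df) <- c("channel", sprintf("t%05d", seq_len(ncol(M))))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(sampling_rate = recording$sampling_rate,
               qrs_window = recording$qrs_window,
               snr_db = if (is.finite(recording$snr_db))
                 recording$snr_db else "Inf",
               seed = recording$seed,
               n_chest_channels = nrow(pot))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  nc <- meta$n_chest_channels
  pot <- M[seq_len(nc), , drop = FALSE]
  limb <- if (nrow(M) >= nc + 4L) M[(nc + 1L):(nc + 4L), , drop = FALSE]
  dimnames(pot) <- NULL
  if (!is.null(limb)) dimnames(limb) <- NULL
  snr <- meta$snr_db
  if (identical(snr, "Inf")) snr <- Inf
  fs <- meta$sampling_rate
  structure(list(potentials = pot, limb = limb, sampling_rate = fs,
                 time_ms = (seq_len(ncol(pot)) - 1L) * 1000 / fs,
                 qrs_window = meta$qrs_window, snr_db = snr,
                 seed = meta$seed),
            class = "body_surface_recording")
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write per-node activation/voltage maps with segment metadata
#'
#' One row per heart node: `node_id`, `segment_id`, `surface_class`,
#' `lat_ms`, `vpp_uv`, `valid`.
#'
#' @param activation an `activation_map`.
#' @param voltage a `voltage_map`.
#' @param seg a `segment_model`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_maps_csv <- function(activation, voltage, seg, path) {
  df <- seg |>
    dplyr::select("node_id", "segment_id", "surface_class") |>
    dplyr::inner_join(dplyr::select(activation, "node_id", "lat_ms",
                                    lat_valid = "valid"), by = "node_id") |>
    dplyr::inner_join(dplyr::select(voltage, "node_id", "vpp_uv",
                                    vpp_valid = "valid"), by = "node_id") |>
    dplyr::mutate(valid = .data$lat_valid & .data$vpp_valid) |>
    dplyr::select("node_id", "segment_id", "surface_class", "lat_ms",
                  "vpp_uv", "valid")
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}
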