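#' Write an epoch set to a directory
#'
#' Self-describing plain-text layout: `meta.json` (channels, positions,
#' sampling rate, t0, labels, subject/run/trial bookkeeping) plus
#' `data.csv` with one row per trial x sample and one column per channel.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  d <- dim(epochs$data)
  meta <- list(channels = epochs$channels,
               positions = unname(apply(epochs$positions, 1, as.numeric,
                                        simplify = FALSE)),
               sfreq = epochs$sfreq, t0 = epochs$t0,
               labels = epochs$labels, subject_id = epochs$subject_id,
               run = epochs$run, trial = epochs$trial,
               n_trials = d[1], n_samples = d[3])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # rows ordered trial-major: trial 1 samples, trial 2 samples, ...
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), d[1] * d[3], d[2])
  colnames(flat) <- epochs$channels
  dt <- data.table::as.data.table(flat)
  dt <- cbind(data.table::data.table(
    trial_row = rep(seq_len(d[1]), each = d[3])), dt)
  data.table::fwrite(dt, file.path(path, "data.csv"))
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path Directory containing `meta.json` and `data.csv`.
#' @param expect_channels Optional channel names that must all be present
#'   (error names any missing one).
#' @return An [eeg_epochs()] object.
#' @export
read_epochs <- function(path, expect_channels = NULL) {
  meta_file <- file.path(path, "meta.json")
  data_file <- file.path(path, "data.csv")
  if (!file.exists(meta_file) || !file.exists(data_file)) {
    stop("not an epochs directory (missing meta.json or data.csv): ", path)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  dt <- data.table::fread(data_file)
  chans <- meta$channels
  if (!is.null(expect_channels)) {
    missing <- setdiff(expect_channels, chans)
    if (length(missing) > 0L) {
      stop("missing channel(s): ", paste(missing, collapse = ", "))
    }
  }
  if (!all(chans %in% names(dt))) {
    stop("data.csv lacks column(s): ",
         paste(setdiff(chans, names(dt)), collapse = ", "))
  }
  n_tr <- meta$n_trials
  n_sa <- meta$n_samples
  if (nrow(dt) != n_tr * n_sa) {
    stop("data.csv has ", nrow(dt), " rows; expected ", n_tr * n_sa)
  }
  flat <- as.matrix(dt[, chans, with = FALSE])
  arr <- aperm(array(flat, c(n_sa, n_tr, length(chans))), c(2, 3, 1))
  pos <- if (is.list(meta$positions)) do.call(rbind, meta$positions)
         else as.matrix(meta$positions)
  eeg_epochs(arr, chans, pos, meta$sfreq, meta$t0, meta$labels,
             meta$subject_id, meta$run, meta$trial)
}

#' Write a tidy analysis table as CSV
#'
#' UTF-8, comma-separated, '.' decimal, header row.
#'
#' @param table Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a PLV table
#'
#' Checks the structural invariants of a pairwise PLV table: required
#' columns present; plv in [0, 1] for rest/mi rows and in [-1, 1] for
#' delta rows; each pair stored once with channel_i before channel_j in
#' montage order (when both are montage channels).
#'
#' @param path CSV file written by [write_table()].
#' @return Tibble of validated PLV rows.
#' @export
read_plv_table <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("subject_id", "condition", "window", "band",
            "channel_i", "channel_j", "plv")
  if (!all(need %in% names(tab))) {
    stop("PLV table lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  is_delta <- tab$window == "delta"
  bad <- (!is_delta & (tab$plv < 0 | tab$plv > 1)) |
    (is_delta & (tab$plv < -1 | tab$plv > 1))
  if (any(bad)) {
    stop("invalid plv value(s), e.g. ", tab$plv[which(bad)[1]],
         " in window '", tab$window[which(bad)[1]], "'")
  }
  mont <- montage_channels()
  ii <- match(tab$channel_i, mont)
  jj <- match(tab$channel_j, mont)
  both <- !is.na(ii) & !is.na(jj)
  if (any(both & ii >= jj)) {
    stop("pair ordering violated: channel_i must precede channel_j")
  }
  tab
}
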