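#' Network-scale pair sets
#'
#' The analysis aggregates pairwise PLV at three spatial scales:
#' \describe{
#'   \item{global}{all C(16, 2) = 120 electrode pairs;}
#'   \item{large}{the 25 inter-hemispheric pairs between the left hub
#'     \{FC5, FC1, C3, CP5, CP1\} and the right hub
#'     \{FC6, FC2, C4, CP6, CP2\};}
#'   \item{local_left / local_right}{the intra-hemispheric neighborhood of
#'     C3 (resp. C4): by default the 4 pairs between the hub center and
#'     each of its surrounding hub electrodes; `local_mode = "within_hub"`
#'     instead uses all 10 within-hub pairs.}
#' }
#'
#' @param name One of "global", "large", "local_left", "local_right".
#' @param channels Montage channel names (default [montage_channels()]).
#' @param local_mode "center" (default, hub center to neighbors) or
#'   "within_hub" (all pairs within the hub).
#' @return An object of class `scale_def`: list with `name` and `pairs`
#'   (data.frame channel_i/channel_j, i before j in montage order).
#' @export
scale_def <- function(name = c("global", "large", "local_left", "local_right"),
                      channels = montage_channels(),
                      local_mode = c("center", "within_hub")) {
  name <- match.arg(name)
  local_mode <- match.arg(local_mode)
  left_hub <- c("FC5", "FC1", "C3", "CP5", "CP1")
  right_hub <- c("FC6", "FC2", "C4", "CP6", "CP2")
  pair_df <- function(a, b) {
    # order each pair by montage position so it matches PLV table storage
    ia <- match(a, channels); ib <- match(b, channels)
    swap <- ia > ib
    data.frame(channel_i = ifelse(swap, b, a),
               channel_j = ifelse(swap, a, b),
               stringsAsFactors = FALSE)
  }
  pairs <- switch(
    name,
    global = {
      cmb <- utils::combn(channels, 2)
      pair_df(cmb[1, ], cmb[2, ])
    },
    large = {
      grid <- expand.grid(a = left_hub, b = right_hub,
                          stringsAsFactors = FALSE)
      pair_df(grid$a, grid$b)
    },
    local_left = local_pairs("C3", left_hub, channels, local_mode),
    local_right = local_pairs("C4", right_hub, channels, local_mode))
  pairs <- pairs[order(match(pairs$channel_i, channels),
                       match(pairs$channel_j, channels)), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(name = name, pairs = pairs), class = "scale_def")
}

local_pairs <- function(center, hub, channels, mode) {
  ia <- function(a, b) {
    sw <- match(a, channels) > match(b, channels)
    data.frame(channel_i = ifelse(sw, b, a), channel_j = ifelse(sw, a, b),
               stringsAsFactors = FALSE)
  }
  if (mode == "center") {
    nb <- setdiff(hub, center)
    ia(rep(center, length(nb)), nb)
  } else {
    cmb <- utils::combn(hub, 2)
    ia(cmb[1, ], cmb[2, ])
  }
}

#' All four default network scales
#' @inheritParams scale_def
#' @return Named list of [scale_def()]s.
#' @export
default_scales <- function(channels = montage_channels(),
                           local_mode = "center") {
  names <- c("global", "large", "local_left", "local_right")
  out <- lapply(names, scale_def, channels = channels,
                local_mode = local_mode)
  names(out) <- names
  out
}

#' Average PLV over a network scale
#'
#' Unweighted arithmetic mean of the pairwise PLV over the scale's pair
#' set, for every (subject_id, condition, window, band) group in the
#' table. Errors if any of the scale's pairs is absent from a group.
#'
#' @param plv_table Tidy PLV table as from [compute_plv_table()].
#' @param scale A [scale_def()] or list of them.
#' @return Tibble: subject_id, condition, window, band, scale, mean_plv.
#' @export
scale_average <- function(plv_table, scale) {
  if (inherits(scale, "scale_def")) scale <- list(scale)
  out <- lapply(scale, function(sc) {
    key <- paste(sc$pairs$channel_i, sc$pairs$channel_j, sep = "|")
    tab_key <- paste(plv_table$channel_i, plv_table$channel_j, sep = "|")
    sub <- plv_table[tab_key %in% key, , drop = FALSE]
    res <- dplyr::summarise(
      dplyr::group_by(sub, .data$subject_id, .data$condition,
                      .data$window, .data$band),
      mean_plv = mean(.data$plv), n_pairs = dplyr::n(), .groups = "drop")
    short <- res$n_pairs < length(key)
    if (any(short)) {
      grp <- res[which(short)[1], ]
      have <- tab_key[plv_table$subject_id == grp$subject_id &
                        plv_table$condition == grp$condition &
                        plv_table$window == grp$window &
                        plv_table$band == grp$band]
      stop("scale '", sc$name, "' pair(s) missing from PLV table: ",
           paste(setdiff(key, have), collapse = ", "))
    }
    res$scale <- sc$name
    res[, c("subject_id", "condition", "window", "band", "scale",
            "mean_plv")]
  })
  dplyr::bind_rows(out)
}
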