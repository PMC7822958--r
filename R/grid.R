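#' Default prefrontal channel layout
#'
#' Returns the layout table for the standard forehead probe: 38 channels from
#' a modified 3x11 optode grid (12 emitters, 13 detectors, inter-optode
#' distance 3 cm). The 32 analyzed channels form, per hemisphere, 4
#' rostro-caudally oriented streams of 4 channels each (level 1 = most
#' rostral). The 6 midline channels are carried along but excluded from the
#' stream/level analysis. Channel positions are on the staggered lattice
#' implied by the optode grid, so that rostro-caudally adjacent channels sit
#' at the diagonal distance of inter-optode distance / sqrt(2) (2.1 cm for a
#' 3 cm grid).
#'
#' @param inter_optode_cm Inter-optode distance in cm (default 3).
#' @param analyzed_only If `TRUE`, drop the midline channels and return only
#'   the 32 analyzed channels.
#' @return A data frame with columns `id`, `x`, `y` (cm), `hemisphere`
#'   (`"left"`/`"right"`), `stream` (1-4 or `NA`), `level` (1-4 or `NA`) and
#'   `analyzed` (logical).
#' @export
default_grid_layout <- function(inter_optode_cm = 3, analyzed_only = FALSE) {
  u <- inter_optode_cm / 2
  rows <- list()
  for (hemi in c("left", "right")) {
    hsign <- if (hemi == "left") -1 else 1
    for (stream in 1:4) {
      for (level in 1:4) {
        # rostro-caudal axis along +y (level 1 most rostral at smallest y);
        # levels zig-zag in x so neighbors are diagonal at distance u*sqrt(2)
        x <- hsign * (2 * u + (stream - 1) * 2 * u + (level %% 2) * u)
        y <- (level - 1) * u
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("%s_s%d_l%d", substr(hemi, 1, 1), stream, level),
          x = x, y = y, hemisphere = hemi, stream = stream, level = level,
          analyzed = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  if (!analyzed_only) {
    # 6 midline channels, not assigned to any stream
    for (k in 1:6) {
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("m_%d", k), x = (k %% 2) * u - u / 2, y = (k - 1) * u / 1.5,
        hemisphere = if (k %% 2 == 0) "right" else "left",
        stream = NA_integer_, level = NA_integer_,
        analyzed = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build and validate a channel grid
#'
#' Validates a channel layout for rostro-caudal stream analysis: per
#' hemisphere the analyzed channels must tile exactly 4 streams x 4 levels
#' (or, for reduced grids, a complete `n_streams` x `n_levels` rectangle),
#' with levels strictly ordered along the rostro-caudal axis within each
#' stream.
#'
#' @param layout A data frame as returned by [default_grid_layout()], or a
#'   path to a delimited file with the same columns.
#' @param inter_optode_cm Inter-optode distance in cm; used to derive the
#'   diagonal channel distance.
#' @return An object of class `channel_grid`: the validated layout data frame
#'   with attributes `inter_optode_cm`, `diagonal_distance_cm`, `n_streams`,
#'   `n_levels`.
#' @export
build_channel_grid <- function(layout = default_grid_layout(),
                               inter_optode_cm = 3) {
  if (is.character(layout)) {
    layout <- utils::read.delim(layout, sep = "\t", stringsAsFactors = FALSE)
  }
  need <- c("id", "x", "y", "hemisphere", "stream", "level")
  miss <- setdiff(need, names(layout))
  if (length(miss)) {
    stop("configuration error: layout lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!"analyzed" %in% names(layout)) layout$analyzed <- !is.na(layout$stream)
  if (anyDuplicated(layout$id)) {
    stop("configuration error: duplicate channel id(s): ",
         paste(unique(layout$id[duplicated(layout$id)]), collapse = ", "))
  }
  ana <- layout[layout$analyzed, , drop = FALSE]
  if (!nrow(ana)) stop("configuration error: no analyzed channels")
  streams <- sort(unique(ana$stream))
  levels <- sort(unique(ana$level))
  for (h in unique(ana$hemisphere)) {
    sub <- ana[ana$hemisphere == h, ]
    for (s in streams) {
      got <- sort(sub$level[sub$stream == s])
      if (!identical(got, levels)) {
        gap <- setdiff(levels, got)
        stop("configuration error: hemisphere ", h, ", stream ", s,
             " missing level(s) ", paste(gap, collapse = ", "))
      }
    }
    # rostro-caudal ordering: level must be strictly monotone in y per stream
    for (s in streams) {
      sub2 <- sub[sub$stream == s, ]
      sub2 <- sub2[order(sub2$level), ]
      if (any(diff(sub2$y) <= 0)) {
        stop("configuration error: levels not strictly ordered ",
             "rostro-caudally in hemisphere ", h, ", stream ", s)
      }
    }
  }
  structure(layout,
            class = c("channel_grid", "data.frame"),
            inter_optode_cm = inter_optode_cm,
            diagonal_distance_cm = inter_optode_cm / sqrt(2),
            n_streams = length(streams),
            n_levels = length(levels))
}

#' Reduced rectangular grid for simulation studies
#'
#' Convenience constructor for smaller stream/level grids (fewer streams,
#' levels or hemispheres) used in Monte-Carlo studies where the full
#' 32-channel grid is unnecessarily expensive.
#'
#' @param n_streams,n_levels Number of streams and levels per hemisphere.
#' @param hemispheres Character vector, subset of `c("left","right")`.
#' @param inter_optode_cm Inter-optode distance in cm.
#' @return A `channel_grid`.
#' @export
make_grid <- function(n_streams = 4, n_levels = 4,
                      hemispheres = c("left", "right"),
                      inter_optode_cm = 3) {
  u <- inter_optode_cm / 2
  rows <- list()
  for (hemi in hemispheres) {
    hsign <- if (hemi == "left") -1 else 1
    for (stream in seq_len(n_streams)) {
      for (level in seq_len(n_levels)) {
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("%s_s%d_l%d", substr(hemi, 1, 1), stream, level),
          x = hsign * (2 * u + (stream - 1) * 2 * u + (level %% 2) * u),
          y = (level - 1) * u,
          hemisphere = hemi, stream = stream, level = level,
          analyzed = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  build_channel_grid(do.call(rbind, rows), inter_optode_cm = inter_optode_cm)
}

#' @export
print.channel_grid <- function(x, ...) {
  cat("Channel grid: ", nrow(x), " channels (",
      sum(x$analyzed), " analyzed), ",
      attr(x, "n_streams"), " streams x ", attr(x, "n_levels"),
      " levels per hemisphere\n", sep = "")
  cat(sprintf("  inter-optode %.1f cm, diagonal channel distance %.2f cm\n",
              attr(x, "inter_optode_cm"), attr(x, "diagonal_distance_cm")))
  invisible(x)
}

#' Ids of the analyzed channels of a grid
#'
#' @param grid A [build_channel_grid()].
#' @return Character vector of channel ids with stream/level assignments.
#' @export
analyzed_channels <- function(grid) {
  grid$id[grid$analyzed]
}
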