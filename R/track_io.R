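# Canonical track-table ingestion, validation, regularization.
#
# The canonical currency of the whole package is a long-format tibble with
# one row per (cell, frame): cell_id, group, frame (0-based int), t (s),
# x/y/z (um), optional unit polarity vector px/py/pz. All downstream
# modules consume this one structure.

TRACK_CORE_COLS <- c("cell_id", "group", "frame", "t", "x", "y")
POLARITY_COLS <- c("px", "py", "pz")

#' Describe the column layout of a track export
#'
#' A dialect maps the columns of a delimited tracking export onto the
#' canonical track-table fields and records the file's units and frame
#' numbering. Two dialects ship with the package: `"canonical"` (the
#' package's own output format) and `"imaris"` (a common commercial-tracker
#' export with `TrackID`, `Time`, `Position X/Y/Z` columns and 1-based
#' frames). Any field can be overridden to register further layouts.
#'
#' @param name Base dialect, `"canonical"` or `"imaris"`.
#' @param sep Field delimiter.
#' @param cols Named list mapping canonical fields (`cell_id`, `group`,
#'   `frame`, `t`, `x`, `y`, `z`, `px`, `py`, `pz`) to source column names;
#'   `NULL` entries mark fields absent from the file.
#' @param pos_scale Multiplier taking file positions to micrometers.
#' @param time_scale Multiplier taking file times to seconds.
#' @param frame_base Frame index of the first frame in the file (0 or 1).
#' @return A `track_dialect` list.
#' @export
track_dialect <- function(name = c("canonical", "imaris"),
                          sep = NULL, cols = NULL,
                          pos_scale = NULL, time_scale = NULL,
                          frame_base = NULL) {
  name <- match.arg(name)
  base <- switch(name,
    canonical = list(
      sep = ",",
      cols = list(cell_id = "cell_id", group = "group", frame = "frame",
                  t = "t", x = "x", y = "y", z = "z",
                  px = "px", py = "py", pz = "pz"),
      pos_scale = 1, time_scale = 1, frame_base = 0L
    ),
    imaris = list(
      sep = ",",
      cols = list(cell_id = "TrackID", group = NULL, frame = "Time",
                  t = NULL, x = "Position X", y = "Position Y",
                  z = "Position Z", px = NULL, py = NULL, pz = NULL),
      pos_scale = 1, time_scale = 1, frame_base = 1L
    )
  )
  if (!is.null(sep)) base$sep <- sep
  if (!is.null(cols)) base$cols <- modifyList(base$cols, cols)
  if (!is.null(pos_scale)) base$pos_scale <- pos_scale
  if (!is.null(time_scale)) base$time_scale <- time_scale
  if (!is.null(frame_base)) base$frame_base <- as.integer(frame_base)
  base$name <- name
  structure(base, class = "track_dialect")
}

#' Coerce and validate a canonical track table
#'
#' Coerces column types, sorts by (`cell_id`, `frame`) and enforces the
#' track-table invariants: unique (cell, frame) pairs, strictly increasing
#' time within each cell, finite positions, a single group per cell, z
#' either present for a whole cell or absent for the whole table (no mixed
#' 2D/3D cells), and unit-norm polarity vectors where present.
#'
#' @param df A data frame with at least `cell_id`, `group`, `frame`, `t`,
#'   `x`, `y` columns.
#' @return A validated `track_table` tibble sorted by cell and frame.
#' @export
as_track_table <- function(df) {
  df <- as_tibble(df)
  missing <- setdiff(TRACK_CORE_COLS, names(df))
  if (length(missing) > 0) {
    stop_format(paste0("missing mandatory column(s): ",
                       paste(missing, collapse = ", ")))
  }
  df$cell_id <- as.character(df$cell_id)
  df$group <- as.character(df$group)
  df$frame <- as.integer(df$frame)
  for (cc in intersect(c("t", "x", "y", "z", POLARITY_COLS), names(df))) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  ord <- order(df$cell_id, df$frame, method = "radix")
  df <- df[ord, , drop = FALSE]
  validate_tracks(df)
  # canonical column order, extras (opaque annotations) trailing
  canon <- intersect(c(TRACK_CORE_COLS, "z", POLARITY_COLS), names(df))
  df <- df[, c(canon, setdiff(names(df), canon)), drop = FALSE]
  class(df) <- unique(c("track_table", class(df)))
  df
}

#' Validate track-table invariants
#'
#' @param df A track table (sorted by cell and frame).
#' @param require_uniform_dt If `TRUE`, additionally require one constant
#'   inter-frame interval across the whole table (relative tolerance
#'   `tol`), i.e. the table must already be regularized.
#' @param tol Relative tolerance for the uniform-interval check.
#' @return `df`, invisibly.
#' @export
validate_tracks <- function(df, require_uniform_dt = FALSE, tol = 1e-6) {
  if (nrow(df) == 0) {
    return(invisible(df))
  }
  dup <- duplicated(df[, c("cell_id", "frame")])
  if (any(dup)) {
    stop_validation(paste0("duplicated (cell_id, frame) rows, e.g. cell '",
                           df$cell_id[dup][1], "' frame ",
                           df$frame[dup][1]))
  }
  if (anyNA(df$frame) || any(df$frame < 0)) {
    stop_validation("frames must be non-negative integers")
  }
  pos_cols <- intersect(c("x", "y", "z"), names(df))
  if ("z" %in% names(df)) {
    z_na <- is.na(df$z)
    if (all(z_na)) {
      pos_cols <- c("x", "y")  # uniformly 2D; treated as absent
    } else if (any(z_na)) {
      bad <- unique(df$cell_id[z_na])
      stop_validation(paste0("mixed 2D/3D positions within cell(s): ",
                             paste(head(bad, 3), collapse = ", ")))
    }
  }
  for (cc in pos_cols) {
    if (any(!is.finite(df[[cc]]))) {
      stop_validation(paste0("non-finite values in position column '", cc, "'"))
    }
  }
  # per-cell checks on the sorted table
  cells <- rle(df$cell_id)
  ends <- cumsum(cells$lengths)
  starts <- ends - cells$lengths + 1L
  for (i in seq_along(cells$values)) {
    idx <- starts[i]:ends[i]
    fr <- df$frame[idx]
    tt <- df$t[idx]
    if (length(idx) > 1) {
      if (any(diff(fr) <= 0)) {
        stop_validation(paste0("frames not strictly increasing within cell '",
                               cells$values[i], "'"))
      }
      if (anyNA(tt) || any(diff(tt) <= 0)) {
        stop_validation(paste0("time not strictly increasing within cell '",
                               cells$values[i], "'"))
      }
    }
    if (length(unique(df$group[idx])) != 1) {
      stop_validation(paste0("cell '", cells$values[i],
                             "' maps to more than one group"))
    }
  }
  if (all(POLARITY_COLS %in% names(df))) {
    pm <- as.matrix(df[, POLARITY_COLS])
    pna <- rowSums(is.na(pm))
    if (any(pna > 0 & pna < 3)) {
      stop_validation("polarity vectors must be fully present or fully NA per row")
    }
    ok <- pna == 0
    if (any(ok)) {
      nr <- sqrt(rowSums(pm[ok, , drop = FALSE]^2))
      if (any(abs(nr - 1) > 1e-6)) {
        stop_validation("polarity vectors must have unit norm")
      }
    }
  } else if (any(POLARITY_COLS %in% names(df))) {
    stop_validation("polarity requires all three columns px, py, pz")
  }
  if (require_uniform_dt) {
    dts <- track_dt(df)
    if (is.na(dts)) {
      stop_validation(paste0("inter-frame interval is not uniform (tolerance ",
                             tol, "); call regularize() first"))
    }
  }
  invisible(df)
}

# The table's single inter-frame interval, or NA if not uniform to within
# relative tolerance tol.
track_dt <- function(df, tol = 1e-6) {
  d <- unlist(lapply(split(df$t, df$cell_id), diff), use.names = FALSE)
  if (length(d) == 0) {
    return(NA_real_)
  }
  dt <- median(d)
  if (any(abs(d - dt) > tol * dt)) {
    return(NA_real_)
  }
  dt
}

#' Read a delimited track export into a canonical track table
#'
#' Parses a tracking-software export according to a [track_dialect()],
#' converts units to micrometers/seconds and frames to 0-based indices,
#' attaches group labels, optionally fills short within-track gaps (see
#' [fill_gaps()]), and validates the result. Columns of the file not named
#' by the dialect are preserved unchanged as opaque annotations.
#'
#' @param path File to read.
#' @param dialect A [track_dialect()].
#' @param group Single group label applied to all cells, used when the file
#'   has no group column.
#' @param group_map Named character vector `cell_id -> group`, an
#'   alternative to `group`.
#' @param dt Inter-frame interval in seconds; required when the dialect has
#'   no time column (time is then reconstructed as `frame * dt`).
#' @param max_gap Maximum number of consecutive missing frames filled by
#'   linear interpolation; longer gaps split the track (see [fill_gaps()]).
#'   Set to `NULL` to leave gaps untouched.
#' @return A `track_table`.
#' @export
read_tracks <- function(path, dialect = track_dialect("canonical"),
                        group = NULL, group_map = NULL, dt = NULL,
                        max_gap = 2L) {
  if (!file.exists(path)) {
    stop_format(paste0("file not found: ", path))
  }
  raw <- readr::read_delim(path, delim = dialect$sep, show_col_types = FALSE,
                           progress = FALSE)
  cols <- dialect$cols
  need <- c("cell_id", "frame", "x", "y")
  for (f in need) {
    src <- cols[[f]]
    if (is.null(src) || !(src %in% names(raw))) {
      stop_format(paste0("missing mandatory column '", f %||% "?",
                         "' (expected source column '",
                         cols[[f]] %||% "<unmapped>", "')"))
    }
  }
  out <- tibble(
    cell_id = as.character(raw[[cols$cell_id]]),
    frame = as.integer(as.numeric(raw[[cols$frame]])) - dialect$frame_base,
    x = as.numeric(raw[[cols$x]]) * dialect$pos_scale,
    y = as.numeric(raw[[cols$y]]) * dialect$pos_scale
  )
  if (!is.null(cols$z) && cols$z %in% names(raw)) {
    zz <- as.numeric(raw[[cols$z]]) * dialect$pos_scale
    if (!all(is.na(zz))) out$z <- zz
  }
  if (!is.null(cols$t) && cols$t %in% names(raw)) {
    out$t <- as.numeric(raw[[cols$t]]) * dialect$time_scale
  } else {
    if (is.null(dt)) {
      stop_format("dialect has no time column; supply dt (seconds per frame)")
    }
    out$t <- out$frame * dt
  }
  if (!is.null(cols$group) && cols$group %in% names(raw)) {
    out$group <- as.character(raw[[cols$group]])
  } else if (!is.null(group_map)) {
    out$group <- unname(group_map[out$cell_id])
    if (anyNA(out$group)) {
      stop_format(paste0("group_map has no entry for cell(s): ",
                         paste(head(unique(out$cell_id[is.na(out$group)]), 3),
                               collapse = ", ")))
    }
  } else if (!is.null(group)) {
    out$group <- group
  } else {
    stop_format("no group column in file; supply group= or group_map=")
  }
  for (f in POLARITY_COLS) {
    if (!is.null(cols[[f]]) && cols[[f]] %in% names(raw)) {
      out[[f]] <- as.numeric(raw[[cols[[f]]]])
    }
  }
  used <- unlist(cols[!vapply(cols, is.null, logical(1))])
  extras <- setdiff(names(raw), used)
  for (e in extras) out[[e]] <- raw[[e]]
  out <- as_track_table(out)
  if (!is.null(max_gap)) {
    out <- fill_gaps(out, max_gap = max_gap)
  }
  out
}

#' Write a track table as canonical delimited text
#'
#' The output is lossless for all canonical fields and re-readable with
#' `read_tracks(path)` under the default dialect.
#'
#' @param table A `track_table`.
#' @param path Output file.
#' @param sep Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(table, path, sep = ",") {
  validate_tracks(table)
  readr::write_delim(as_tibble(table), path, delim = sep)
  invisible(path)
}

#' Fill or split gaps inside tracks
#'
#' Tracklet metrics assume uniform sampling, so missing frames inside a
#' track are repaired: runs of at most `max_gap` consecutive missing frames
#' are filled by linear interpolation of positions (and time); longer gaps
#' split the track into independent segments whose ids get a `#k` suffix.
#' Polarity vectors, when present, are interpolated and renormalized.
#'
#' @param table A `track_table`.
#' @param max_gap Maximum gap length (missing frames) to interpolate.
#' @return A `track_table` with contiguous frames within every cell.
#' @export
fill_gaps <- function(table, max_gap = 2L) {
  validate_tracks(table)
  if (nrow(table) == 0) {
    return(table)
  }
  pieces <- lapply(split(as_tibble(table), table$cell_id), function(cc) {
    if (nrow(cc) < 2 || all(diff(cc$frame) == 1L)) {
      return(cc)
    }
    gaps <- diff(cc$frame) - 1L
    seg <- cumsum(c(0L, gaps > max_gap))
    segs <- split(cc, seg)
    n_seg <- length(segs)
    segs <- lapply(seq_along(segs), function(i) {
      s <- segs[[i]]
      if (n_seg > 1) s$cell_id <- paste0(s$cell_id, "#", i)
      if (nrow(s) < 2 || all(diff(s$frame) == 1L)) {
        return(s)
      }
      full <- s$frame[1]:s$frame[nrow(s)]
      out <- s[rep(1L, length(full)), , drop = FALSE]
      out$frame <- full
      num_cols <- intersect(c("t", "x", "y", "z", POLARITY_COLS), names(s))
      for (cc2 in num_cols) {
        out[[cc2]] <- approx(s$frame, s[[cc2]], xout = full)$y
      }
      if (all(POLARITY_COLS %in% names(out))) {
        pm <- normalize_rows(as.matrix(out[, POLARITY_COLS]))
        out[, POLARITY_COLS] <- pm
      }
      out
    })
    bind_rows(segs)
  })
  as_track_table(bind_rows(pieces))
}

#' Resample tracks onto a uniform time grid
#'
#' Per cell, positions are linearly interpolated onto the grid
#' `t_first, t_first + dt_target, ...` up to the last observed time; the
#' resampling never extrapolates and preserves each cell's start time.
#' Upsampling is refused. Cells with fewer than two frames on the new grid
#' are dropped with a message.
#'
#' @param table A `track_table`.
#' @param dt_target Target inter-frame interval in seconds; must be at
#'   least the table's native interval.
#' @param tol Relative tolerance when comparing intervals.
#' @return A regularized `track_table` with uniform `dt_target` sampling.
#' @export
regularize <- function(table, dt_target, tol = 1e-6) {
  validate_tracks(table)
  if (!is_number(dt_target) || dt_target <= 0) {
    stop_config("dt_target must be a positive number of seconds")
  }
  if (nrow(table) == 0) {
    return(table)
  }
  dropped <- character(0)
  pieces <- lapply(split(as_tibble(table), table$cell_id), function(cc) {
    if (nrow(cc) < 2) {
      dropped <<- c(dropped, cc$cell_id[1])
      return(NULL)
    }
    native <- min(diff(cc$t))
    if (dt_target < native * (1 - tol)) {
      stop_validation(paste0(
        "dt_target (", dt_target, " s) is below the native interval (",
        signif(native, 6), " s) of cell '", cc$cell_id[1],
        "'; upsampling is not supported"))
    }
    n_new <- floor((cc$t[nrow(cc)] - cc$t[1]) / dt_target + tol) + 1L
    if (n_new < 2) {
      dropped <<- c(dropped, cc$cell_id[1])
      return(NULL)
    }
    grid <- cc$t[1] + dt_target * (0:(n_new - 1L))
    out <- tibble(cell_id = cc$cell_id[1], group = cc$group[1],
                  frame = 0:(n_new - 1L), t = grid)
    for (cc2 in intersect(c("x", "y", "z", POLARITY_COLS), names(cc))) {
      if (all(is.na(cc[[cc2]]))) next
      out[[cc2]] <- approx(cc$t, cc[[cc2]], xout = grid)$y
    }
    if (all(POLARITY_COLS %in% names(out))) {
      out[, POLARITY_COLS] <- normalize_rows(as.matrix(out[, POLARITY_COLS]))
    }
    out
  })
  if (length(dropped) > 0) {
    message("regularize: dropped ", length(dropped),
            " cell(s) with < 2 frames on the new grid")
  }
  out <- as_track_table(bind_rows(pieces))
  attr(out, "dropped_cells") <- dropped
  out
}
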