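#' Resampling configuration
#'
#' Controls how raw, possibly irregular monitor records are aligned to the
#' uniform 1-minute grid. The fill method is applied to the protocol-sparse
#' channels in `fill_channels` (by default the non-invasive cuff pressures,
#' which are only measured every few minutes): `forward_fill` carries the last
#' observed reading until the next one, the clinical convention that a stable
#' cuff reading persists until re-measured; `linear_interpolation` is the
#' sensitivity-analysis alternative and interpolates between observations
#' only, never extrapolating. Continuous channels keep their gaps, so that
#' monitor dropout remains measurable as missingness downstream.
#'
#' @param interval Grid interval in minutes (default 1).
#' @param method `"forward_fill"` (default) or `"linear_interpolation"`.
#' @param fill_channels Channels the fill method applies to; `"all"` applies
#'   it to every channel.
#' @return A list of class `resample_config`.
#' @export
resample_config <- function(interval = 1,
                            method = c("forward_fill", "linear_interpolation"),
                            fill_channels = c("NIBP_SYS", "NIBP_DIA")) {
  stopifnot_scalar_number(interval, "interval", lower = 1e-9)
  method <- match.arg(method)
  structure(list(interval = interval, method = method,
                 fill_channels = fill_channels),
            class = "resample_config")
}

#' Read one surgical case's vital-sign record from CSV
#'
#' Two dialects are supported. The canonical long dialect has columns
#' `time_min, channel, value` (missing value = empty field); the wide dialect
#' has `time_min` plus one column per channel. Channel names are mapped onto
#' the controlled vocabulary via [ioh_channel_aliases()]; unknown names are
#' preserved verbatim. Times may be irregular; use [resample_to_grid()] to
#' align them.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @param case_id Case identifier; defaults to a `case_id` column if present,
#'   else the file name without extension.
#' @param aliases Named character vector of extra channel aliases, merged over
#'   the defaults.
#' @return A wide tibble with columns `case_id`, `time_min` and one column per
#'   channel (`NA` = missing), ordered by time.
#' @export
read_case <- function(path, dialect = c("long", "wide"), case_id = NULL,
                      aliases = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) abort(paste0("empty vital-sign file: ", path))

  num_or_fail <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad)) {
      abort(sprintf("malformed value in column '%s' at data line %d of %s: '%s'",
                    col, bad[1], path, x[bad[1]]))
    }
    out
  }

  cid <- if (!is.null(case_id)) {
    rep(as.character(case_id), nrow(raw))
  } else if ("case_id" %in% names(raw)) {
    as.character(raw$case_id)
  } else {
    rep(sub("\\.[^.]*$", "", basename(path)), nrow(raw))
  }

  if (dialect == "long") {
    need <- c("time_min", "channel", "value")
    if (!all(need %in% names(raw))) {
      abort(paste0("long dialect requires columns time_min, channel, value; found: ",
                   paste(names(raw), collapse = ", ")))
    }
    df <- tibble(
      case_id = cid,
      time_min = num_or_fail(raw$time_min, "time_min"),
      channel = canonical_channel(raw$channel, aliases),
      value = num_or_fail(raw$value, "value")
    )
    if (anyNA(df$time_min)) {
      abort(sprintf("missing time_min at data line %d of %s",
                    which(is.na(df$time_min))[1], path))
    }
    wide <- df |>
      tidyr::pivot_wider(names_from = "channel", values_from = "value",
                         values_fn = function(x) x[length(x)]) |>
      arrange(.data$case_id, .data$time_min)
  } else {
    if (!"time_min" %in% names(raw)) abort("wide dialect requires a time_min column")
    chans <- setdiff(names(raw), c("time_min", "case_id", "patient_id"))
    wide <- tibble(case_id = cid, time_min = num_or_fail(raw$time_min, "time_min"))
    for (ch in chans) wide[[canonical_channel(ch, aliases)]] <- num_or_fail(raw[[ch]], ch)
    wide <- arrange(wide, .data$case_id, .data$time_min)
  }
  as_tibble(wide)
}

#' Write one case's vital-sign record to CSV
#'
#' Inverse of [read_case()]: lossless round-trip for grid-aligned series.
#' Missing values are written as empty fields.
#'
#' @param vitals Wide tibble as returned by [read_case()] / [resample_to_grid()].
#' @param path Output CSV path.
#' @param dialect `"long"` (canonical) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_case <- function(vitals, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  assert_vitals(vitals)
  chans <- channel_cols(vitals)
  if (dialect == "long") {
    long <- vitals |>
      tidyr::pivot_longer(all_of(chans), names_to = "channel", values_to = "value") |>
      select(all_of(c("case_id", "time_min", "channel", "value")))
    readr::write_csv(long, path, na = "")
  } else {
    readr::write_csv(select(vitals, all_of(c("case_id", "time_min", chans))), path, na = "")
  }
  invisible(path)
}

#' Align a raw vital-sign record to the uniform 1-minute grid
#'
#' Each channel's observations are binned into half-open 1-minute epochs
#' `[t, t+1)` (the last observation in a bin wins; duplicate timestamps for a
#' channel keep the last value with a warning). Channels listed in
#' `cfg$fill_channels` are then gap-filled per `cfg$method`: forward fill
#' carries the last observation until the next one and never fills before the
#' channel's first observation; linear interpolation acts only between
#' observations. The operation is idempotent on its own output.
#'
#' @param vitals Wide tibble from [read_case()] (one or more cases).
#' @param cfg A [resample_config()].
#' @return Wide tibble on the integer minute grid `0..duration-1` per case.
#' @export
resample_to_grid <- function(vitals, cfg = resample_config()) {
  assert_vitals(vitals)
  chans <- channel_cols(vitals)
  fill_ch <- if (identical(cfg$fill_channels, "all")) chans else
    intersect(cfg$fill_channels, chans)

  resample_one <- function(df) {
    tt <- df$time_min
    if (is.unsorted(tt)) abort("raw timestamps must be non-decreasing within a case")
    bins <- floor(tt / cfg$interval)
    grid <- seq.int(0L, max(bins))
    out <- tibble(case_id = df$case_id[1], time_min = as.integer(grid))
    if ("patient_id" %in% names(df)) out$patient_id <- df$patient_id[1]
    for (ch in chans) {
      v <- df[[ch]]
      obs <- which(!is.na(v))
      col <- rep(NA_real_, length(grid))
      if (length(obs)) {
        if (anyDuplicated(tt[obs])) {
          warn(sprintf("duplicate timestamps for channel %s in case %s: keeping last",
                       ch, df$case_id[1]))
        }
        # last observation per bin wins (also resolves duplicate timestamps)
        col[bins[obs] + 1L] <- v[obs]
        if (ch %in% fill_ch) {
          ob <- which(!is.na(col))
          if (length(ob) >= 1L) {
            if (cfg$method == "forward_fill") {
              idx <- findInterval(seq_along(col), ob)
              filled <- col[ob][pmax(idx, 1L)]
              filled[idx == 0L] <- NA_real_   # nothing before first observation
              col <- filled
            } else if (length(ob) >= 2L) {
              col <- stats::approx(x = ob, y = col[ob], xout = seq_along(col),
                                   method = "linear", rule = 1)$y
            }
          }
        }
      }
      out[[ch]] <- col
    }
    out
  }

  vitals |>
    group_by(.data$case_id) |>
    dplyr::group_split() |>
    purrr::map(resample_one) |>
    bind_rows()
}
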