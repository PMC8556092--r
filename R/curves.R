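#' Construct a depth-ionization curve
#'
#' @param depth Depths in mm, strictly increasing, at least 5 samples.
#' @param reading Chamber readings (arbitrary charge units), >= 0.
#' @param metadata Named list: chamber, energy (MeV/u), field_size (cm),
#'   normalized (logical), plus free-form entries.
#' @return Data frame of class `depth_curve` with columns `depth_mm` and
#'   `reading`; metadata kept in the `"meta"` attribute.
#' @export
depth_curve <- function(depth, reading, metadata = list()) {
  stopifnot(is.numeric(depth), is.numeric(reading),
            length(depth) == length(reading))
  if (length(depth) < 5L) {
    stop("a depth-ionization curve needs at least 5 samples, got ",
         length(depth), call. = FALSE)
  }
  dd <- diff(depth)
  if (any(dd == 0)) {
    stop("duplicate depth at row ", which(dd == 0)[1] + 1L, call. = FALSE)
  }
  if (any(dd < 0)) {
    stop("depths not strictly increasing at row ", which(dd < 0)[1] + 1L,
         call. = FALSE)
  }
  if (any(reading < 0)) {
    stop("negative reading at row ", which(reading < 0)[1], call. = FALSE)
  }
  out <- data.frame(depth_mm = depth, reading = reading)
  attr(out, "meta") <- utils::modifyList(list(normalized = FALSE), metadata)
  class(out) <- c("depth_curve", "data.frame")
  out
}

#' Metadata of a depth curve
#' @param curve A [depth_curve()].
#' @return Named list of metadata.
#' @export
curve_meta <- function(curve) attr(curve, "meta")

#' @export
print.depth_curve <- function(x, ...) {
  m <- curve_meta(x)
  cat(sprintf("<depth_curve> %d samples, depth %.2f-%.2f mm%s\n",
              nrow(x), min(x$depth_mm), max(x$depth_mm),
              if (isTRUE(m$normalized)) ", peak-normalized" else ""))
  for (k in setdiff(names(m), "normalized")) {
    cat(sprintf("  %s: %s\n", k, format(m[[k]])))
  }
  invisible(x)
}

#' Read a depth-ionization curve from delimited text
#'
#' Accepts two-column comma- or tab-separated text with columns
#' `depth_mm,reading`, an optional header row, and optional leading
#' `# key=value` metadata lines. Depth monotonicity, duplicate depths,
#' negative readings and minimum length are validated with the offending
#' data row number in the error.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab.
#' @return A [depth_curve()].
#' @export
read_curve <- function(path, sep = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\t", body[1])) "\t" else ","
  has_header <- !grepl("^[0-9.+-]", trimws(strsplit(body[1], sep)[[1]][1]))
  dat <- utils::read.table(text = body, sep = sep, header = has_header,
                           strip.white = TRUE)
  if (ncol(dat) < 2L) stop("expected two columns in ", path, call. = FALSE)
  if (!is.numeric(dat[[1]]) || !is.numeric(dat[[2]])) {
    stop("non-numeric data in ", path, call. = FALSE)
  }
  meta <- list()
  for (ml in meta_lines) {
    kv <- regmatches(ml, regexec("^#\\s*([^=]+?)\\s*=\\s*(.*)$", ml))[[1]]
    if (length(kv) == 3L) {
      v <- utils::type.convert(kv[3], as.is = TRUE)
      meta[[kv[2]]] <- v
    }
  }
  depth_curve(dat[[1]], dat[[2]], metadata = meta)
}

#' Write a depth-ionization curve as delimited text
#'
#' Inverse of [read_curve()]: metadata as `# key=value` lines, a header
#' row, then `depth_mm,reading` records at full precision (17 significant
#' digits, so write-read round-trips are bit-exact).
#'
#' @param curve A [depth_curve()].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, sep = ",") {
  m <- curve_meta(curve)
  hdr <- vapply(names(m), function(k) {
    sprintf("# %s=%s", k, format(m[[k]], digits = 17))
  }, character(1))
  rows <- sprintf("%s%s%s",
                  formatC(curve$depth_mm, digits = 17, format = "g"), sep,
                  formatC(curve$reading, digits = 17, format = "g"))
  writeLines(c(hdr, paste0("depth_mm", sep, "reading"), rows), path)
  invisible(path)
}

#' Normalize a curve to its peak
#'
#' Scales readings so the maximum sample equals 1.0. Idempotent.
#'
#' @param curve A [depth_curve()].
#' @return Peak-normalized [depth_curve()].
#' @export
normalize_to_peak <- function(curve) {
  mx <- max(curve$reading)
  if (mx <= 0) stop("cannot normalize: all readings are zero", call. = FALSE)
  meta <- curve_meta(curve)
  meta$normalized <- TRUE
  depth_curve(curve$depth_mm, curve$reading / mx, metadata = meta)
}

#' Locate the Bragg peak of a depth-ionization curve
#'
#' The peak is the vertex abscissa of a least-squares parabola fitted to
#' the samples within `window_mm` of the maximum sample (ties on the
#' maximum broken toward the smaller depth). Exact for any symmetric peak
#' sampled symmetrically about its centre. The maximum must not sit at
#' either end of the sampled range.
#'
#' @param curve A [depth_curve()].
#' @param window_mm Half-width of the fit window in mm (default 2).
#' @return Peak depth in mm.
#' @export
find_peak_depth <- function(curve, window_mm = 2) {
  i_max <- which.max(curve$reading)          # first index on ties
  if (i_max == 1L || i_max == nrow(curve)) {
    stop("maximum reading sits at the boundary of the sampled range; ",
         "extend the scan range", call. = FALSE)
  }
  d0 <- curve$depth_mm[i_max]
  sel <- abs(curve$depth_mm - d0) <= window_mm
  if (sum(sel) < 3L) sel <- seq(max(1L, i_max - 1L), min(nrow(curve), i_max + 1L))
  x <- curve$depth_mm[sel] - d0
  y <- curve$reading[sel]
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  a <- fit$coefficients[3]; b <- fit$coefficients[2]
  if (!is.finite(a) || a >= 0) {
    # degenerate window (flat or upward-curved): fall back to the sample max
    return(d0)
  }
  unname(d0 - b / (2 * a))
}

#' Construct a beam-setup WET chain
#'
#' The item-by-item water-equivalent-thickness accounting between the
#' nozzle and a chamber's point of measurement: tank wall, clearances,
#' chamber windows. Summed WET is added to raw peak positions to obtain
#' water-equivalent peak depths.
#'
#' @param chain Data frame with columns `label`, `wet_mm` (and optionally
#'   `physical_mm`); `wet_mm` must be >= 0 and non-missing.
#' @param chamber Optional [chamber_spec()] reference.
#' @param raw_position_offset Stage coordinate of the point of measurement
#'   at zero depth, mm (default 0).
#' @return An object of class `beam_setup`.
#' @export
beam_setup <- function(chain, chamber = NULL, raw_position_offset = 0) {
  chain <- as.data.frame(chain)
  if (!all(c("label", "wet_mm") %in% names(chain))) {
    stop("chain needs columns 'label' and 'wet_mm'", call. = FALSE)
  }
  bad <- chain$label[is.na(chain$wet_mm)]
  if (length(bad)) {
    stop("missing WET for chain item(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(chain$wet_mm < 0)) {
    stop("chain WET entries must be >= 0", call. = FALSE)
  }
  structure(list(chain = chain, chamber = chamber,
                 raw_position_offset = raw_position_offset),
            class = "beam_setup")
}

#' @export
print.beam_setup <- function(x, ...) {
  cat("<beam_setup>\n")
  for (i in seq_len(nrow(x$chain))) {
    cat(sprintf("  %-40s %8.3f mm WET\n", x$chain$label[i], x$chain$wet_mm[i]))
  }
  cat(sprintf("  %-40s %8.3f mm WET\n", "total", setup_wet(x)))
  invisible(x)
}

#' Total WET of a beam setup chain
#' @param setup A [beam_setup()].
#' @return Summed water-equivalent thickness in mm.
#' @export
setup_wet <- function(setup) sum(setup$chain$wet_mm)

#' Water-equivalent peak depth of a measured curve
#'
#' Raw peak position from [find_peak_depth()] plus the summed WET of the
#' setup chain (empty chain: the raw position).
#'
#' @param curve A [depth_curve()].
#' @param setup A [beam_setup()]; its chain may be empty.
#' @param window_mm Passed to [find_peak_depth()].
#' @return Water-equivalent peak depth in mm.
#' @export
corrected_peak_depth <- function(curve, setup, window_mm = 2) {
  wet <- if (nrow(setup$chain) == 0L) 0 else setup_wet(setup)
  find_peak_depth(curve, window_mm) + wet + setup$raw_position_offset
}

#' Effective-point shift between two corrected peak depths
#'
#' The cylindrical chamber's curve, plotted at the cavity centre, reaches
#' its corrected Bragg peak deeper than the plane-parallel reference; the
#' difference is the upstream displacement of the effective point of
#' measurement.
#'
#' @param reference_depth Corrected peak depth of the plane-parallel
#'   reference, mm.
#' @param test_depth Corrected peak depth of the cylindrical chamber, mm.
#' @param r Cavity inner radius in mm (> 0).
#' @return List with `shift_mm` (test - reference) and `ratio` (shift / r).
#'   Positive ratios mean the effective point lies upstream of the centre;
#'   serialization prefixes a minus sign.
#' @examples
#' peff_shift(195.782, 198.06, 3.05) # 2.278 mm, ratio 0.7469
#' @export
peff_shift <- function(reference_depth, test_depth, r) {
  stopifnot(is.numeric(r), r > 0)
  shift <- test_depth - reference_depth
  list(shift_mm = shift, ratio = shift / r)
}

#' Aggregate shift ratios over replicate curve pairs
#'
#' For each (energy, field size) cell, the mean shift ratio over replicate
#' pairs and the sample standard deviation as its uncertainty (marked
#' `NA` when only one replicate exists).
#'
#' @param pairs Data frame with columns `energy`, `field_size`,
#'   `reference_depth`, `test_depth` (one row per replicate pair); or
#'   columns `energy`, `field_size`, `ratio` with precomputed ratios.
#' @param r Cavity inner radius in mm.
#' @return Data frame with columns energy, field_size, n, ratio,
#'   uncertainty, sorted by field size then energy. Zero-row input gives a
#'   zero-row table.
#' @export
shift_ratio_table <- function(pairs, r = 3.05) {
  pairs <- as.data.frame(pairs)
  cols <- c("energy", "field_size")
  out_cols <- c(cols, "n", "ratio", "uncertainty")
  if (nrow(pairs) == 0L) {
    return(stats::setNames(
      as.data.frame(matrix(numeric(0), ncol = 5)), out_cols))
  }
  if (!"ratio" %in% names(pairs)) {
    pairs$ratio <- vapply(seq_len(nrow(pairs)), function(i) {
      peff_shift(pairs$reference_depth[i], pairs$test_depth[i], r)$ratio
    }, numeric(1))
  }
  agg <- do.call(rbind, lapply(split(pairs, pairs[cols], drop = TRUE),
    function(d) {
      data.frame(energy = d$energy[1], field_size = d$field_size[1],
                 n = nrow(d), ratio = mean(d$ratio),
                 uncertainty = if (nrow(d) > 1L) stats::sd(d$ratio) else NA_real_)
    }))
  agg <- agg[order(agg$field_size, agg$energy), ]
  rownames(agg) <- NULL
  agg
}

#' Format a shift-ratio table in the published layout
#'
#' Serializes a [shift_ratio_table()] as `-(ratio +/- sd) r` cells, one row
#' per field size and one column per energy; the minus sign expresses the
#' upstream direction of ratios stored as positive magnitudes.
#'
#' @param tab Output of [shift_ratio_table()].
#' @param digits Decimals for the ratio (default 3).
#' @return Character matrix (field size x energy).
#' @export
format_shift_table <- function(tab, digits = 3) {
  Es <- sort(unique(tab$energy)); Fs <- sort(unique(tab$field_size))
  out <- matrix("", nrow = length(Fs), ncol = length(Es),
                dimnames = list(paste0(Fs, "x", Fs, " cm^2"),
                                paste0(Es, " MeV/u")))
  for (i in seq_len(nrow(tab))) {
    cell <- if (is.na(tab$uncertainty[i])) {
      sprintf("-%.*fr (n=1)", digits, tab$ratio[i])
    } else {
      sprintf("-(%.*f +/- %.*f)r", digits, tab$ratio[i], 2, tab$uncertainty[i])
    }
    out[match(tab$field_size[i], Fs), match(tab$energy[i], Es)] <- cell
  }
  out
}

#' Resample a curve on a new depth grid
#'
#' Monotone piecewise-cubic interpolation (Fritsch-Carlson) for overlay
#' plotting and alignment displays; never used for peak finding.
#'
#' @param curve A [depth_curve()].
#' @param depth_out New depth grid in mm (within the sampled range).
#' @return A [depth_curve()] on the new grid.
#' @export
resample_curve <- function(curve, depth_out) {
  if (min(depth_out) < min(curve$depth_mm) ||
      max(depth_out) > max(curve$depth_mm)) {
    stop("resampling grid extends beyond the sampled range", call. = FALSE)
  }
  f <- stats::splinefun(curve$depth_mm, curve$reading, method = "monoH.FC")
  depth_curve(depth_out, pmax(f(depth_out), 0), metadata = curve_meta(curve))
}

#' Overlay plot of depth-ionization curves
#'
#' @param curves Named list of [depth_curve()] objects.
#' @param normalize Peak-normalize each curve first (default TRUE).
#' @return A ggplot object.
#' @export
plot_curves <- function(curves, normalize = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_curves needs the ggplot2 package", call. = FALSE)
  }
  if (is.null(names(curves))) names(curves) <- paste("curve", seq_along(curves))
  dat <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- if (normalize) normalize_to_peak(curves[[nm]]) else curves[[nm]]
    data.frame(curve = nm, depth_mm = cv$depth_mm, reading = cv$reading)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$depth_mm, y = .data$reading,
                                    colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (mm, water-equivalent)",
                  y = if (normalize) "relative ionization" else "reading",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
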