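#' Construct an AFM force curve
#'
#' The unit of analysis: a time series of piezo height and cantilever force
#' with acquisition metadata. Coordinate convention: `z` increases as the
#' probe advances into the sample and force is positive in compression, so
#' the tip-sample separation `z - F/k` also increases into the sample and
#' indentation is positive beyond the contact point.
#'
#' @param t Time samples \[s\], strictly increasing.
#' @param z Piezo height samples \[m\] (increasing into the sample).
#' @param F Force samples \[N\].
#' @param segment Per-sample labels, `"approach"` or `"retract"`. Defaults
#'   to all-approach.
#' @param meta Named list of acquisition metadata. Recognised fields:
#'   `k` spring constant \[N/m\] (required for separation correction),
#'   `v` nominal approach velocity \[m/s\], `geom` a [probe_geometry()],
#'   `setpoint` force setpoint \[N\], `curve_id`, `group`, `cell` character
#'   identifiers, and `ground_truth` (generator provenance).
#' @return An object of class `"force_curve"`.
#' @export
force_curve <- function(t, z, F, segment = NULL, meta = list()) {
  n <- length(t)
  stopifnot(is.numeric(t), is.numeric(z), is.numeric(F),
            length(z) == n, length(F) == n, n >= 16L)
  if (any(diff(t) <= 0))
    stop("time samples must be strictly increasing", call. = FALSE)
  if (is.null(segment)) segment <- rep("approach", n)
  segment <- as.character(segment)
  stopifnot(length(segment) == n, all(segment %in% c("approach", "retract")))
  stopifnot(is.list(meta))
  if (!is.null(meta$k)) stopifnot(is.numeric(meta$k), meta$k > 0)
  structure(list(t = t, z = z, F = F, segment = segment, meta = meta),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("force_curve: %d samples (%d approach, %d retract), F range [%.3g, %.3g] nN\n",
              n, sum(x$segment == "approach"), sum(x$segment == "retract"),
              min(x$F) * 1e9, max(x$F) * 1e9))
  if (!is.null(x$meta$k))
    cat(sprintf("  k = %.3g N/m", x$meta$k))
  if (!is.null(x$meta$v))
    cat(sprintf(", v = %.3g um/s", x$meta$v * 1e6))
  if (!is.null(x$meta$curve_id))
    cat(sprintf(", id = %s", x$meta$curve_id))
  cat("\n")
  invisible(x)
}

#' @export
length.force_curve <- function(x) length(x$t)

.subset_curve <- function(curve, idx) {
  force_curve(curve$t[idx], curve$z[idx], curve$F[idx],
              segment = curve$segment[idx], meta = curve$meta)
}

.meta_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a force curve to delimited text plus a JSON metadata sidecar
#'
#' The curve file is a TSV with unit-suffixed header columns `time_s`,
#' `height_m`, `force_N`, `segment`; acquisition metadata (spring constant,
#' velocity, geometry, identifiers, generator ground truth if any) goes to
#' a JSON sidecar with the same basename. [read_force_curve()] reads the
#' pair back.
#'
#' @param curve A [force_curve()].
#' @param path Output path for the TSV (`.tsv` recommended); the sidecar is
#'   written next to it as `<basename>.json`.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  df <- data.frame(time_s = curve$t, height_m = curve$z,
                   force_N = curve$F, segment = curve$segment)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- curve$meta
  if (!is.null(meta$geom)) meta$geom <- unclass(meta$geom)
  jsonlite::write_json(meta, .meta_sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a force curve written by [write_force_curve()]
#'
#' Rejects files without the unit-suffixed columns (`time_s`, `height_m`,
#' `force_N`) or without a metadata sidecar carrying the spring constant:
#' unit-less inputs are a silent source of magnitude errors in this domain.
#'
#' @param path Path to the TSV curve file.
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path) {
  if (!file.exists(path)) stop("no such curve file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("time_s", "height_m", "force_N")
  if (!all(need %in% names(df)))
    stop("curve file must have unit-suffixed columns time_s, height_m, force_N: ",
         path, call. = FALSE)
  side <- .meta_sidecar_path(path)
  if (!file.exists(side))
    stop("missing metadata sidecar (spring constant etc.): ", side,
         call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$k))
    stop("metadata sidecar must carry the spring constant k [N/m]: ", side,
         call. = FALSE)
  if (!is.null(meta$geom) && !inherits(meta$geom, "probe_geometry")) {
    g <- meta$geom
    meta$geom <- probe_geometry(R = g$R, Rcell = g$Rcell, h = g$h)
  }
  seg <- if ("segment" %in% names(df)) df$segment else NULL
  force_curve(df$time_s, df$height_m, df$force_N, segment = seg, meta = meta)
}
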