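#' ABC/2 haematoma volume
#'
#' Estimates the volume of a roughly ellipsoidal haematoma from its three
#' largest perpendicular diameters as \eqn{A \cdot B \cdot C / 2}. The factor
#' 1/2 approximates the exact ellipsoid factor \eqn{\pi/6 \approx 0.5236};
#' the ABC/2 estimate is therefore \eqn{3/\pi \approx 95.5\%} of the exact
#' ellipsoid volume for the same axes.
#'
#' @param a,b,c diameters in mm: `a` the largest diameter, `b` the largest
#'   diameter perpendicular to `a`, `c` the extent perpendicular to the
#'   a--b plane. All must be >= 0. Vectorised.
#' @return Volume in cm^3 (mm^3 / 1000). Zero iff any axis is zero.
#' @export
#' @examples
#' abc2_volume(40, 30, 50)  # 30 cm^3
abc2_volume <- function(a, b, c) {
  .check_number(c(a, b, c), "diameters")
  if (any(c(a, b, c) < 0)) .stopf("ABC/2 diameters must be non-negative")
  a * b * c / 2 / 1000
}

#' Average slice thickness from four calliper readings
#'
#' Formalin fixation shrinks brain slices, so the nominal cutting thickness
#' is unreliable; the working thickness of each coronal slice is the
#' arithmetic mean of four measurements taken at different locations.
#'
#' @param readings numeric vector of exactly four positive thicknesses (mm).
#' @return Mean thickness in mm.
#' @export
slice_thickness <- function(readings) {
  if (length(readings) != 4)
    .stopf("exactly four thickness readings are required, got %d", length(readings))
  .check_number(readings, "readings", positive = TRUE)
  mean(readings)
}

#' Construct a cadaver slice stack
#'
#' An ordered set of post-mortem coronal slice measurements for one brain.
#' Each slice carries four thickness readings, the maximal horizontal and
#' perpendicular haematoma diameters on that slice, and whether the
#' haematoma fully penetrates the slice. For end slices that the haematoma
#' only partially penetrates, the depth of blood is measured with a probe
#' instead of the slice thickness.
#'
#' @param slices data.frame with columns `t1_mm`, `t2_mm`, `t3_mm`, `t4_mm`
#'   (thickness readings, mm), `diam_h_mm`, `diam_p_mm` (maximal haematoma
#'   diameters, mm), `fully_penetrated` (logical/0-1).
#' @param probe_depth_first,probe_depth_last probe depth (mm) for the first /
#'   last slice; must be present exactly when that end slice is not fully
#'   penetrated.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, probe_depth_first = NULL,
                        probe_depth_last = NULL) {
  need <- c("t1_mm", "t2_mm", "t3_mm", "t4_mm", "diam_h_mm", "diam_p_mm",
            "fully_penetrated")
  miss <- setdiff(need, names(slices))
  if (length(miss)) .stopf("slice table is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(slices) < 1) .stopf("a slice stack must contain at least one slice")
  th <- as.matrix(slices[, c("t1_mm", "t2_mm", "t3_mm", "t4_mm")])
  if (anyNA(th) || any(th <= 0)) .stopf("all thickness readings must be positive")
  if (any(slices$diam_h_mm < 0) || any(slices$diam_p_mm < 0))
    .stopf("diameters must be non-negative")
  slices$fully_penetrated <- as.logical(slices$fully_penetrated)
  n <- nrow(slices)
  fp <- slices$fully_penetrated
  .chk_end <- function(full, depth, which) {
    if (!full && is.null(depth))
      .stopf("%s slice is not fully penetrated but has no probe depth", which)
    if (full && !is.null(depth))
      .stopf("%s slice is fully penetrated yet a probe depth was supplied", which)
    if (!is.null(depth)) .check_number(depth, paste0("probe_depth_", which))
    if (!is.null(depth) && depth < 0) .stopf("probe depths must be >= 0")
  }
  .chk_end(fp[1], probe_depth_first, "first")
  if (n > 1) .chk_end(fp[n], probe_depth_last, "last")
  else if (!is.null(probe_depth_last)) .stopf("single-slice stack cannot take a last probe depth")
  if (n > 2 && !all(fp[2:(n - 1)]))
    .stopf("interior slices must be fully penetrated by the haematoma")
  structure(list(slices = slices,
                 probe_depth_first = probe_depth_first,
                 probe_depth_last = probe_depth_last),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("Cadaver slice stack: %d slices", nrow(x$slices)))
  if (!is.null(x$probe_depth_first))
    cat(sprintf(", first probe depth %.1f mm", x$probe_depth_first))
  if (!is.null(x$probe_depth_last))
    cat(sprintf(", last probe depth %.1f mm", x$probe_depth_last))
  cat("\n")
  invisible(x)
}

#' C axis from a cadaver slice stack
#'
#' The haematoma extent perpendicular to the slicing plane: the sum of the
#' averaged measured thicknesses of all fully penetrated slices, plus the
#' probe depths of partially penetrated end slices. Measuring actual (post-
#' fixation) thickness rather than the nominal cutting thickness makes the
#' sum robust to fixation shrinkage.
#'
#' @param stack a [slice_stack()] object.
#' @return The summed C diameter in mm.
#' @export
cadaver_c_axis <- function(stack) {
  stopifnot(inherits(stack, "slice_stack"))
  s <- stack$slices
  thick <- rowMeans(s[, c("t1_mm", "t2_mm", "t3_mm", "t4_mm")])
  total <- sum(thick[s$fully_penetrated])
  for (end in list(c(1, "probe_depth_first"), c(nrow(s), "probe_depth_last"))) {
    i <- as.integer(end[1]); d <- stack[[end[2]]]
    if (!is.null(d)) {
      if (d > thick[i] + 1e-9)
        .stopf("probe depth (%.2f mm) exceeds the averaged slice thickness (%.2f mm)",
               d, thick[i])
      total <- total + d
    }
  }
  total
}

#' Cadaver ABC/2 volume from a slice stack
#'
#' ABC/2 volumetry on post-mortem coronal slices: A is the largest
#' horizontal haematoma diameter over all slices, B the largest perpendicular
#' diameter (not necessarily on the same slice), and C the summed extent from
#' [cadaver_c_axis()]. Because parenchymal and intraventricular blood are not
#' reliably distinguishable in fixed, sliced brains, the estimate is the
#' combined (total) haematoma volume.
#'
#' @param stack a [slice_stack()] object.
#' @return Total haematoma volume in cm^3.
#' @export
cadaver_abc2 <- function(stack) {
  stopifnot(inherits(stack, "slice_stack"))
  a <- max(stack$slices$diam_h_mm)
  b <- max(stack$slices$diam_p_mm)
  abc2_volume(a, b, cadaver_c_axis(stack))
}

#' Relative haematoma volume
#'
#' The ratio of a haematoma volume to the intracranial volume, a unitless
#' size measure that adjusts for head size.
#'
#' @param haematoma haematoma volume, cm^3 (0 <= haematoma <= icv).
#' @param icv intracranial volume, cm^3 (> 0). Vectorised.
#' @return Ratio in \[0, 1).
#' @export
#' @examples
#' relative_volume(57.8, 1344.2)
relative_volume <- function(haematoma, icv) {
  .check_number(haematoma, "haematoma")
  .check_number(icv, "icv", positive = TRUE)
  if (any(haematoma < 0)) .stopf("haematoma volume must be >= 0")
  if (any(haematoma > icv)) .stopf("haematoma volume cannot exceed the intracranial volume")
  haematoma / icv
}

#' Absolute and relative haematoma volumes for one examination
#'
#' Bundles the intracranial volume with the total, intraparenchymal and
#' intraventricular haematoma volumes and computes the corresponding
#' relative volumes. When both compartment volumes are given they must sum
#' to the total (within 1e-6 cm^3).
#'
#' @param icv intracranial volume, cm^3.
#' @param total total haematoma volume, cm^3.
#' @param parenchymal,ivh optional compartment volumes, cm^3 (`NA` = not
#'   measured; at autopsy the compartments are often indistinguishable).
#' @return An object of class `volume_set` with absolute volumes and
#'   `rel_total`, `rel_parenchymal`, `rel_ivh`.
#' @export
volume_set <- function(icv, total, parenchymal = NA_real_, ivh = NA_real_) {
  .check_number(icv, "icv", positive = TRUE)
  rel_total <- relative_volume(total, icv)
  if (!is.na(parenchymal) && !is.na(ivh) && abs(parenchymal + ivh - total) > 1e-6)
    .stopf("parenchymal (%g) + intraventricular (%g) volumes must equal the total (%g)",
           parenchymal, ivh, total)
  rel_par <- if (is.na(parenchymal)) NA_real_ else relative_volume(parenchymal, icv)
  rel_ivh <- if (is.na(ivh)) NA_real_ else relative_volume(ivh, icv)
  structure(list(icv = icv, total = total, parenchymal = parenchymal,
                 ivh = ivh, rel_total = rel_total, rel_parenchymal = rel_par,
                 rel_ivh = rel_ivh),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  cat(sprintf("ICV %.1f cm^3; haematoma total %.1f cm^3 (relative %.4f)\n",
              x$icv, x$total, x$rel_total))
  if (!is.na(x$parenchymal))
    cat(sprintf("  parenchymal %.1f cm^3 (relative %.4f)\n", x$parenchymal, x$rel_parenchymal))
  if (!is.na(x$ivh))
    cat(sprintf("  intraventricular %.1f cm^3 (relative %.4f)\n", x$ivh, x$rel_ivh))
  invisible(x)
}

#' Read / write a slice-stack CSV
#'
#' Plain-text interchange for cadaver slice measurements. Columns:
#' `slice_index`, `t1_mm` .. `t4_mm`, `diam_h_mm`, `diam_p_mm`,
#' `fully_penetrated` (0/1), `probe_depth_mm` (empty except on partially
#' penetrated end slices).
#'
#' @param path file path.
#' @return `read_slice_stack` returns a [slice_stack()];
#'   `write_slice_stack` returns `path` invisibly.
#' @export
read_slice_stack <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- d[order(d$slice_index), , drop = FALSE]
  pd <- if ("probe_depth_mm" %in% names(d)) d$probe_depth_mm else rep(NA_real_, nrow(d))
  first <- if (!is.na(pd[1])) pd[1] else NULL
  last <- if (nrow(d) > 1 && !is.na(pd[nrow(d)])) pd[nrow(d)] else NULL
  slice_stack(d, probe_depth_first = first, probe_depth_last = last)
}

#' @rdname read_slice_stack
#' @param stack a [slice_stack()] object.
#' @export
write_slice_stack <- function(stack, path) {
  stopifnot(inherits(stack, "slice_stack"))
  d <- stack$slices
  d$slice_index <- seq_len(nrow(d))
  d$probe_depth_mm <- NA_real_
  if (!is.null(stack$probe_depth_first)) d$probe_depth_mm[1] <- stack$probe_depth_first
  if (!is.null(stack$probe_depth_last)) d$probe_depth_mm[nrow(d)] <- stack$probe_depth_last
  cols <- c("slice_index", "t1_mm", "t2_mm", "t3_mm", "t4_mm",
            "diam_h_mm", "diam_p_mm", "fully_penetrated", "probe_depth_mm")
  d$fully_penetrated <- as.integer(d$fully_penetrated)
  utils::write.csv(d[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}
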