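# Subcutaneous fat by convex hull, intensity threshold, residual pixel
# assignment and label-map assembly.

#' Derive the subcutaneous fat mask
#'
#' SCF is the thigh circumference minus the convex hull of the fascial
#' (muscle hull) mask — concavities of the fascia are part of the hull and
#' therefore excluded from SCF. Fascia pixels outside the thigh are clipped
#' with a warning; an empty fascia returns the whole thigh.
#'
#' @param thigh,fascia 0/1 matrices on the same grid.
#' @return 0/1 SCF mask.
#' @export
derive_scf <- function(thigh, fascia) {
  stopifnot(all(dim(thigh) == dim(fascia)))
  outside <- sum(fascia == 1 & thigh == 0)
  if (outside > 0) {
    warning(outside, " fascia pixel(s) outside the thigh clipped", call. = FALSE)
    fascia <- ((fascia == 1) & (thigh == 1)) + 0L
  }
  if (sum(fascia) == 0) {
    warning("empty fascia mask; SCF set to the whole thigh", call. = FALSE)
    return((thigh != 0) + 0L)
  }
  hull <- convex_hull_mask(fascia)
  ((thigh == 1) & (hull == 0)) + 0L
}

#' Compute the fat/muscle intensity threshold
#'
#' The threshold is the midpoint of the mean SCF signal intensity and the
#' mean quadriceps+hamstrings signal intensity, evaluated on the
#' range-normalized image: `t = (mean_si_scf + mean_si_qh) / 2`. This
#' realizes the printed form with denominator
#' `2 (pixel_highest - pixel_lowest)` — dividing the class-mean sum of the
#' raw image by the range is the same as averaging class means of the
#' `[0, 1]`-normalized image — and makes the rule invariant to affine
#' intensity rescaling.
#'
#' @param img_norm [grayscale_image] or matrix with values in `[0, 1]`.
#' @param scf,quad,ham Non-empty 0/1 masks.
#' @param extrema Length-2 `(pixel_lowest, pixel_highest)` of the image
#'   before normalization (recorded in the context).
#' @return Object of class `threshold_context`: `mean_si_scf`, `mean_si_qh`,
#'   `pixel_lowest`, `pixel_highest`, `t`.
#' @export
compute_threshold <- function(img_norm, scf, quad, ham, extrema = c(0, 1)) {
  px <- as_image_matrix(img_norm)
  if (sum(scf) == 0 || (sum(quad) + sum(ham)) == 0)
    stop_thighseg("threshold masks must be non-empty")
  if (extrema[1] >= extrema[2]) stop_thighseg("degenerate intensity extrema")
  m_scf <- mean(px[scf == 1])
  m_qh <- mean(px[quad == 1 | ham == 1])
  structure(list(mean_si_scf = m_scf, mean_si_qh = m_qh,
                 pixel_lowest = extrema[1], pixel_highest = extrema[2],
                 t = (m_scf + m_qh) / 2),
            class = "threshold_context")
}

#' Assign residual intra-fascial pixels
#'
#' The residual region is the fascia minus the assigned components
#' (quadriceps, hamstrings, sartorius, gracilis, femur fill). Each residual
#' pixel is classified fat-like vs muscle-like; muscle-like pixels are
#' grouped by 8-connectivity, groups of more than `min_adductor_px` pixels
#' become adductors, smaller groups become other intermuscular tissue (veins
#' etc.), and fat-like pixels become IMF. The gracilis mask is merged into
#' the adductors output.
#'
#' By default a pixel is assigned to the nearer class mean (muscle-like iff
#' `|I - mean_si_qh| <= |I - mean_si_scf|`), which equals the midpoint
#' threshold with the polarity that matches T1 contrast (fat bright). With
#' `literal_threshold = TRUE` the printed inequality is applied verbatim:
#' `I < t` to IMF, `I >= t` to the muscle-like pool.
#'
#' @param img_norm Normalized image.
#' @param assigned Named list of 0/1 masks with entries `quadriceps`,
#'   `hamstrings`, `sartorius`, `gracilis`, `femur`.
#' @param fascia 0/1 mask.
#' @param ctx A [compute_threshold()] context.
#' @param min_adductor_px Connected-size cut (strictly greater passes),
#'   default 70.
#' @param literal_threshold Apply the printed inequality verbatim.
#' @return List of 0/1 masks `imf`, `adductors`, `other`.
#' @export
assign_residual_pixels <- function(img_norm, assigned, fascia, ctx,
                                   min_adductor_px = 70,
                                   literal_threshold = FALSE) {
  px <- as_image_matrix(img_norm)
  used <- matrix(0L, nrow(px), ncol(px))
  for (nm in c("quadriceps", "hamstrings", "sartorius", "gracilis", "femur"))
    if (!is.null(assigned[[nm]])) used <- used | (assigned[[nm]] == 1)
  residual <- (fascia == 1) & !used
  imf <- matrix(0L, nrow(px), ncol(px))
  add <- matrix(0L, nrow(px), ncol(px))
  oth <- matrix(0L, nrow(px), ncol(px))
  if (any(residual)) {
    vals <- px[residual]
    muscle_like <- if (literal_threshold) vals >= ctx$t
                   else abs(vals - ctx$mean_si_qh) <= abs(vals - ctx$mean_si_scf)
    imf[residual] <- as.integer(!muscle_like)
    mus <- matrix(0L, nrow(px), ncol(px))
    mus[residual] <- as.integer(muscle_like)
    if (sum(mus) > 0) {
      lab <- label_components(mus)
      sizes <- tabulate(lab[lab > 0L])
      big <- which(sizes > min_adductor_px)
      add[lab %in% big & lab > 0L] <- 1L
      oth[lab > 0L & !(lab %in% big)] <- 1L
    }
  }
  if (!is.null(assigned$gracilis)) add[assigned$gracilis == 1] <- 1L
  list(imf = imf, adductors = add, other = oth)
}

#' Assemble the final label map and area table
#'
#' Paints all masks into one label map using the fixed code table
#' ([LABEL_CODES]) with precedence on overlap: femur cortex > medulla >
#' named muscles > adductors > other > IMF > SCF > background. Conflicting
#' assignments are counted and reported as an attribute. Areas are tabulated
#' in pixels and cm^2 (`px * row_mm * col_mm / 100`).
#'
#' @param masks Named list with `scf`, `quadriceps`, `hamstrings`,
#'   `sartorius`, `femur_cortex`, `medulla` 0/1 masks.
#' @param imf,adductors,other 0/1 masks from [assign_residual_pixels()].
#' @param spacing `(row_mm, col_mm)`.
#' @param settings,provenance Optional records stored in the result.
#' @return Object of class `segmentation_result`: `label_map` (integer
#'   matrix), `areas` (data.frame structure/code/px/cm2), `conflicts`
#'   (overlap count), `settings`, `provenance`.
#' @export
assemble_labelmap <- function(masks, imf, adductors, other, spacing = c(1, 1),
                              settings = list(), provenance = list()) {
  grid <- dim(imf)
  lab <- matrix(0L, grid[1], grid[2])
  painted <- matrix(0L, grid[1], grid[2])
  layers <- list(
    scf = masks$scf, imf = imf, other = other, adductors = adductors,
    sartorius = masks$sartorius, hamstrings = masks$hamstrings,
    quadriceps = masks$quadriceps, medulla = masks$medulla,
    femur_cortex = masks$femur_cortex
  )
  conflicts <- 0L
  for (nm in names(layers)) {  # increasing precedence; later paints win
    m <- layers[[nm]]
    if (is.null(m)) next
    sel <- m == 1
    conflicts <- conflicts + sum(sel & painted == 1L)
    lab[sel] <- LABEL_CODES[[nm]]
    painted[sel] <- 1L
  }
  counts <- vapply(LABEL_CODES, function(code) sum(lab == code), numeric(1))
  areas <- data.frame(
    structure = names(LABEL_CODES),
    code = unname(LABEL_CODES),
    px = unname(counts),
    cm2 = unname(counts) * spacing[1] * spacing[2] / 100,
    stringsAsFactors = FALSE
  )
  structure(list(label_map = lab, areas = areas, conflicts = conflicts,
                 spacing = spacing, settings = settings,
                 provenance = provenance),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>\n")
  print(x$areas[x$areas$px > 0, ], row.names = FALSE)
  invisible(x)
}

#' Per-structure areas of a label map
#'
#' @param label_map Integer matrix of [LABEL_CODES].
#' @param spacing `(row_mm, col_mm)`.
#' @return data.frame structure/code/px/cm2.
#' @export
labelmap_areas <- function(label_map, spacing = c(1, 1)) {
  counts <- vapply(LABEL_CODES, function(code) sum(label_map == code), numeric(1))
  data.frame(structure = names(LABEL_CODES), code = unname(LABEL_CODES),
             px = unname(counts),
             cm2 = unname(counts) * spacing[1] * spacing[2] / 100,
             stringsAsFactors = FALSE)
}
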