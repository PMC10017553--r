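#' Focal-length factor for the idealized fish eye
#'
#' The idealized focal length of the larval/adult zebrafish eye is the lens
#' radius times 2.324 (Matthiessen-type ratio used in OCT biometry work).
#' @export
focal_length_factor <- 2.324

#' Lens circularity ratio
#'
#' Ratio of the proximal-distal to the anterior-posterior lens diameter; a
#' perfectly spherical lens gives 1.
#'
#' @param pd_um,ap_um lens diameters in micrometres (> 0); vectorized.
#' @return dimensionless ratio.
#' @export
lens_ratio <- function(pd_um, ap_um) {
  if (any(pd_um <= 0) || any(ap_um <= 0)) {
    stop("lens diameters must be > 0", call. = FALSE)
  }
  pd_um / ap_um
}

#' Axial length normalized by body length
#'
#' @param axial_um eye axial length (top of lens to RPE), micrometres.
#' @param body_mm body length, millimetres.
#' @return micrometres per millimetre.
#' @export
normalized_axial_length <- function(axial_um, body_mm) {
  if (any(axial_um <= 0) || any(body_mm <= 0)) {
    stop("lengths must be > 0", call. = FALSE)
  }
  axial_um / body_mm
}

#' Relative refractive error (RRE)
#'
#' `rre = 1 - retinal_radius / F` with the idealized focal length
#' `F = 2.324 * lens_radius`. Negative values indicate a myopic eye (the
#' lens-to-RPE distance exceeds the expected retinal radius), positive
#' values a hyperopic eye; an increase marks a hyperopic shift.
#'
#' @param lens_radius_um lens radius, micrometres (> 0); vectorized.
#' @param retinal_radius_um centre of lens to RPE, micrometres (> 0).
#' @param focal_factor focal-length factor (default [focal_length_factor]).
#' @return dimensionless RRE (< 1 always).
#' @export
rre <- function(lens_radius_um, retinal_radius_um,
                focal_factor = focal_length_factor) {
  if (any(lens_radius_um <= 0) || any(retinal_radius_um <= 0)) {
    stop("radii must be > 0", call. = FALSE)
  }
  1 - retinal_radius_um / (focal_factor * lens_radius_um)
}

#' Derive per-fish ocular metrics from a biometry table
#'
#' Adds lens ratio, normalized axial length, idealized focal length, and RRE
#' per fish. Warns when the recorded lens radius disagrees with the mean
#' lens diameter / 2 by more than 10% (consistency check only). Cohort
#' statistics should be taken over these per-fish values; the ratio-of-means
#' variant (metric on the cohort mean parameters) is available via
#' [cohort_ocular_metrics()] for worked-example checks.
#'
#' @param biometry tibble as produced by [simulate_biometry()] (fields:
#'   `fish_id`, `genotype`, `body_length_mm`, `axial_length_um`,
#'   `lens_diam_pd_um`, `lens_diam_ap_um`, `lens_radius_um`,
#'   `retinal_radius_um`, `retinal_thickness_um`).
#' @return the input with columns `lens_ratio`, `norm_axial_um_per_mm`,
#'   `idealized_focal_um`, `rre` appended.
#' @export
derive_ocular_metrics <- function(biometry) {
  b <- tibble::as_tibble(biometry)
  num <- c("body_length_mm", "axial_length_um", "lens_diam_pd_um",
           "lens_diam_ap_um", "lens_radius_um", "retinal_radius_um",
           "retinal_thickness_um")
  if (any(vapply(num, function(cn) any(b[[cn]] <= 0), logical(1)))) {
    stop("all biometry lengths must be > 0", call. = FALSE)
  }
  half_diam <- (b$lens_diam_pd_um + b$lens_diam_ap_um) / 4
  off <- abs(b$lens_radius_um - half_diam) / half_diam
  if (any(off > 0.10)) {
    warning("lens radius differs from mean(diameters)/2 by > 10% for ",
            sum(off > 0.10), " fish", call. = FALSE)
  }
  b$lens_ratio <- lens_ratio(b$lens_diam_pd_um, b$lens_diam_ap_um)
  b$norm_axial_um_per_mm <- normalized_axial_length(b$axial_length_um,
                                                    b$body_length_mm)
  b$idealized_focal_um <- focal_length_factor * b$lens_radius_um
  b$rre <- rre(b$lens_radius_um, b$retinal_radius_um)
  b
}

#' Cohort-level ocular metrics
#'
#' Two aggregations per genotype: `mean_of_fish`, the mean of the per-fish
#' metrics (the convention for cohort reporting), and `ratio_of_means`, the
#' metric evaluated on the cohort mean parameters (useful for arithmetic on
#' published cohort means; the two differ when parameters covary across
#' fish).
#'
#' @param biometry a biometry tibble (see [derive_ocular_metrics()]).
#' @return tibble with one row per genotype x metric x aggregation.
#' @export
cohort_ocular_metrics <- function(biometry) {
  d <- derive_ocular_metrics(biometry)
  do.call(rbind, lapply(split(d, d$genotype), function(g) {
    tibble::tibble(
      genotype = g$genotype[1],
      metric = rep(c("lens_ratio", "norm_axial_um_per_mm", "rre"), 2),
      aggregation = rep(c("mean_of_fish", "ratio_of_means"), each = 3),
      value = c(mean(g$lens_ratio), mean(g$norm_axial_um_per_mm),
                mean(g$rre),
                lens_ratio(mean(g$lens_diam_pd_um), mean(g$lens_diam_ap_um)),
                normalized_axial_length(mean(g$axial_length_um),
                                        mean(g$body_length_mm)),
                rre(mean(g$lens_radius_um), mean(g$retinal_radius_um)))
    )
  }))
}

#' Average triplicate morphometric measurements
#'
#' Each trait is measured three times per fish; the replicates are averaged
#' before any reporting. Warns when a fish's replicate coefficient of
#' variation exceeds 50%.
#'
#' @param morphometry tibble with `fish_id`, `genotype`, and replicate
#'   columns `body_mm_1..3`, `head_mm_1..3`, `midbrain_mm_1..3` (see
#'   [simulate_morphometry()]).
#' @return tibble with `fish_id`, `genotype`, `body_mm`, `head_mm`,
#'   `midbrain_mm`.
#' @export
average_triplicate <- function(morphometry) {
  m <- tibble::as_tibble(morphometry)
  traits <- c("body_mm", "head_mm", "midbrain_mm")
  out <- tibble::tibble(fish_id = m$fish_id, genotype = m$genotype)
  for (tr in traits) {
    cols <- paste0(tr, "_", 1:3)
    if (!all(cols %in% names(m))) {
      stop("expected three replicates per trait (columns ",
           paste(cols, collapse = ", "), ")", call. = FALSE)
    }
    reps <- as.matrix(m[, cols])
    if (any(reps <= 0)) stop("replicates must be > 0", call. = FALSE)
    cv <- apply(reps, 1, stats::sd) / rowMeans(reps)
    if (any(cv > 0.5)) {
      warning(sum(cv > 0.5), " fish exceed 50% replicate CV for ", tr,
              call. = FALSE)
    }
    out[[tr]] <- rowMeans(reps)
  }
  out
}

#' Morphometric ratios
#'
#' `head_to_body = head / body`. The conventional "head-to-midbrain ratio"
#' is computed as `midbrain / head`: that orientation is what the reported
#' cohort values follow (e.g. trait means of 0.52 mm midbrain and 0.70 mm
#' head give 0.74), despite the name suggesting the inverse.
#'
#' @param body_mm,head_mm,midbrain_mm trait values in mm (> 0); vectorized.
#' @return tibble with `head_to_body` and `head_to_midbrain`.
#' @export
morpho_ratios <- function(body_mm, head_mm, midbrain_mm) {
  if (any(body_mm <= 0) || any(head_mm <= 0) || any(midbrain_mm <= 0)) {
    stop("trait values must be > 0", call. = FALSE)
  }
  tibble::tibble(
    head_to_body = head_mm / body_mm,
    head_to_midbrain = midbrain_mm / head_mm
  )
}
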