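#' Synthetic binary patch with planted micro-holes
#'
#' Rasterises black disks (pixel p is black iff `||p - c|| <= r`, pixel
#' centres on the integer lattice) on a white canvas, with rejection-sampled
#' centres enforcing a minimum boundary-to-boundary gap between holes. The
#' planted ground truth (centres, radii, pairwise gaps) is returned with the
#' mask, so the pipeline's recovered statistics can be checked against it:
#' the maximal inscribed radius of each rasterised disk equals its planted
#' radius to within one pixel, and the half-gap predicts the H0-quadrant-2
#' death of well-separated holes.
#'
#' @param n_holes Number of disks (0 gives a degenerate all-white patch).
#' @param radius_mean,radius_sd Normal radius distribution (pixels), truncated
#'   below at 1.
#' @param min_gap Minimum boundary gap between holes (pixels).
#' @param side Canvas edge length (default 300).
#' @param seed Optional integer seed.
#' @param border Width of a black exterior frame (default 0); a positive
#'   border emulates real patches where the essential class is the exterior
#'   background region.
#' @param annuli Logical vector (recycled) marking holes to draw as annuli
#'   (black ring of the planted radius around a white core of half that
#'   radius), which plant H1-quadrant-2 micro-hole loops.
#' @param max_tries Placement attempts per hole before giving up.
#' @return List with `mask` (logical, `TRUE` = white), and `truth`
#'   (data frame: `center_row`, `center_col`, `radius`, `annulus`,
#'   `min_gap_to_next` = boundary gap to the nearest other hole).
#' @export
make_disk_field <- function(n_holes, radius_mean = 3, radius_sd = 0.8,
                            min_gap = 12, side = 300L, seed = NULL,
                            border = 0L, annuli = FALSE, max_tries = 2000L) {
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(TRUE, side, side)
  if (border > 0L) {
    mask[c(seq_len(border), side - seq_len(border) + 1L), ] <- FALSE
    mask[, c(seq_len(border), side - seq_len(border) + 1L)] <- FALSE
  }
  if (n_holes == 0L) {
    truth <- data.frame(center_row = numeric(0), center_col = numeric(0),
                        radius = numeric(0), annulus = logical(0),
                        min_gap_to_next = numeric(0))
    attr(mask, "degenerate") <- border == 0L
    return(list(mask = mask, truth = truth))
  }
  annuli <- rep_len(annuli, n_holes)
  radii <- pmax(1, round(rnorm(n_holes, radius_mean, radius_sd)))
  centers <- matrix(NA_real_, n_holes, 2)
  for (i in seq_len(n_holes)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      margin <- radii[i] + 2 + border + min_gap / 2
      cand <- round(runif(2, margin, side - margin + 1))
      ok <- TRUE
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        gaps <- sqrt((centers[prev, 1] - cand[1])^2 +
                     (centers[prev, 2] - cand[2])^2) - radii[prev] - radii[i]
        ok <- all(gaps >= min_gap)
      }
      if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("packing infeasible: could not place hole ", i, " of ", n_holes,
           " after ", max_tries, " tries")
  }
  rows <- row(mask); cols <- col(mask)
  for (i in seq_len(n_holes)) {
    d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
    if (annuli[i]) {
      inner <- max(1, radii[i] / 2)
      mask[d2 <= radii[i]^2 & d2 > inner^2] <- FALSE
    } else {
      mask[d2 <= radii[i]^2] <- FALSE
    }
  }
  gap_to_next <- if (n_holes > 1L) {
    vapply(seq_len(n_holes), function(i) {
      others <- setdiff(seq_len(n_holes), i)
      min(sqrt((centers[others, 1] - centers[i, 1])^2 +
               (centers[others, 2] - centers[i, 2])^2) -
          radii[others] - radii[i])
    }, numeric(1))
  } else rep(NA_real_, n_holes)
  truth <- data.frame(center_row = centers[, 1], center_col = centers[, 2],
                      radius = radii, annulus = annuli,
                      min_gap_to_next = gap_to_next)
  attr(mask, "degenerate") <- FALSE
  list(mask = mask, truth = truth)
}

#' Generator presets for the two study-like groups
#'
#' `wt-like` emulates control patches: many small, crowded micro-holes.
#' `ko-like` emulates the pathological contrast — half the hole count,
#' double the mean radius, double the spacing. `null` equals `wt-like` and
#' is used for calibration.
#'
#' @param preset `"wt-like"`, `"ko-like"` or `"null"`.
#' @return Named list of [make_disk_field()] parameters.
#' @export
synth_preset <- function(preset = c("wt-like", "ko-like", "null")) {
  preset <- match.arg(preset)
  switch(preset,
    "wt-like" = ,
    "null" = list(n_holes = 40L, radius_mean = 3, radius_sd = 0.8,
                  min_gap = 12, side = 300L),
    "ko-like" = list(n_holes = 20L, radius_mean = 6, radius_sd = 1.6,
                     min_gap = 24, side = 300L))
}

#' Two-group labelled synthetic patch set
#'
#' Draws `n_per_group` patches from each of two generator parameter sets and
#' labels them KO / WT, fully reproducible from the seed.
#'
#' @param params_ko,params_wt Parameter lists as from [synth_preset()].
#' @param n_per_group Patches per group.
#' @param seed Integer seed.
#' @return List of patches, each with `mask`, `truth`, and `labels`
#'   (`genotype`, `sample` = patch index).
#' @export
make_group_dataset <- function(params_ko, params_wt, n_per_group, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_group)
  one <- function(i, params, genotype) {
    fld <- do.call(make_disk_field, c(params, list(seed = seeds[i])))
    fld$labels <- list(genotype = genotype, sample = i)
    fld
  }
  c(lapply(seq_len(n_per_group), one, params = params_ko, genotype = "KO"),
    lapply(n_per_group + seq_len(n_per_group), one, params = params_wt,
           genotype = "WT"))
}
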