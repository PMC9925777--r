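#' Persistent entropy
#'
#' Shannon entropy (natural log) of the normalised lifetimes
#' `p_i = (d_i - b_i) / P`, where `P` is the total persistence
#' `sum(d_i - b_i)`. Maximal (`log n`) when all features are equally
#' persistent; 0 for a single feature.
#'
#' @param births,deaths Numeric vectors with `deaths > births`, finite.
#' @return Entropy in nats; `NA` for empty input (undefined, not 0).
#' @export
persistent_entropy <- function(births, deaths) {
  stopifnot(length(births) == length(deaths))
  if (length(births) == 0L) return(NA_real_)
  p <- deaths - births
  if (any(p <= 0) || any(!is.finite(p)))
    stop("persistent entropy requires finite lifetimes with death > birth")
  p <- p / sum(p)
  -sum(p * log(p))
}

# Panel column names: the informative quadrants are H0 quadrant 2 (separate
# micro-holes) and H1 quadrant 1 (signal loops between micro-holes).
panel_moment_cols <- function(prefix) {
  paste0(prefix, c("n_points", "entropy",
                   "birth_mean", "birth_median", "birth_q25", "birth_q75",
                   "birth_iqr", "birth_sd",
                   "death_mean", "death_median", "death_q25", "death_q75",
                   "death_iqr", "death_sd",
                   "total_persistence"))
}

#' Names of the panel statistics
#'
#' `panel_stats()` lists every column the per-patch panel computes (32).
#' `canonical_stats()` lists the 28 statistics used for group comparison:
#' for H0 quadrant 2 the 13 moment/entropy/count statistics plus the two
#' radius-thresholded counts, and the matching 13 for H1 quadrant 1
#' (the 75th birth percentile and the total persistence are computed but are
#' not part of the canonical 28).
#'
#' @return Character vector of column names.
#' @export
panel_stats <- function() {
  c(panel_moment_cols("H0Q2_"), "H0Q2_n_radius_ge", "H0Q2_n_radius_lt",
    panel_moment_cols("H1Q1_"))
}

#' @rdname panel_stats
#' @export
canonical_stats <- function() {
  drop <- c("H0Q2_birth_q75", "H0Q2_total_persistence",
            "H1Q1_birth_q75", "H1Q1_total_persistence")
  setdiff(panel_stats(), drop)
}

quadrant_stats <- function(b, d, prefix) {
  out <- stats::setNames(rep(NA_real_, 15L), panel_moment_cols(prefix))
  out[[paste0(prefix, "n_points")]] <- length(b)
  if (length(b) == 0L) return(out)
  q <- function(x, p) unname(quantile(x, p, type = 7))  # linear interpolation
  out[[paste0(prefix, "entropy")]] <- persistent_entropy(b, d)
  out[[paste0(prefix, "birth_mean")]] <- mean(b)
  out[[paste0(prefix, "birth_median")]] <- median(b)
  out[[paste0(prefix, "birth_q25")]] <- q(b, 0.25)
  out[[paste0(prefix, "birth_q75")]] <- q(b, 0.75)
  out[[paste0(prefix, "birth_iqr")]] <- q(b, 0.75) - q(b, 0.25)
  out[[paste0(prefix, "birth_sd")]] <- if (length(b) > 1L) sd(b) else 0
  out[[paste0(prefix, "death_mean")]] <- mean(d)
  out[[paste0(prefix, "death_median")]] <- median(d)
  out[[paste0(prefix, "death_q25")]] <- q(d, 0.25)
  out[[paste0(prefix, "death_q75")]] <- q(d, 0.75)
  out[[paste0(prefix, "death_iqr")]] <- q(d, 0.75) - q(d, 0.25)
  out[[paste0(prefix, "death_sd")]] <- if (length(d) > 1L) sd(d) else 0
  out[[paste0(prefix, "total_persistence")]] <- sum(d - b)
  out
}

#' Per-patch panel of persistence statistics
#'
#' Computes the interpretable summary statistics of the H0-quadrant-2 and
#' H1-quadrant-1 points of a patch diagram: point counts, persistent entropy,
#' mean/median/quartiles/IQR/standard deviation of the raw birth and death
#' coordinates, total persistence, and (H0-Q2 only) the number of micro-holes
#' with inscribed radius (`-birth`) at least / below `radius_threshold`.
#' The essential class is excluded throughout, since it usually captures the
#' exterior background region. Statistics of an empty quadrant are `NA`
#' (missing), with `n_points = 0`.
#'
#' @param diag A `persistence_diagram` (quadrants assigned internally if
#'   absent).
#' @param radius_threshold Radius cut for the two count statistics
#'   (default 2, pixels).
#' @return One-row data frame with the [panel_stats()] columns.
#' @export
compute_panel <- function(diag, radius_threshold = 2) {
  if (!("quadrant" %in% names(diag))) diag <- split_quadrants(diag, check = FALSE)
  fin <- diag[!diag$essential, , drop = FALSE]
  h0 <- fin[fin$dim == 0 & fin$quadrant == 2L, , drop = FALSE]
  h1 <- fin[fin$dim == 1 & fin$quadrant == 1L, , drop = FALSE]
  out <- c(quadrant_stats(h0$birth, h0$death, "H0Q2_"),
           H0Q2_n_radius_ge = sum(-h0$birth >= radius_threshold),
           H0Q2_n_radius_lt = sum(-h0$birth < radius_threshold),
           quadrant_stats(h1$birth, h1$death, "H1Q1_"))
  as.data.frame(as.list(out))[, panel_stats(), drop = FALSE]
}

#' Restrict a diagram to a scale window
#'
#' Keeps points whose birth and death fall in the given intervals, so panels
#' can be recomputed on features at a specific scale of interest.
#'
#' @param diag A `persistence_diagram`.
#' @param birth_window,death_window Length-2 numeric intervals, possibly
#'   infinite.
#' @return The filtered diagram (attributes preserved).
#' @export
restrict_scale <- function(diag, birth_window = c(-Inf, Inf),
                           death_window = c(-Inf, Inf)) {
  stopifnot(length(birth_window) == 2L, length(death_window) == 2L)
  keep <- diag$birth >= birth_window[1] & diag$birth <= birth_window[2] &
    diag$death >= death_window[1] & diag$death <= death_window[2]
  out <- diag[keep, , drop = FALSE]
  attributes(out)$degenerate <- attr(diag, "degenerate")
  out
}

#' Patch score map for one statistic
#'
#' Arranges one panel statistic on the patch grid of a single source image,
#' to highlight regions of interest. Tiles with no patch (discarded
#' background) are `NA`.
#'
#' @param panels Data frame of per-patch panels carrying `patch_row` and
#'   `patch_col` columns.
#' @param statistic One of [panel_stats()].
#' @return Numeric matrix (patch rows x patch cols) of scores.
#' @export
score_patches <- function(panels, statistic) {
  if (!statistic %in% names(panels))
    stop("unknown statistic '", statistic, "'; valid names: ",
         paste(panel_stats(), collapse = ", "))
  stopifnot(all(c("patch_row", "patch_col") %in% names(panels)))
  out <- matrix(NA_real_, max(panels$patch_row), max(panels$patch_col))
  out[cbind(panels$patch_row, panels$patch_col)] <- panels[[statistic]]
  out
}
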