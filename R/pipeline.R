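#' Persistence panel of one binary patch
#'
#' Runs SEDT, persistence and the statistic panel on a single binary patch,
#' the per-patch unit of the whole workflow.
#'
#' @param mask Logical matrix (`TRUE` = white).
#' @param radius_threshold Passed to [compute_panel()].
#' @return One-row panel data frame; all-missing (except zero counts) for
#'   degenerate single-phase patches.
#' @export
patch_panel <- function(mask, radius_threshold = 2) {
  field <- signed_edt(mask)
  diag <- compute_persistence(field)
  diag <- split_quadrants(diag, check = !isTRUE(attr(field, "degenerate")))
  compute_panel(diag, radius_threshold = radius_threshold)
}

#' Panel table of a patch collection
#'
#' Applies [patch_panel()] to a list of patches (as produced by
#' [preprocess_image()] or [make_group_dataset()]) and binds the rows with
#' their provenance and labels.
#'
#' @param patches List of patches with `mask` and optional `labels`,
#'   `patch_row`, `patch_col` entries.
#' @inheritParams patch_panel
#' @return Data frame: one row per patch, label/provenance columns plus the
#'   [panel_stats()] columns.
#' @export
panel_table <- function(patches, radius_threshold = 2) {
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    row <- patch_panel(p$mask, radius_threshold = radius_threshold)
    meta <- data.frame(patch = i)
    if (!is.null(p$patch_row)) {
      meta$patch_row <- p$patch_row
      meta$patch_col <- p$patch_col
    }
    if (!is.null(p$labels))
      for (nm in names(p$labels)) meta[[nm]] <- p$labels[[nm]]
    cbind(meta, row)
  })
  do.call(rbind, rows)
}

#' Run the full micro-hole analysis workflow
#'
#' Composes all stages: preprocessing of greyscale images (or directly
#' supplied binary patches) into patches, SEDT + persistence + statistic
#' panels, group permutation tests with Benjamini-Hochberg adjustment, the
#' patch classifier, and diagnostic figures; writes all artefacts plus a
#' manifest of parameters and seeds sufficient to re-run identically.
#'
#' @param images Named list of greyscale matrices, or `NULL` when `patches`
#'   is given.
#' @param labels Data frame with one row per image (columns such as
#'   `sample`, `sex`, `genotype`, `modality`), row order matching `images`.
#' @param patches Pre-made binary patch list (e.g. from
#'   [make_group_dataset()]); used instead of `images`.
#' @param out_dir Output directory (created if needed).
#' @param patch_size,stride Patch geometry (defaults 300/300).
#' @param radius_threshold Radius cut for the count statistics (default 2).
#' @param n_shuffles Permutation shuffles (default 10000).
#' @param alpha Significance level (default 0.05).
#' @param C,folds,repeats Classifier settings (defaults 3, 10, 100).
#' @param seed Integer seed for all stochastic stages.
#' @param figures Write diagnostic figures (default TRUE).
#' @return List with `panels`, `tests`, `classifier`, `manifest` (also
#'   written under `out_dir`).
#' @export
run_pipeline <- function(images = NULL, labels = NULL, patches = NULL,
                         out_dir = NULL, patch_size = 300L, stride = patch_size,
                         radius_threshold = 2, n_shuffles = 10000L,
                         alpha = 0.05, C = 3, folds = 10L, repeats = 100L,
                         seed = 1L, figures = TRUE) {
  if (is.null(images) && is.null(patches))
    stop("no input: supply 'images' (greyscale matrices) or 'patches'")
  if (is.null(patches)) {
    if (length(images) == 0L) stop("empty input image list")
    patches <- list()
    for (i in seq_along(images)) {
      lab <- if (!is.null(labels)) as.list(labels[i, , drop = FALSE]) else NULL
      ps <- preprocess_image(images[[i]], side = patch_size, stride = stride,
                             labels = lab)
      patches <- c(patches, ps)
    }
    if (length(patches) == 0L) stop("preprocessing produced no patches")
  }
  panels <- panel_table(patches, radius_threshold = radius_threshold)
  tests <- if ("genotype" %in% names(panels))
    run_comparison_suite(panels, n_shuffles = n_shuffles, seed = seed,
                         alpha = alpha)
  else NULL
  classifier <- if ("genotype" %in% names(panels) &&
                    all(table(panels$genotype) >= folds))
    evaluate_classifier(panels, features = "panel10", C = C, folds = folds,
                        repeats = repeats, seed = seed)
  else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("topoholes")),
    n_patches = nrow(panels), patch_size = patch_size, stride = stride,
    radius_threshold = radius_threshold, n_shuffles = n_shuffles,
    alpha = alpha, C = C, folds = folds, repeats = repeats, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(panels, file.path(out_dir, "panels.csv"), row.names = FALSE)
    if (!is.null(tests))
      write.csv(tests, file.path(out_dir, "tests.csv"), row.names = FALSE)
    if (!is.null(classifier))
      write.csv(data.frame(t(classifier$metrics)),
                file.path(out_dir, "classifier.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (figures) {
      diag1 <- split_quadrants(
        compute_persistence(signed_edt(patches[[1]]$mask)), check = FALSE)
      plot_diagram(diag1, file = file.path(out_dir, "diagram_patch1.png"))
      if (!is.null(tests) && "genotype" %in% names(panels)) {
        s <- "H0Q2_n_points"
        pa <- tests$p_adjusted[tests$statistic == s][1]
        plot_group_boxes(panels, s, group = "genotype", p_adjusted = pa,
                         file = file.path(out_dir, "boxes_n_points.png"))
      }
      if (all(c("patch_row", "patch_col") %in% names(panels)) &&
          !anyDuplicated(panels[, c("patch_row", "patch_col")])) {
        # patch grid identifies tiles uniquely only for a single source image
        sm <- score_patches(panels, "H0Q2_n_points")
        plot_scoremap(sm, "H0Q2_n_points",
                      file = file.path(out_dir, "scoremap_n_points.png"))
      }
    }
  }
  list(panels = panels, tests = tests, classifier = classifier,
       manifest = manifest)
}

#' Write a diagram to CSV and read it back
#'
#' CSV interchange for per-patch diagrams: columns `dim`, `birth`, `death`,
#' `birth_row`, `birth_col`, `essential` (`death` may be `Inf` for the
#' essential class).
#'
#' @param diag A `persistence_diagram`.
#' @param path CSV path.
#' @return `write_diagram_csv`: the path, invisibly. `read_diagram_csv`:
#'   the diagram.
#' @export
write_diagram_csv <- function(diag, path) {
  write.csv(as.data.frame(diag), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagram_csv
#' @export
read_diagram_csv <- function(path) {
  out <- read.csv(path)
  out$essential <- as.logical(out$essential)
  class(out) <- c("persistence_diagram", class(out))
  out
}
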