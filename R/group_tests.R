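#' Unpaired permutation test on a difference of means
#'
#' Tests the null hypothesis that two groups of patch statistics have
#' identical distributions. The observed statistic is `|mean(x) - mean(y)|`
#' (two-sided); each shuffle reassigns the pooled values at random to groups
#' of the original sizes and records the absolute mean difference. The pseudo
#' p-value is the proportion of shuffled differences at least as large as the
#' observed one (ties qualify); no add-one correction is applied, so a pseudo
#' p of exactly 0 is reportable and should be read as "very small".
#'
#' @param x,y Numeric vectors (missing values dropped); both must be
#'   non-empty after exclusion.
#' @param n_shuffles Number of random reassignments (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param mode `"absolute"` (two-sided, default) or `"signed"`
#'   (one-sided on `mean(x) - mean(y)`).
#' @return List of class `perm_test`: `observed`, `p_value`, `n_shuffles`,
#'   `n_x`, `n_y`, `seed`, `mode`.
#' @export
perm_test <- function(x, y, n_shuffles = 10000L, seed = NULL,
                      mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty after missing-value exclusion")
  if (!is.null(seed)) set.seed(seed)
  stat <- if (mode == "absolute") function(a, b) abs(mean(a) - mean(b))
          else function(a, b) mean(a) - mean(b)
  obs <- stat(x, y)
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  sp <- sum(pooled)
  shuffled <- vapply(seq_len(n_shuffles), function(i) {
    sx <- sum(pooled[sample.int(n, nx)])
    mx <- sx / nx; my <- (sp - sx) / (n - nx)
    if (mode == "absolute") abs(mx - my) else mx - my
  }, numeric(1))
  # round-off guard so reassignments that reproduce the observed split
  # qualify as ties despite floating-point summation order
  eps <- 1e-9 * (1 + abs(obs))
  structure(list(observed = obs, p_value = mean(shuffled >= obs - eps),
                 n_shuffles = n_shuffles, n_x = nx, n_y = n - nx,
                 seed = seed, mode = mode),
            class = "perm_test")
}

#' Paired permutation test between modalities
#'
#' Tests whether a patch statistic differs between two imaging modalities,
#' pairing values per patch. Each shuffle independently swaps each pair's
#' two values (equivalently, flips the sign of each paired difference) with
#' probability 1/2; the test statistic is the mean of the differences
#' normalised by their standard deviation, and the two-tailed pseudo p-value
#' is the proportion of shuffled |statistics| at least as large as the
#' observed |statistic|. If the differences have zero standard deviation the
#' statistic is defined as 0, so identical columns give p = 1 by the
#' qualifying-tie convention.
#'
#' @param x,y Equal-length paired numeric vectors (pairs with a missing
#'   value are dropped).
#' @inheritParams perm_test
#' @return List of class `perm_test`.
#' @export
paired_perm_test <- function(x, y, n_shuffles = 10000L, seed = NULL) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  keep <- !(is.na(x) | is.na(y))
  d <- (x - y)[keep]
  if (length(d) == 0L) stop("no complete pairs")
  if (!is.null(seed)) set.seed(seed)
  tstat <- function(v) { s <- sd(v); if (is.na(s) || s == 0) 0 else mean(v) / s }
  obs <- tstat(d)
  shuffled <- vapply(seq_len(n_shuffles), function(i) {
    tstat(d * sample(c(-1, 1), length(d), replace = TRUE))
  }, numeric(1))
  structure(list(observed = obs, p_value = mean(abs(shuffled) >= abs(obs)),
                 n_shuffles = n_shuffles, n_x = length(d), n_y = length(d),
                 seed = seed, mode = "paired"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test (", x$mode, "): observed = ",
      format(x$observed, digits = 4), ", pseudo p = ",
      format(x$p_value, digits = 4), " (", x$n_shuffles, " shuffles)\n",
      sep = "")
  invisible(x)
}

#' Benjamini-Hochberg adjustment within families
#'
#' Step-up false-discovery-rate adjustment, applied independently within
#' each family of tests (e.g. separately for the SHG and TPaF statistic
#' families).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param family Optional vector of family labels, same length as `p`;
#'   `NULL` treats all p-values as one family.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p, family = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (is.null(family)) return(p.adjust(p, method = "BH"))
  stopifnot(length(family) == length(p))
  out <- p
  for (f in unique(family)) {
    idx <- which(family == f)
    out[idx] <- p.adjust(p[idx], method = "BH")
  }
  out
}

#' Group comparison suite over a panel table
#'
#' Runs the unpaired permutation test for each statistic between the groups
#' defined by the label columns of a panel table, mirroring the layout of a
#' per-modality comparison report: per modality, test vs control within each
#' sex, and male vs female within each genotype; plus (when both modalities
#' are present with matched patch keys) the paired modality test per
#' statistic. Benjamini-Hochberg adjustment is applied within each
#' (comparison, modality) family.
#'
#' @param panels Data frame of per-patch panels with label columns
#'   `genotype` (levels `"KO"`/`"WT"`) and optionally `sex` (`"M"`/`"F"`),
#'   `modality`, and patch keys (`sample`, `patch_row`, `patch_col`) for
#'   pairing.
#' @param statistics Statistic columns to test (default [canonical_stats()]).
#' @param n_shuffles Shuffles per test (default 10000).
#' @param seed Integer seed; per-test seeds are derived from it.
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05, applied to adjusted p-values).
#' @return Data frame with one row per (comparison, modality, statistic):
#'   observed difference, raw and adjusted pseudo p-values, significance
#'   flag.
#' @export
run_comparison_suite <- function(panels, statistics = canonical_stats(),
                                 n_shuffles = 10000L, seed = 1L,
                                 alpha = 0.05) {
  stopifnot("genotype" %in% names(panels))
  statistics <- intersect(statistics, names(panels))
  modalities <- if ("modality" %in% names(panels)) unique(panels$modality) else NA
  has_sex <- "sex" %in% names(panels)

  comparisons <- list()
  add <- function(name, sel_a, sel_b) {
    if (sum(sel_a) >= 2L && sum(sel_b) >= 2L)
      comparisons[[length(comparisons) + 1L]] <<-
        list(name = name, a = sel_a, b = sel_b)
    else
      warning("comparison '", name, "' skipped: fewer than 2 patches in a group")
  }
  rows <- list()
  seed_i <- 0L
  for (m in modalities) {
    in_m <- if (is.na(m[1])) rep(TRUE, nrow(panels)) else panels$modality == m
    comparisons <- list()
    if (has_sex) {
      add("M KO v WT", in_m & panels$sex == "M" & panels$genotype == "KO",
          in_m & panels$sex == "M" & panels$genotype == "WT")
      add("F KO v WT", in_m & panels$sex == "F" & panels$genotype == "KO",
          in_m & panels$sex == "F" & panels$genotype == "WT")
      add("KO M v F", in_m & panels$genotype == "KO" & panels$sex == "M",
          in_m & panels$genotype == "KO" & panels$sex == "F")
      add("WT M v F", in_m & panels$genotype == "WT" & panels$sex == "M",
          in_m & panels$genotype == "WT" & panels$sex == "F")
    } else {
      add("KO v WT", in_m & panels$genotype == "KO",
          in_m & panels$genotype == "WT")
    }
    for (cmp in comparisons) {
      for (s in statistics) {
        seed_i <- seed_i + 1L
        res <- perm_test(panels[[s]][cmp$a], panels[[s]][cmp$b],
                         n_shuffles = n_shuffles,
                         seed = (seed + 7919L * seed_i) %% .Machine$integer.max)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = cmp$name, modality = as.character(m), statistic = s,
          observed = res$observed, p_value = res$p_value)
      }
    }
  }
  # paired modality tests on matched patches
  if (length(modalities) == 2L && !any(is.na(modalities))) {
    keys <- c("sample", "patch_row", "patch_col")
    keys <- keys[keys %in% names(panels)]
    if (length(keys)) {
      key <- do.call(paste, c(panels[keys], sep = "|"))
      a <- panels$modality == modalities[1]
      b <- panels$modality == modalities[2]
      idx <- match(key[a], key[b])
      ok <- !is.na(idx)
      if (sum(ok) >= 2L) {
        for (s in statistics) {
          seed_i <- seed_i + 1L
          res <- paired_perm_test(panels[[s]][a][ok],
                                  panels[[s]][b][idx[ok]],
                                  n_shuffles = n_shuffles,
                                  seed = (seed + 7919L * seed_i) %% .Machine$integer.max)
          rows[[length(rows) + 1L]] <- data.frame(
            comparison = paste(modalities[1], "v", modalities[2], "(paired)"),
            modality = "both", statistic = s,
            observed = res$observed, p_value = res$p_value)
        }
      }
    }
  }
  if (length(rows) == 0L)
    stop("no feasible comparisons: every group had fewer than 2 patches")
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value,
                              family = paste(out$comparison, out$modality))
  out$significant <- out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}
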