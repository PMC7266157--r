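## Homolog-resolved BrdU replication-timing quantification. Chromosome
## bodies are segmented from the DAPI channel (Otsu threshold + connected
## components), homologs identified by the centromere-size polymorphism
## (larger integrated centromere signal = 6A), total BrdU incorporation per
## chromosome computed as mean pixel intensity x occupied area (identically
## the pixel sum), and the per-cell 6B/6A ratio compared across genotype
## groups with a tie-corrected Kruskal-Wallis test. Measurements may also
## enter as pre-extracted per-homolog tables; the statistical path is
## identical.

#' Segment chromosome bodies from a DAPI grid
#'
#' Global Otsu threshold (between-class-variance maximization) followed by
#' connected-component labeling; components below `min_area` pixels are
#' dropped. Deterministic for a given input.
#'
#' @param dapi Numeric matrix (>= 64 x 64).
#' @param min_area Minimum component area in pixels (default 50).
#' @return Integer label matrix (0 = background); 0 components gives an
#'   all-zero matrix with a warning.
#' @export
segment_chromosomes <- function(dapi, min_area = 50) {
  stopifnot(is.matrix(dapi), nrow(dapi) >= 64, ncol(dapi) >= 64)
  rng <- range(dapi)
  if (diff(rng) == 0) {
    warning("constant DAPI grid: no chromosomes segmented")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  scaled <- (dapi - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- scaled > thr
  labels <- EBImage::bwlabel(EBImage::Image(mask))
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(dapi), ncol(dapi))
  keep <- which(tabulate(labels[labels > 0]) >= min_area)
  if (length(keep) == 0) {
    warning("no components above min_area")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  out <- matrix(0L, nrow(dapi), ncol(dapi))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

#' Identify homologs 6A/6B by centromere size
#'
#' Of exactly two chromosome masks, the one containing the larger integrated
#' centromere-channel signal is 6A (the centromere-size polymorphism);
#' blobs whose integrated signals differ by less than `margin` (relative to
#' the larger) are indistinguishable and the cell is excluded.
#'
#' @param labels Label matrix from [segment_chromosomes()] with exactly two
#'   components.
#' @param cen Centromere-channel matrix.
#' @param margin Relative indistinguishability margin (default 0.10).
#' @return Named integer vector `c("6A" = label, "6B" = label)`, or `NULL`
#'   (with a warning) for an indeterminate cell.
#' @export
identify_homologs <- function(labels, cen, margin = 0.10) {
  labs <- sort(unique(labels[labels > 0]))
  if (length(labs) != 2) {
    stop("expected exactly two chromosome masks, found ", length(labs))
  }
  ## integrated centromere intensity over each mask, background suppressed
  ## at half the channel's dynamic range so diffuse noise does not count
  thr <- max(cen) / 2
  sig <- vapply(labs, function(l) sum(cen[labels == l & cen > thr]), 0)
  big <- which.max(sig)
  if (sig[big] <= 0 || (sig[big] - sig[-big]) / sig[big] < margin) {
    warning("centromere blobs indistinguishable; cell excluded")
    return(NULL)
  }
  stats::setNames(c(labs[big], labs[-big]), c("6A", "6B"))
}

#' Measure one chromosome mask
#'
#' Mean BrdU and DAPI intensities over the mask pixels and the occupied
#' area; `total_brdu` is mean intensity x area, which is identically the
#' pixel sum.
#'
#' @param mask Logical matrix (non-empty, same dim as the grids).
#' @param brdu,dapi Intensity matrices.
#' @return List of class `chromosome_measurement`: `pixel_area`,
#'   `mean_brdu`, `mean_dapi`, `total_brdu`.
#' @export
measure_chromosome <- function(mask, brdu, dapi) {
  stopifnot(is.logical(mask))
  if (!all(dim(mask) == dim(brdu)) || !all(dim(mask) == dim(dapi))) {
    stop("mask and intensity grids must have identical dimensions")
  }
  area <- sum(mask)
  if (area == 0) stop("empty chromosome mask")
  mb <- mean(brdu[mask])
  md <- mean(dapi[mask])
  structure(list(pixel_area = area, mean_brdu = mb, mean_dapi = md,
                 total_brdu = mb * area),
            class = "chromosome_measurement")
}

#' Per-cell BrdU 6B/6A ratio from an image triplet
#'
#' Runs the full image path: segment the DAPI channel, identify homologs by
#' centromere size, optionally subtract the per-image median of non-mask
#' pixels from the BrdU channel (background correction, default on for
#' images), measure both chromosomes, and form
#' `total_brdu(6B) / total_brdu(6A)`.
#'
#' @param img List with `dapi`, `brdu`, `cen` matrices (e.g. from
#'   [simulate_brdu_image()]).
#' @param bg_subtract Subtract per-image background (default TRUE).
#' @param margin Centromere indistinguishability margin.
#' @return List: `ratio`, `measurements` (per homolog), or `NULL` when the
#'   cell is excluded (indeterminate homologs or zero 6A signal).
#' @export
brdu_ratio_image <- function(img, bg_subtract = TRUE, margin = 0.10) {
  labels <- segment_chromosomes(img$dapi)
  homs <- identify_homologs(labels, img$cen, margin = margin)
  if (is.null(homs)) return(NULL)
  brdu <- img$brdu
  if (bg_subtract) {
    bg <- median(brdu[labels == 0])
    brdu <- pmax(brdu - bg, 0)
  }
  m6a <- measure_chromosome(labels == homs[["6A"]], brdu, img$dapi)
  m6b <- measure_chromosome(labels == homs[["6B"]], brdu, img$dapi)
  if (m6a$total_brdu <= 0) {
    warning("zero BrdU signal on 6A; cell excluded")
    return(NULL)
  }
  list(ratio = m6b$total_brdu / m6a$total_brdu,
       measurements = list(`6A` = m6a, `6B` = m6b))
}

#' Per-cell BrdU ratios from a measurement table
#'
#' For workstation-extracted measurements (no background subtraction: the
#' table is assumed already corrected). Each cell needs exactly one 6A and
#' one 6B row; cells violating this, or with zero 6A signal, are excluded
#' with a reason.
#'
#' @param measurements data.frame: `cell_id`, `homolog` (`"6A"`/`"6B"`),
#'   `pixel_area`, `mean_brdu`, optional `group`.
#' @return data.frame: `cell_id`, `ratio`, `group` (NA if absent); excluded
#'   cells are attached as attribute `excluded`.
#' @export
brdu_ratio_table <- function(measurements) {
  need <- c("cell_id", "homolog", "pixel_area", "mean_brdu")
  stopifnot(all(need %in% names(measurements)))
  measurements$total_brdu <-
    measurements$mean_brdu * measurements$pixel_area
  out <- list()
  excluded <- character(0)
  for (id in unique(measurements$cell_id)) {
    sub <- measurements[measurements$cell_id == id, , drop = FALSE]
    a <- sub[sub$homolog == "6A", , drop = FALSE]
    b <- sub[sub$homolog == "6B", , drop = FALSE]
    if (nrow(a) != 1 || nrow(b) != 1) {
      excluded <- c(excluded, paste0(id, ": need one 6A and one 6B row"))
      next
    }
    if (a$total_brdu <= 0) {
      excluded <- c(excluded, paste0(id, ": zero 6A signal"))
      next
    }
    grp <- if ("group" %in% names(sub)) sub$group[1] else NA_character_
    out[[length(out) + 1]] <- data.frame(
      cell_id = id, ratio = b$total_brdu / a$total_brdu, group = grp,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(cell_id = character(0), ratio = numeric(0),
               group = character(0))
  attr(res, "excluded") <- excluded
  res
}

#' Tie-corrected Kruskal-Wallis comparison of ratio groups
#'
#' Mid-ranks over the pooled data;
#' `H = 12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1)`, divided by the tie
#' correction `1 - sum(t^3 - t) / (N^3 - N)`; p from the chi-square upper
#' tail with k - 1 degrees of freedom (delegated to [stats::kruskal.test()]).
#' The chi-square p is approximate at the small group sizes typical of
#' per-clone metaphase counts; `p_method = "permutation"` replaces it with a
#' Monte-Carlo permutation p (group labels permuted, one-sided on H).
#' All values identical degenerates to H = 0, p = 1.
#'
#' @param groups Named list of numeric vectors (k >= 2, none empty).
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Permutations for `p_method = "permutation"` (default 10000).
#' @param perm_seed Seed for the permutation draw.
#' @return List of class `group_comparison`: `H`, `df`, `p_value`,
#'   `group_sizes`, `group_medians`, `p_method`.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "permutation"),
                           n_perm = 10000, perm_seed = 1) {
  p_method <- match.arg(p_method)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("empty group(s)")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1) {
    kt <- list(statistic = 0, parameter = length(groups) - 1, p.value = 1)
  } else {
    fit <- kruskal.test(x, g)
    kt <- list(statistic = unname(fit$statistic),
               parameter = unname(fit$parameter),
               p.value = fit$p.value)
    if (p_method == "permutation") {
      set.seed(perm_seed)
      n <- length(x)
      h_perm <- vapply(seq_len(n_perm), function(b) {
        perm <- kruskal.test(x[sample.int(n)], g)
        unname(perm$statistic)
      }, 0)
      kt$p.value <- (sum(h_perm >= kt$statistic - 1e-9) + 1) / (n_perm + 1)
    }
  }
  structure(list(H = kt$statistic, df = kt$parameter,
                 p_value = kt$p.value,
                 group_sizes = lengths(groups),
                 group_medians = vapply(groups, median, 0),
                 p_method = p_method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  med <- paste(sprintf("%s: %.3f", names(x$group_medians),
                       x$group_medians), collapse = ", ")
  cat("  group medians  ", med, "\n")
  invisible(x)
}
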