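## Per-cell cytogenetic scoring: RNA-FISH signal-count summaries, cis/trans
## coordination of two monoallelically expressed loci (the random-vs-imprinted
## logic: coordinated expression in nearly all cells of a non-clonal
## population indicates random monoallelic expression under chromosome-wide
## coordination, whereas ~50% cis would indicate imprinting), and ReTiSH
## replication-asynchrony classification.

#' Summarize FISH signal counts for one probe
#'
#' @param cells Long FISH table (`cell_id`, `probe`, `n_signals`, ...).
#' @param probe Probe name.
#' @return List: `fractions` (named, signals 0/1/2, summing to 1),
#'   `monoallelic_fraction` (fraction with exactly one signal), `n_cells`.
#' @export
summarize_fish_counts <- function(cells, probe) {
  sub <- cells[cells$probe == probe, , drop = FALSE]
  if (nrow(sub) == 0) stop("no cells for probe ", probe)
  n <- nrow(sub)
  fr <- vapply(0:2, function(k) sum(sub$n_signals == k) / n, 0)
  names(fr) <- c("0", "1", "2")
  list(fractions = fr, monoallelic_fraction = fr[["1"]], n_cells = n)
}

#' Score cis/trans coordination of two probes
#'
#' Informative cells are those where both probes show exactly one signal on
#' a resolved homolog; two-signal (biallelic-appearing) cells are excluded
#' from coordination and tallied separately. The test is the exact two-sided
#' binomial test of the cis count against p = 0.5 (summation of all outcome
#' probabilities at most that of the observed count); classification is
#' `coordinated_cis`/`coordinated_trans` when p < alpha with the
#' corresponding majority, else `not_coordinated`.
#'
#' @param cells Long FISH table with `homolog` per probe per cell.
#' @param probes Length-2 character vector.
#' @param alpha Classification level (default 0.01); the exact p is always
#'   reported.
#' @return List of class `coordination_result`: `n_cis`, `n_trans`,
#'   `cis_fraction`, `p_value`, `classification`, `n_biallelic_cells`,
#'   `n_informative`.
#' @export
score_cis_trans <- function(cells, probes, alpha = 0.01) {
  stopifnot(length(probes) == 2)
  a <- cells[cells$probe == probes[1], , drop = FALSE]
  b <- cells[cells$probe == probes[2], , drop = FALSE]
  i <- match(a$cell_id, b$cell_id)
  b <- b[i, , drop = FALSE]
  n_biall <- sum(a$n_signals == 2 | b$n_signals == 2, na.rm = TRUE)
  ok <- a$n_signals == 1 & b$n_signals == 1 &
    !is.na(a$homolog) & !is.na(b$homolog)
  if (sum(ok, na.rm = TRUE) == 0) {
    stop("no informative cells (both probes single-signal with resolved ",
         "homolog); QC failure")
  }
  cis <- a$homolog[ok] == b$homolog[ok]
  n_cis <- sum(cis)
  n_trans <- sum(!cis)
  bt <- binom.test(n_cis, n_cis + n_trans, p = 0.5)
  p <- bt$p.value
  cls <- "not_coordinated"
  if (p < alpha) {
    cls <- if (n_cis > n_trans) "coordinated_cis" else "coordinated_trans"
  }
  structure(list(n_cis = n_cis, n_trans = n_trans,
                 cis_fraction = n_cis / (n_cis + n_trans),
                 p_value = p, classification = cls,
                 n_biallelic_cells = n_biall,
                 n_informative = n_cis + n_trans),
            class = "coordination_result")
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf(
    "coordination: %d cis / %d trans (cis fraction %.3f), p = %.3g -> %s\n",
    x$n_cis, x$n_trans, x$cis_fraction, x$p_value, x$classification))
  invisible(x)
}

split_homologs <- function(s) {
  if (is.na(s) || s == "") character(0) else strsplit(s, ",")[[1]]
}

#' Classify one ReTiSH cell for one probe
#'
#' A 5 h BrdU pulse labels only late S phase, so a 5 h hybridization signal
#' on exactly one homolog marks that homolog as late-replicating
#' (asynchronous locus). QC: the 14 h signal must be on both homologs, and
#' the centromere probe must hybridize to both homologs at both time points
#' (centromeric heterochromatin is late-replicating).
#'
#' @param cell_5h,cell_14h Rows of a ReTiSH table for one cell at the two
#'   time points (including the `"cen"` probe rows).
#' @param probe Locus probe name.
#' @return List: `class` (`"asynchronous"`, `"synchronous_late"`,
#'   `"synchronous_early"`, `"qc_fail"`), `late_homolog` (for asynchronous).
#' @export
classify_retish_cell <- function(cell_5h, cell_14h, probe) {
  get <- function(df, p) {
    r <- df[df$probe == p, , drop = FALSE]
    if (nrow(r) != 1) return(NULL)
    split_homologs(r$homologs)
  }
  cen5 <- get(cell_5h, "cen")
  cen14 <- get(cell_14h, "cen")
  both <- c("A", "B")
  if (is.null(cen5) || is.null(cen14) ||
      !setequal(cen5, both) || !setequal(cen14, both)) {
    return(list(class = "qc_fail", late_homolog = NA_character_,
                reason = "centromeric probe must hybridize to both homologs"))
  }
  h14 <- get(cell_14h, probe)
  if (is.null(h14) || !setequal(h14, both)) {
    return(list(class = "qc_fail", late_homolog = NA_character_,
                reason = "14 h signal must be on both homologs"))
  }
  h5 <- get(cell_5h, probe)
  if (is.null(h5)) {
    return(list(class = "qc_fail", late_homolog = NA_character_,
                reason = "missing 5 h record"))
  }
  if (length(h5) == 1) {
    return(list(class = "asynchronous", late_homolog = h5))
  }
  if (length(h5) == 2) {
    return(list(class = "synchronous_late", late_homolog = NA_character_))
  }
  list(class = "synchronous_early", late_homolog = NA_character_)
}

#' Aggregate ReTiSH coordination over cells
#'
#' Among cells where both loci are asynchronous (and QC passes), the
#' fraction with both late alleles on the same homolog (cis) vs opposite
#' (trans), with counts and a QC-failure tally.
#'
#' @param cells Long ReTiSH table (from [simulate_retish_table()] or TSV).
#' @param probe_a,probe_b Locus probe names.
#' @return List: `n_cis`, `n_trans`, `cis_fraction`, `trans_fraction`,
#'   `n_informative`, `n_qc_fail`, `n_cells`, `per_cell` (data.frame).
#' @export
aggregate_retish <- function(cells, probe_a, probe_b) {
  ids <- unique(cells$cell_id)
  rows <- lapply(ids, function(id) {
    c5 <- cells[cells$cell_id == id & cells$timepoint == "5h", , drop = FALSE]
    c14 <- cells[cells$cell_id == id & cells$timepoint == "14h", ,
                 drop = FALSE]
    ca <- classify_retish_cell(c5, c14, probe_a)
    cb <- classify_retish_cell(c5, c14, probe_b)
    data.frame(cell_id = id, class_a = ca$class, class_b = cb$class,
               late_a = ca$late_homolog, late_b = cb$late_homolog,
               stringsAsFactors = FALSE)
  })
  per_cell <- do.call(rbind, rows)
  qc_fail <- per_cell$class_a == "qc_fail" | per_cell$class_b == "qc_fail"
  informative <- !qc_fail & per_cell$class_a == "asynchronous" &
    per_cell$class_b == "asynchronous"
  cis <- informative & per_cell$late_a == per_cell$late_b
  n_inf <- sum(informative)
  list(n_cis = sum(cis),
       n_trans = n_inf - sum(cis),
       cis_fraction = if (n_inf > 0) sum(cis) / n_inf else NA_real_,
       trans_fraction = if (n_inf > 0) 1 - sum(cis) / n_inf else NA_real_,
       n_informative = n_inf,
       n_qc_fail = sum(qc_fail),
       n_cells = length(ids),
       per_cell = per_cell)
}
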