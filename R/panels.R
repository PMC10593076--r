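#' Genotype panel
#'
#' Container for a subjects-by-variants dosage matrix plus per-variant
#' metadata. Dosages count the alternate allele (0, 1, 2) with `NA` as the
#' missing sentinel. Minor allele frequency, per-variant missing rate and the
#' Hardy-Weinberg exact-test p-value are computed from the dosages at
#' construction time. Variants must be sorted by position within chromosome,
#' as required by windowed LD pruning.
#'
#' @param dosage numeric matrix, subjects in rows (rownames = subject ids),
#'   variants in columns (colnames = variant ids); entries in `{0, 1, 2, NA}`.
#' @param chrom,pos per-variant chromosome label and position.
#' @param ref,alt per-variant reference / alternate allele (single bases);
#'   defaults `"A"` / `"G"` when not supplied.
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosage` and `variants` (a data.frame with columns `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `maf`, `missing_rate`, `hwe_p`).
#' @export
genotype_panel <- function(dosage, chrom = NULL, pos = NULL,
                           ref = NULL, alt = NULL) {
  if (!is.matrix(dosage) || !is.numeric(dosage)) {
    stop_config("dosage must be a numeric matrix")
  }
  p <- ncol(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("var%05d", seq_len(p))
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%05d", seq_len(nrow(dosage)))
  }
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop_config("dosage entries must be 0, 1, 2 or NA")
  if (is.null(chrom)) chrom <- rep("1", p)
  if (is.null(pos)) pos <- seq_len(p)
  if (is.null(ref)) ref <- rep("A", p)
  if (is.null(alt)) alt <- rep("G", p)
  stopifnot(length(chrom) == p, length(pos) == p)
  # positional sort within chromosome
  ord <- order(chrom, pos)
  if (!identical(ord, seq_len(p))) {
    dosage <- dosage[, ord, drop = FALSE]
    chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
  }
  af <- colMeans(dosage, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  maf <- pmin(af, 1 - af)
  miss <- colMeans(is.na(dosage))
  hwe <- vapply(seq_len(ncol(dosage)), function(j) {
    d <- dosage[, j]
    d <- d[!is.na(d)]
    if (!length(d)) return(1)
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
  }, numeric(1))
  structure(list(
    dosage = dosage,
    variants = data.frame(
      variant_id = colnames(dosage), chrom = as.character(chrom),
      pos = as.numeric(pos), ref = as.character(ref), alt = as.character(alt),
      af = unname(af), maf = unname(maf),
      missing_rate = unname(miss), hwe_p = unname(hwe),
      stringsAsFactors = FALSE
    )
  ), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d subjects x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  MAF range [%.4f, %.4f]; %d variants with missing calls\n",
              min(x$variants$maf), max(x$variants$maf),
              sum(x$variants$missing_rate > 0)))
  invisible(x)
}

# restrict a panel to a variant subset (ids) and/or subject subset,
# preserving the precomputed metadata
subset_panel <- function(panel, variant_ids = NULL, subject_ids = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosage
  meta <- panel$variants
  if (!is.null(variant_ids)) {
    keep <- meta$variant_id %in% variant_ids
    dos <- dos[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  if (!is.null(subject_ids)) {
    dos <- dos[subject_ids, , drop = FALSE]
  }
  structure(list(dosage = dos, variants = meta), class = "genotype_panel")
}

#' Metabolite panel
#'
#' Subjects-by-metabolites abundance matrix with missing values coded `NA`,
#' plus the designation of a template subset: fully observed metabolites used
#' as prior knowledge by the imputation pipeline. Template metabolites must
#' be observed for every subject.
#'
#' @param abundance numeric matrix, subjects in rows, metabolites in columns.
#' @param template_ids character vector of metabolite ids designated as the
#'   template set (may be empty; [choose_template_set()] can pick one later).
#' @return An object of class `metabolite_panel`.
#' @export
metabolite_panel <- function(abundance, template_ids = character()) {
  if (!is.matrix(abundance) || !is.numeric(abundance)) {
    stop_config("abundance must be a numeric matrix")
  }
  if (is.null(colnames(abundance))) {
    colnames(abundance) <- sprintf("met%04d", seq_len(ncol(abundance)))
  }
  if (is.null(rownames(abundance))) {
    rownames(abundance) <- sprintf("S%05d", seq_len(nrow(abundance)))
  }
  template_ids <- as.character(template_ids)
  bad <- setdiff(template_ids, colnames(abundance))
  if (length(bad)) stop_config("unknown template ids: %s", paste(bad, collapse = ", "))
  if (length(template_ids)) {
    incomplete <- template_ids[colSums(is.na(abundance[, template_ids, drop = FALSE])) > 0]
    if (length(incomplete)) {
      stop_config("template metabolites must be fully observed: %s",
                  paste(incomplete, collapse = ", "))
    }
  }
  structure(list(abundance = abundance, template_ids = template_ids),
            class = "metabolite_panel")
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf("metabolite_panel: %d subjects x %d metabolites (%d templates)\n",
              nrow(x$abundance), ncol(x$abundance), length(x$template_ids)))
  cat(sprintf("  overall missing fraction %.4f\n", mean(is.na(x$abundance))))
  invisible(x)
}

#' Filter metabolites by missing rate
#'
#' Restricts a panel to metabolites whose missing rate is below a cut-off
#' (default 5%), the usual pre-filter before imputation modelling.
#'
#' @param panel a [metabolite_panel()].
#' @param max_missing maximum tolerated per-metabolite missing fraction.
#' @return A filtered `metabolite_panel`.
#' @export
filter_metabolites <- function(panel, max_missing = 0.05) {
  stopifnot(inherits(panel, "metabolite_panel"))
  miss <- colMeans(is.na(panel$abundance))
  keep <- names(miss)[miss < max_missing]
  metabolite_panel(panel$abundance[, keep, drop = FALSE],
                   intersect(panel$template_ids, keep))
}

#' Scoring table for polygenic scores
#'
#' A PGS-Catalog-style scoring table: variant ids with the allele the weight
#' applies to and the effect weight.
#'
#' @param score_id identifier of the score.
#' @param variant_id,effect_allele,effect_weight parallel vectors describing
#'   the entries; `variant_id` must be unique within a table.
#' @return A data.frame of class `scoring_table` with attribute `score_id`.
#' @export
scoring_table <- function(score_id, variant_id, effect_allele, effect_weight) {
  if (anyDuplicated(variant_id)) stop_config("variant ids must be unique within a scoring table")
  out <- data.frame(variant_id = as.character(variant_id),
                    effect_allele = as.character(effect_allele),
                    effect_weight = as.numeric(effect_weight),
                    stringsAsFactors = FALSE)
  attr(out, "score_id") <- as.character(score_id)
  class(out) <- c("scoring_table", "data.frame")
  out
}
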