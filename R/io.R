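# Plain-text readers/writers for the package's standard formats: dosage
# matrices and variant metadata as TSV, genotypes as minimal VCF (GT field),
# metabolite panels as TSV with empty cells for missing values, and
# PGS-Catalog-style scoring tables.

#' Write / read a genotype panel as TSV
#'
#' `write_genotype_tsv()` writes two files: `<stem>.dosage.tsv`
#' (subjects x variants, first column `subject_id`) and
#' `<stem>.variants.tsv` (variant metadata). `read_genotype_tsv()` rebuilds
#' the panel from them.
#'
#' @param panel a [genotype_panel()].
#' @param stem output path stem.
#' @return The stem (write) or a `genotype_panel` (read), invisibly/visibly.
#' @export
write_genotype_tsv <- function(panel, stem) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- data.frame(subject_id = rownames(panel$dosage), panel$dosage,
                  check.names = FALSE)
  utils::write.table(d, paste0(stem, ".dosage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$variants[, c("variant_id", "chrom", "pos", "ref", "alt")],
                     paste0(stem, ".variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(stem) {
  d <- utils::read.table(paste0(stem, ".dosage.tsv"), header = TRUE, sep = "\t",
                         check.names = FALSE)
  meta <- utils::read.table(paste0(stem, ".variants.tsv"), header = TRUE,
                            sep = "\t", colClasses = c(chrom = "character"))
  dosage <- as.matrix(d[, -1, drop = FALSE])
  rownames(dosage) <- d$subject_id
  m <- meta[match(colnames(dosage), meta$variant_id), ]
  genotype_panel(dosage, chrom = m$chrom, pos = m$pos, ref = m$ref, alt = m$alt)
}

#' Write a genotype panel as VCF
#'
#' Minimal VCFv4.2 with diploid unphased GT genotypes; dosage 0/1/2 maps to
#' `0/0`, `0/1`, `1/1` and missing to `./.`.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(panel$dosage)), collapse = "\t"),
             con)
  gt_map <- c("0/0", "0/1", "1/1")
  meta <- panel$variants
  for (j in seq_len(ncol(panel$dosage))) {
    d <- panel$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_map[d + 1])
    writeLines(paste(c(meta$chrom[j], meta$pos[j], meta$variant_id[j],
                       meta$ref[j], meta$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype panel
#'
#' Reads diploid GT genotypes with `vcfR` and converts allele counts to
#' dosages (alternate-allele count; `./.` becomes `NA`).
#'
#' @param path VCF file path.
#' @return A [genotype_panel()].
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_config("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  dosage <- apply(gt, 1, count_alt)  # subjects x variants
  if (!is.matrix(dosage)) dosage <- matrix(dosage, nrow = ncol(gt))
  rownames(dosage) <- colnames(gt)
  colnames(dosage) <- v@fix[, "ID"]
  genotype_panel(dosage,
                 chrom = v@fix[, "CHROM"], pos = as.numeric(v@fix[, "POS"]),
                 ref = v@fix[, "REF"], alt = v@fix[, "ALT"])
}

#' Write / read a metabolite panel as TSV
#'
#' Subjects x metabolites with a leading `subject_id` column; missing cells
#' are written empty. Template designation travels in a one-column sidecar
#' `<stem>.templates.tsv`.
#'
#' @param panel a [metabolite_panel()].
#' @param stem path stem.
#' @export
write_metabolite_tsv <- function(panel, stem) {
  stopifnot(inherits(panel, "metabolite_panel"))
  # 17 significant digits so abundances round-trip bit-exactly
  ab <- panel$abundance
  ch <- matrix(ifelse(is.na(ab), "", sprintf("%.17g", ab)),
               nrow(ab), ncol(ab), dimnames = dimnames(ab))
  d <- data.frame(subject_id = rownames(ab), ch, check.names = FALSE)
  utils::write.table(d, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  writeLines(c("template_id", panel$template_ids), paste0(stem, ".templates.tsv"))
  invisible(stem)
}

#' @rdname write_metabolite_tsv
#' @export
read_metabolite_tsv <- function(stem) {
  d <- utils::read.table(paste0(stem, ".tsv"), header = TRUE, sep = "\t",
                         check.names = FALSE, na.strings = "")
  ab <- as.matrix(d[, -1, drop = FALSE])
  rownames(ab) <- d$subject_id
  tfile <- paste0(stem, ".templates.tsv")
  templates <- if (file.exists(tfile)) readLines(tfile)[-1] else character()
  metabolite_panel(ab, templates)
}

#' Write / read scoring tables as TSV
#'
#' One file per table, named `<score_id>.tsv`, with columns `variant_id`,
#' `effect_allele`, `effect_weight`.
#'
#' @param tables list of [scoring_table()] objects.
#' @param dir output directory.
#' @export
write_scoring_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in tables) {
    out <- data.frame(variant_id = tab$variant_id,
                      effect_allele = tab$effect_allele,
                      effect_weight = sprintf("%.17g", tab$effect_weight),
                      stringsAsFactors = FALSE)
    utils::write.table(out, file.path(dir, paste0(attr(tab, "score_id"), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_scoring_tables
#' @export
read_scoring_tables <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  lapply(files, function(f) {
    d <- utils::read.table(f, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "numeric"))
    scoring_table(sub("\\.tsv$", "", basename(f)),
                  d$variant_id, d$effect_allele, d$effect_weight)
  })
}
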