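#' Write and read per-study summary-statistic files
#'
#' Summary statistics travel as tab-separated text with the column header
#' STUDY, STRATUM, CHR, POS, RSID, EA, OA, EAF, BETA, SE, P, N, INFO
#' (positions 1-based; CHR is the literal "X" or "AUTO" for autosomal
#' calibration variants). Internally the package uses the lower-case
#' column names `study, stratum, trait, chrom, pos, rsid, ea, oa, eaf,
#' beta, se, p, n, info`.
#'
#' @param records internal-format summary-statistic data.frame.
#' @param path file path.
#' @return `write_summary_stats()` returns `path` invisibly;
#'   `read_summary_stats()` returns an internal-format data.frame.
#' @export
write_summary_stats <- function(records, path) {
  out <- data.frame(STUDY = records$study, STRATUM = records$stratum,
                    CHR = records$chrom, POS = records$pos,
                    RSID = records$rsid, EA = records$ea, OA = records$oa,
                    EAF = records$eaf, BETA = records$beta, SE = records$se,
                    P = records$p, N = records$n, INFO = records$info)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(CHR = "character"))
  data.frame(study = x$STUDY, stratum = x$STRATUM, trait = "sim",
             chrom = x$CHR, pos = x$POS, rsid = x$RSID, ea = x$EA, oa = x$OA,
             eaf = x$EAF, beta = x$BETA, se = x$SE, p = x$P, n = x$N,
             info = x$INFO, stringsAsFactors = FALSE)
}

#' Write a simulated panel to a directory
#'
#' Emits one summary file per study (`<study>.tsv`), the ground-truth table
#' (`truth.tsv`), the LD matrix (`ld.tsv`, square with a header row of
#' variant identifiers) and a `manifest.tsv` echoing the seed and scalar
#' configuration so a run is fully reproducible from disk.
#'
#' @param panel an `xwas_panel` from [simulate_panel()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "xwas_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in unique(panel$records$study))
    write_summary_stats(panel$records[panel$records$study == s, ],
                        file.path(dir, paste0(s, ".tsv")))
  utils::write.table(panel$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_ld_matrix(panel$ld, file.path(dir, "ld.tsv"))
  cfg <- panel$config
  manifest <- data.frame(
    key = c("seed", "n_studies", "n_variants", "n_auto_variants", "ld_decay",
            "xci_escape", "residual_sd"),
    value = c(cfg$seed, cfg$n_studies, cfg$n_variants, cfg$n_auto_variants,
              cfg$ld_decay, cfg$xci_escape, cfg$residual_sd))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read/write an LD reference as a signed correlation matrix
#'
#' The on-disk format is a square tab-separated matrix with a header row of
#' variant identifiers (signed r, unit diagonal).
#'
#' @param ld square correlation matrix with dimnames.
#' @param path file path.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(ld, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  x <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  rownames(x) <- colnames(x)
  x
}

#' Published X-chromosomal kidney-trait index variants
#'
#' Index-variant association statistics of the 23 X-chromosomal loci found
#' for eGFR and serum urate in a large cross-ancestry, sex-stratified
#' meta-analysis of kidney traits (about 0.9 million individuals from 40
#' studies). One row per locus: index variant, position (hg19), best
#' analysis stratum, effect/other allele, effect-allele frequency, beta,
#' SE, association p-value, phenotypic variance explained (percent) and the
#' sex-interaction p-value. Used for worked examples and for the aggregate
#' variance-explained computation.
#'
#' @return a data.frame with 23 rows.
#' @export
xchr_index_variants <- function() {
  path <- system.file("extdata", "xchr_kidney_index_variants.tsv",
                      package = "xwasmeta", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(locus = "character"))
}
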