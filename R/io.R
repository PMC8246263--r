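# Read a TSV tolerantly: strips a UTF-8 BOM and CRLF line endings, checks
# the header, and reports problems with file name and line number.
read_clean_tsv <- function(path, required) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0L) stop(path, ": empty file")
  lines[1] <- sub("^\ufeff", "", lines[1])
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  unknown <- setdiff(required, header)
  if (length(unknown)) {
    stop(path, ":1: missing column(s) ", paste(unknown, collapse = ", "))
  }
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  attr(tab, "source_path") <- path
  tab
}

#' Write a pedigree as three TSV tables
#'
#' The interchange format of the pipeline: `mice.tsv` (mouse_id,
#' generation, sex, sire_id, dam_id, phenotype), `alleles.tsv` (allele_id,
#' gene_id, chrom, pos_cM, effect_class) and `genotypes.tsv` (mouse_id,
#' allele_id, genotype). The simulation-truth causal flag and phenotype
#' model are deliberately not written: mapping must not see them.
#'
#' @param pedigree An `enu_pedigree`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pedigree_tables <- function(pedigree, dir) {
  stopifnot(inherits(pedigree, "enu_pedigree"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(pedigree$mice[, c("mouse_id", "generation", "sex", "sire_id",
                       "dam_id", "phenotype")], "mice.tsv")
  wt(pedigree$alleles[, c("allele_id", "gene_id", "chrom", "pos_cM",
                          "effect_class")], "alleles.tsv")
  geno <- data.frame(
    mouse_id = rep(rownames(pedigree$genotypes), ncol(pedigree$genotypes)),
    allele_id = rep(colnames(pedigree$genotypes),
                    each = nrow(pedigree$genotypes)),
    genotype = as.vector(pedigree$genotypes),
    stringsAsFactors = FALSE
  )
  wt(geno, "genotypes.tsv")
  invisible(dir)
}

#' Read a pedigree back from its three TSV tables
#'
#' Cross-validates the tables: every genotype row must reference a known
#' mouse and allele, genotype symbols must be legal, and parentage must
#' close within the pedigree. Errors name the file and line. Tolerates
#' CRLF line endings and a UTF-8 byte-order mark.
#'
#' @param dir Directory containing `mice.tsv`, `alleles.tsv`,
#'   `genotypes.tsv`.
#' @param pedigree_id Label for the rebuilt pedigree (default: the
#'   directory name).
#' @return An `enu_pedigree` (with a null [phenotype_model()]: simulation
#'   truth is not persisted).
#' @export
read_pedigree_tables <- function(dir, pedigree_id = basename(dir)) {
  mice <- read_clean_tsv(file.path(dir, "mice.tsv"),
                         c("mouse_id", "generation", "sex", "sire_id",
                           "dam_id", "phenotype"))
  alleles <- read_clean_tsv(file.path(dir, "alleles.tsv"),
                            c("allele_id", "gene_id", "chrom", "pos_cM",
                              "effect_class"))
  geno_tab <- read_clean_tsv(file.path(dir, "genotypes.tsv"),
                             c("mouse_id", "allele_id", "genotype"))
  gpath <- attr(geno_tab, "source_path")
  attr(mice, "source_path") <- NULL
  attr(alleles, "source_path") <- NULL
  check_ref <- function(values, known, what) {
    bad <- which(!values %in% known)
    if (length(bad)) {
      stop(gpath, ":", bad[1] + 1L, ": unknown ", what, " '",
           values[bad[1]], "'")
    }
  }
  check_ref(geno_tab$mouse_id, mice$mouse_id, "mouse id")
  check_ref(geno_tab$allele_id, alleles$allele_id, "allele id")
  bad_sym <- which(!geno_tab$genotype %in% GENOTYPE_LEVELS)
  if (length(bad_sym)) {
    stop(gpath, ":", bad_sym[1] + 1L, ": illegal genotype symbol '",
         geno_tab$genotype[bad_sym[1]], "'")
  }
  key <- paste(geno_tab$mouse_id, geno_tab$allele_id)
  if (anyDuplicated(key)) {
    stop(gpath, ":", anyDuplicated(key) + 1L, ": duplicate genotype entry")
  }
  geno <- matrix("MISSING", nrow(mice), nrow(alleles),
                 dimnames = list(mice$mouse_id, alleles$allele_id))
  geno[cbind(geno_tab$mouse_id, geno_tab$allele_id)] <- geno_tab$genotype
  mice$sire_id <- as.character(mice$sire_id)
  mice$dam_id <- as.character(mice$dam_id)
  new_pedigree(pedigree_id, alleles, mice, geno)
}

#' Export a pedigree's genotypes as minimal VCF 4.2
#'
#' An optional export for interoperability: one record per allele with a
#' synthetic contig per map chromosome, sample columns per mouse, and
#' genotypes REF -> `0/0`, HET -> `0/1`, HOM -> `1/1`, MISSING -> `./.`.
#' Because the pipeline's coordinates are genetic (cM), POS is the
#' synthetic integer `round(pos_cM * 1e4) + 1` and the true cM position is
#' kept in the INFO field `CM`. REF/ALT bases are placeholders.
#'
#' @param pedigree An `enu_pedigree`.
#' @param path Output `.vcf` path.
#' @param map A [genetic_map()] used for contig declarations.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(pedigree, path, map = default_mouse_map()) {
  stopifnot(inherits(pedigree, "enu_pedigree"))
  al <- pedigree$alleles
  al <- al[order(match(al$chrom, map$chrom), al$pos_cM), ]
  contigs <- map[map$chrom %in% al$chrom, ]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=enuscreen",
    sprintf("##contig=<ID=%s,length=%d>", contigs$chrom,
            as.integer(round(contigs$length_cM * 1e4)) + 1L),
    "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic map position in centimorgans\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene label\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(pedigree$genotypes)), collapse = "\t")
  )
  gt_code <- c(REF = "0/0", HET = "0/1", HOM = "1/1", MISSING = "./.")
  records <- vapply(seq_len(nrow(al)), function(i) {
    gts <- gt_code[pedigree$genotypes[, al$allele_id[i]]]
    paste(c(al$chrom[i], as.integer(round(al$pos_cM[i] * 1e4)) + 1L,
            al$allele_id[i], "A", "G", ".", "PASS",
            sprintf("CM=%.6g;GENE=%s", al$pos_cM[i], al$gene_id[i]),
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}
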