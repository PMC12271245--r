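#' Read a genotype table
#'
#' Two interchange dialects are supported.  `"vcf"` reads a VCF via the vcfR
#' parser: biallelic sites only, `GT` fields mapped 0/0 -> 0, 0/1 or 1/0 ->
#' 1, 1/1 -> 2, ./. -> missing, gene membership taken from a `GENE` INFO
#' key.  `"tsv"` reads the long tabular dialect (`subject_id`, `snp_id`,
#' `genotype`) together with a SNP metadata table.
#'
#' @param path File path.
#' @param dialect `"vcf"`, `"tsv"` or `"auto"` (by file extension).
#' @param snp_info SNP metadata for the TSV dialect: a data frame or a path
#'   to a TSV with columns `snp_id`, `gene`, `chrom`, `pos`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, dialect = c("auto", "vcf", "tsv"), snp_info = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (dialect == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path, snp_info)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_mat <- vcfR::getFIX(v)
  if (is.null(dim(fix_mat))) {
    fix_mat <- matrix(fix_mat, nrow = 1, dimnames = list(NULL, names(fix_mat)))
  }
  fix <- as.data.frame(fix_mat, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    abort(paste0("multi-allelic sites are unsupported: ",
                 paste(head(fix$ID[multi], 5), collapse = ", ")),
          class = "genevec_unsupported_site")
  }
  gene <- vcfR::extract.info(v, "GENE")
  gt <- vcfR::extract.gt(v, element = "GT")
  map_gt <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    bad <- !is.na(g) & !(g %in% c("0/0", "0/1", "1/0", "1/1", "./."))
    if (any(bad)) abort(paste0("unparseable GT value: ", g[bad][1]))
    out
  }
  geno <- apply(gt, 2, map_gt)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1, dimnames = list(NULL, colnames(gt)))
  geno <- t(geno)
  colnames(geno) <- fix$ID
  snp_info <- tibble::tibble(
    snp_id = fix$ID,
    gene = if (is.null(gene)) NA_character_ else gene,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS)
  )
  genotype_table(geno, snp_info)
}

read_genotypes_tsv <- function(path, snp_info) {
  if (is.null(snp_info)) abort("the TSV dialect requires snp_info metadata")
  if (is.character(snp_info) && length(snp_info) == 1) {
    snp_info <- read_snp_info(snp_info)
  }
  snp_info <- tibble::as_tibble(snp_info)
  long <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  need <- c("subject_id", "snp_id", "genotype")
  if (!all(need %in% names(long))) {
    abort(paste0("genotype TSV needs columns: ", paste(need, collapse = ", ")))
  }
  subjects <- unique(long$subject_id)
  geno <- matrix(NA_integer_, length(subjects), nrow(snp_info),
                 dimnames = list(subjects, snp_info$snp_id))
  geno[cbind(match(long$subject_id, subjects), match(long$snp_id, snp_info$snp_id))] <-
    as.integer(long$genotype)
  genotype_table(geno, snp_info)
}

#' @rdname read_genotypes
#' @param table A [genotype_table()] to write.
#' @export
write_genotypes <- function(table, path, dialect = c("auto", "vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf$", path)) "vcf" else "tsv"
  }
  if (dialect == "vcf") write_genotypes_vcf(table, path) else write_genotypes_tsv(table, path)
  invisible(path)
}

write_genotypes_vcf <- function(table, path) {
  gt_strings <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene membership of the SNP\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            table$subjects), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(table$snps)), function(i) {
    g <- table$geno[, i]
    calls <- ifelse(is.na(g), "./.", gt_strings[g + 1])
    info <- if (is.na(table$snps$gene[i])) "." else paste0("GENE=", table$snps$gene[i])
    paste(c(table$snps$chrom[i], table$snps$pos[i], table$snps$snp_id[i],
            "A", "G", ".", "PASS", info, "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

write_genotypes_tsv <- function(table, path) {
  long <- as_tibble(table)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write SNP metadata
#'
#' @param path TSV path with columns `snp_id`, `gene`, `chrom`, `pos`.
#' @return A tibble.
#' @export
read_snp_info <- function(path) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_snp_info
#' @param snp_info SNP metadata tibble.
#' @export
write_snp_info <- function(snp_info, path) {
  write.table(snp_info, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write clinical trajectories
#'
#' TSV dialect: `subject_id`, `diagnosis`, `scale`, `day`, `score`.
#'
#' @param path TSV path.
#' @return A trajectory tibble.
#' @export
read_trajectories <- function(path) {
  out <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  check_trajectory(out)
  out
}

#' @rdname read_trajectories
#' @param trajectories Trajectory tibble.
#' @export
write_trajectories <- function(trajectories, path) {
  check_trajectory(trajectories)
  write.table(trajectories, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write outcome labels
#'
#' @param path TSV path.
#' @return A labels tibble.
#' @export
read_labels <- function(path) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_labels
#' @param labels Labels tibble.
#' @export
write_labels <- function(labels, path) {
  write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
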